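# Internal validation and RNG helpers.

stop_cumrisk <- function(msg, class) {
  abort(msg, class = c(class, "cumrisk_error"))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cumrisk(sprintf("`%s` must be a single finite number.", name),
                 "cumrisk_validation_error")
  }
  if (positive && x <= 0) {
    stop_cumrisk(sprintf("`%s` must be > 0 (got %g).", name, x),
                 "cumrisk_validation_error")
  }
  if (nonneg && x < 0) {
    stop_cumrisk(sprintf("`%s` must be >= 0 (got %g).", name, x),
                 "cumrisk_validation_error")
  }
  invisible(x)
}

assert_has_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_cumrisk(sprintf("`%s` is missing column(s): %s.",
                         name, paste(missing, collapse = ", ")),
                 "cumrisk_validation_error")
  }
  invisible(df)
}

# Deterministic 31-bit hash of a string, used to derive independent
# RNG substreams per population group so results are invariant to
# group ordering and safe for parallel execution.
hash31 <- function(s) {
  v <- utf8ToInt(enc2utf8(as.character(s)))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483629
  as.integer(h)
}

# Substream seed for (master seed, group label, outer replicate index).
# Kept below 2^31 - 1; outer = 0 is reserved for shared per-replicate
# parameter draws and summary-level streams.
substream_seed <- function(seed, group_id = "", outer = 0L) {
  h <- hash31(paste0(group_id, "|", outer))
  as.integer((as.numeric(seed) * 48271 + as.numeric(h)) %% 2147483629)
}

# Lognormal (mu, sigma) matching a target arithmetic mean and CV.
# cv = 0 collapses to a point mass at `mean`.
lognormal_params <- function(mean, cv) {
  sigma2 <- log(1 + cv^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Draws n lognormal values with arithmetic mean `mean` and coefficient
# of variation `cv`; degenerate (mean 0 or cv 0) cases return constants.
rlnorm_meancv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  p <- lognormal_params(mean, cv)
  rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}
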