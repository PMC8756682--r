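# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, ..., class = "sbaspatial_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(paste0(...), class = c(class, "sbaspatial_error")))
  }
  invisible(TRUE)
}

# population z-score (1/n variance); chosen so that sum(z^2) = n, which makes
# the bivariate Moran statistic with y = x collapse exactly onto the
# univariate one and makes the LISA-to-global sum identity hold on both paths
.zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  .assert(s > 0, "variable is constant; spatial statistics are undefined",
          class = "sbaspatial_degenerate")
  (x - mu) / s
}

.check_numeric_vector <- function(x, n, what = "x") {
  .assert(is.numeric(x), what, " must be numeric")
  .assert(length(x) == n, what, " has length ", length(x),
          " but the weight matrix indexes ", n, " units")
  .assert(all(is.finite(x)), what, " contains non-finite values")
  invisible(TRUE)
}

# deterministic per-stage seed derived from a master seed; stays < 2^31
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 100003L)
}

# tiny polynomial rolling hash of a character scalar, for run metadata only
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}
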