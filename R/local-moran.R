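# Local Moran (LISA): per-unit decomposition of Moran's I, conditional
# permutation inference, and the hotspot/coldspot/outlier classification.

.lisa_labels <- c("hotspot", "coldspot", "high_low_outlier",
                  "low_high_outlier", "not_significant", "island")

.new_local_moran <- function(df, variable_x, variable_y, weights,
                             permutations = NA_integer_, seed = NA_integer_,
                             alpha = NA_real_) {
  structure(df, class = c("local_moran", "data.frame"),
            variable_x = variable_x, variable_y = variable_y,
            s0 = weights$s0, permutations = permutations,
            seed = seed, alpha = alpha)
}

#' @export
print.local_moran <- function(x, ...) {
  vy <- attr(x, "variable_y")
  kind <- if (is.na(vy %||% NA)) "univariate" else "bivariate"
  cat("<local_moran> ", kind, " LISA, ", nrow(x), " units, variable ",
      attr(x, "variable_x"),
      if (!is.na(vy %||% NA)) paste0(" vs ", vy) else "", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more rows\n", sep = "")
  invisible(x)
}

# quadrant from signs; an exact zero is tie-broken to the "low" side
.quadrant <- function(z, lag) {
  ifelse(z > 0, ifelse(lag > 0, "HH", "HL"), ifelse(lag > 0, "LH", "LL"))
}

#' Local univariate Moran (LISA)
#'
#' Per-unit decomposition of global Moran's I,
#' \deqn{I_i = \frac{n\,(x_i-\bar x)}{\sum_k (x_k-\bar x)^2}
#'   \sum_j w_{ij}(x_j-\bar x),}
#' which satisfies \eqn{\sum_i I_i = S_0 \cdot I}. Each unit also gets its
#' standardized value `z_value`, the standardized neighbor lag `lag_value`,
#' and the Moran-scatterplot quadrant (HH/LL/HL/LH). Islands get `local_i =
#' 0` and label `"island"`. Pseudo p-values come from conditional
#' permutation (set `permutations = 0` to skip), and significance labels are
#' filled by [classify_clusters()] at level `alpha`.
#'
#' @inheritParams global_moran
#' @param alpha significance level for cluster labels.
#' @return a `local_moran` data frame with columns `unit_id`, `local_i`,
#'   `z_value`, `lag_value`, `quadrant`, `pseudo_p`, `cluster_label`.
#' @export
local_moran <- function(weights, x, variable = deparse(substitute(x)),
                        permutations = 999, seed = 42, alpha = 0.05) {
  .check_moran_inputs(weights, x)
  n <- weights$n
  z <- x - mean(x)
  lag_dev <- as.numeric(weights$W %*% z)
  local_i <- n * z * lag_dev / sum(z^2)
  zs <- .zscore(x)
  df <- data.frame(
    unit_id = weights$ids,
    local_i = local_i,
    z_value = zs,
    lag_value = as.numeric(weights$W %*% zs),
    stringsAsFactors = FALSE
  )
  .finish_lisa(df, weights, x, NULL, variable, NA_character_,
               permutations, seed, alpha)
}

#' Local bivariate Moran (bivariate LISA)
#'
#' The bivariate local statistic \eqn{I_i = z_{x,i} \sum_j w_{ij} z_{y,j}} on
#' z-scored variables: the standardized value of `x` at a unit against the
#' standardized lag of `y` at its neighbors. With `y = x` it coincides with
#' [local_moran()] unit by unit.
#'
#' @inheritParams local_moran
#' @param y second numeric vector (lagged variable).
#' @param variable_x,variable_y names to record.
#' @return a `local_moran` data frame (see [local_moran()]).
#' @export
local_moran_bivariate <- function(weights, x, y,
                                  variable_x = deparse(substitute(x)),
                                  variable_y = deparse(substitute(y)),
                                  permutations = 999, seed = 42,
                                  alpha = 0.05) {
  .check_moran_inputs(weights, x, bivariate = TRUE, y = y)
  zx <- .zscore(x); zy <- .zscore(y)
  lag <- as.numeric(weights$W %*% zy)
  df <- data.frame(
    unit_id = weights$ids,
    local_i = zx * lag,
    z_value = zx,
    lag_value = lag,
    stringsAsFactors = FALSE
  )
  .finish_lisa(df, weights, x, y, variable_x, variable_y,
               permutations, seed, alpha)
}

.finish_lisa <- function(df, weights, x, y, vx, vy, permutations, seed, alpha) {
  island <- weights$ids %in% weights$islands
  df$local_i[island] <- 0
  df$quadrant <- .quadrant(df$z_value, df$lag_value)
  df$quadrant[island] <- NA_character_
  if (permutations > 0) {
    df$pseudo_p <- conditional_permutation(weights, x, y, permutations, seed)
  } else {
    df$pseudo_p <- NA_real_
  }
  df$cluster_label <- NA_character_
  out <- .new_local_moran(df, vx, vy, weights,
                          permutations = as.integer(permutations),
                          seed = as.integer(seed), alpha = alpha)
  if (permutations > 0) out <- classify_clusters(out, alpha) else {
    out$cluster_label[island] <- "island"
  }
  out
}

# R x k index matrix, each row a without-replacement draw from 1..m,
# vectorized rejection of rows with duplicates (k is a small neighbor count)
.sample_rows <- function(R, k, m) {
  .assert(k <= m, "cannot draw ", k, " neighbors from ", m, " candidates")
  M <- matrix(sample.int(m, R * k, replace = TRUE), R, k)
  if (k == 1) return(M)
  repeat {
    dup <- rep(FALSE, R)
    for (a in 1:(k - 1)) for (b in (a + 1):k) dup <- dup | (M[, a] == M[, b])
    nb <- sum(dup)
    if (nb == 0) break
    M[dup, ] <- matrix(sample.int(m, nb * k, replace = TRUE), nb, k)
  }
  M
}

#' Conditional permutation pseudo p-values for local Moran
#'
#' Conditional randomization: for each unit i its own value is held fixed
#' while the values observed at the other n-1 units are randomly re-assigned
#' to its neighbors R times and the local statistic recomputed each time;
#' \eqn{p_i = (m_i+1)/(R+1)} where `m_i` counts null statistics at least as
#' extreme as the observed \eqn{I_i}, extremity measured as absolute
#' deviation from the unit's permutation-null mean (symmetric counting keeps
#' the nominal level calibrated while flagging both cluster cores and
#' spatial outliers; see [moran_permutation_test()]). Islands get `NA`.
#'
#' @inheritParams moran_permutation_test
#' @return numeric vector of per-unit pseudo p-values.
#' @export
conditional_permutation <- function(weights, x, y = NULL, permutations = 999,
                                    seed = 42) {
  .assert(permutations >= 19,
          "permutations must be >= 19 for a meaningful pseudo p-value")
  bi <- !is.null(y)
  .check_moran_inputs(weights, x, bivariate = bi, y = y)
  n <- weights$n
  if (bi) {
    scale_i <- .zscore(x)          # held fixed at each unit
    pool_all <- .zscore(y)         # permuted over neighbors
  } else {
    z <- x - mean(x)
    scale_i <- n * z / sum(z^2)
    pool_all <- z
  }
  Wl <- methods::as(weights$W, "RsparseMatrix")
  pseudo_p <- rep(NA_real_, n)
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    from <- Wl@p[i] + 1L; to <- Wl@p[i + 1L]
    if (to < from) next                      # island
    wrow <- Wl@x[from:to]
    nbrs <- Wl@j[from:to] + 1L
    obs <- scale_i[i] * sum(wrow * pool_all[nbrs])
    pool <- pool_all[-i]
    draws <- .sample_rows(permutations, length(wrow), n - 1L)
    null_lag <- matrix(pool[draws], nrow(draws), ncol(draws)) %*% wrow
    null_i <- scale_i[i] * as.numeric(null_lag)
    center <- mean(null_i)
    m <- sum(abs(null_i - center) >= abs(obs - center))
    pseudo_p[i] <- (m + 1) / (permutations + 1)
  }
  pseudo_p
}

#' Classify LISA quadrants into cluster labels
#'
#' Fills the four-quadrant taxonomy: significant HH units are hotspots
#' (high values with alike neighbors), significant LL units coldspots,
#' significant HL/LH units spatial outliers; everything else is
#' `not_significant` and islands keep the label `island`. Quadrants come from
#' the signs of the standardized value and standardized lag, so the
#' high/low thresholds sit at the variable means; a value exactly at the
#' mean is tie-broken to the "low" side.
#'
#' @param stats a `local_moran` object with `pseudo_p` filled.
#' @param alpha significance level in (0, 1).
#' @return the `local_moran` object with `cluster_label` filled.
#' @export
classify_clusters <- function(stats, alpha = 0.05) {
  stopifnot(inherits(stats, "local_moran"))
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must lie strictly in (0, 1)")
  island <- is.na(stats$quadrant)
  lab <- rep("not_significant", nrow(stats))
  sig <- !island & !is.na(stats$pseudo_p) & stats$pseudo_p <= alpha
  map <- c(HH = "hotspot", LL = "coldspot",
           HL = "high_low_outlier", LH = "low_high_outlier")
  lab[sig] <- map[stats$quadrant[sig]]
  lab[island] <- "island"
  stats$cluster_label <- lab
  attr(stats, "alpha") <- alpha
  stats
}

#' Count units per cluster label
#'
#' @param stats a `local_moran` object with labels filled.
#' @return named integer vector over the labels `hotspot`, `coldspot`,
#'   `high_low_outlier`, `low_high_outlier`, `not_significant`, `island`;
#'   sums to the number of units.
#' @export
cluster_counts <- function(stats) {
  stopifnot(inherits(stats, "local_moran"))
  .assert(!anyNA(stats$cluster_label), "cluster labels are not filled")
  tab <- table(factor(stats$cluster_label, levels = .lisa_labels))
  out <- as.integer(tab)
  names(out) <- .lisa_labels
  out
}
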