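#' @include AllClasses.R
NULL

# vectorised unpaired two-tailed Student's t (pooled variance).
# Degenerate groups (pooled sd 0) give t = 0, p = 1 when the means agree and
# |t| = Inf, p = 0 when they differ, instead of erroring like stats::t.test.
.tPooledVec <- function(mean1, var1, n1, mean2, var2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean1 - mean2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), ifelse(t == 0, 1, 0))
  p[se == 0 & d == 0] <- 1
  list(t = t, df = df, p = p)
}

#' Unpaired two-tailed Student's t-test (pooled variance)
#'
#' The comparison used throughout: mean of group `x` versus mean of group
#' `y`, equal-variance pooling, two-tailed p. Identical constant groups give
#' `t = 0`, `p = 1` rather than an error.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`, and per-group means/sds.
#' @examples
#' pooledTTest(c(0.10, 0.12, 0.11), c(0.50, 0.55, 0.45))
#' @export
pooledTTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 non-missing values")
  r <- .tPooledVec(mean(x), stats::var(x), length(x),
                   mean(y), stats::var(y), length(y))
  list(t = r$t, df = r$df, p = r$p,
       mean_x = mean(x), sd_x = stats::sd(x),
       mean_y = mean(y), sd_y = stats::sd(y))
}

# row-wise pooled t between two column groups of a matrix
.rowTPooled <- function(mat, idx1, idx2) {
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- apply(mat[, idx1, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, idx2, drop = FALSE], 1L, stats::var)
  r <- .tPooledVec(m1, v1, length(idx1), m2, v2, length(idx2))
  data.frame(mean1 = m1, mean2 = m2, t = r$t, df = r$df, p = r$p)
}
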