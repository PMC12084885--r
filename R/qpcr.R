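#' @include AllClasses.R stats-utils.R
NULL

#' Relative quantification of qPCR Ct values
#'
#' Delta-Ct quantification with amplification efficiency fixed at 2 (one
#' template doubling per cycle; no standard curves assumed): the relative
#' level of a target in a sample is `2^-(Ct_target - Ct_ref)`, where
#' `Ct_ref` is the arithmetic mean of the reference-gene Ct values in that
#' sample. Averaging reference Cts is equivalent to taking the geometric
#' mean of the per-reference relative levels. Multiple reference mRNAs
#' (e.g. act5c, gapdh, rp49) guard against drift in any single one.
#'
#' A sample missing a reference Ct violates the contract and errors; a
#' sample missing a target Ct is dropped for that target with a warning.
#'
#' @param ct numeric matrix of Ct values, genes x samples.
#' @param targets target gene names (rows of `ct`).
#' @param references reference gene names (rows of `ct`).
#' @return data.frame `sample`, `target`, `rel_level`.
#' @examples
#' ct <- rbind(act5c = c(s1 = 18, s2 = 18), targetA = c(17, 19))
#' qpcrRelativeQuant(ct, "targetA", "act5c")
#' @export
qpcrRelativeQuant <- function(ct, targets, references) {
  ct <- as.matrix(ct)
  missing_rows <- setdiff(c(targets, references), rownames(ct))
  if (length(missing_rows))
    stop("genes absent from the Ct table: ",
         paste(missing_rows, collapse = ", "))
  refct <- ct[references, , drop = FALSE]
  if (anyNA(refct))
    stop("every sample must have a Ct for every reference gene")
  ref_mean <- colMeans(refct)
  out <- list()
  for (tg in targets) {
    tct <- ct[tg, ]
    drop <- is.na(tct)
    if (any(drop))
      warning("dropping ", sum(drop), " sample(s) with missing Ct for ", tg)
    keep <- which(!drop)
    out[[tg]] <- data.frame(sample = colnames(ct)[keep], target = tg,
                            rel_level = 2^-(tct[keep] - ref_mean[keep]),
                            row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fold-change of qPCR relative levels between conditions
#'
#' Ratio of mean relative levels (condition of interest over reference
#' condition) per target, with an unpaired two-tailed Student's t-test
#' (pooled variance) on the per-replicate levels.
#'
#' @param rq output of [qpcrRelativeQuant()].
#' @param design data.frame `sample`, `genotype` (or any condition column
#'   named `genotype`).
#' @param numerator,denominator condition labels to compare.
#' @return data.frame per target: group means, `fold`, `t`, `p`.
#' @export
qpcrFoldChange <- function(rq, design, numerator, denominator) {
  gt <- design$genotype[match(rq$sample, design$sample)]
  out <- list()
  for (tg in unique(rq$target)) {
    xv <- rq$rel_level[rq$target == tg & gt == numerator]
    yv <- rq$rel_level[rq$target == tg & gt == denominator]
    tt <- pooledTTest(xv, yv)
    out[[tg]] <- data.frame(target = tg, mean_num = tt$mean_x,
                            mean_den = tt$mean_y,
                            fold = tt$mean_x / tt$mean_y,
                            t = tt$t, p = tt$p, row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
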