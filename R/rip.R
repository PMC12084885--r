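#' @include AllClasses.R stats-utils.R
NULL

#' Normalize a count matrix
#'
#' `"CPM"` scales each column to one million total counts, making fold
#' enrichments invariant to library size. `"median-of-ratios"` computes a
#' per-column size factor as the median, over features with a positive
#' geometric mean across samples, of count / geometric-row-mean, and divides
#' each column by its factor (the standard RNA-seq size-factor estimator,
#' robust to a minority of truly enriched features).
#'
#' @param counts numeric matrix, features x samples.
#' @param method `"CPM"` or `"median-of-ratios"`.
#' @return normalized matrix of the same shape. For `"median-of-ratios"` the
#'   size factors are attached as `attr(, "sizeFactors")`.
#' @export
normalizeCounts <- function(counts, method = c("CPM", "median-of-ratios")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (method == "CPM") {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("cannot CPM-normalize an all-zero column")
    sweep(counts, 2L, tot / 1e6, `/`)
  } else {
    loggeo <- rowMeans(log(counts))
    use <- is.finite(loggeo)
    if (!any(use)) stop("no feature has nonzero counts in every sample")
    sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
      stats::median(col / exp(loggeo[use])))
    out <- sweep(counts, 2L, sf, `/`)
    attr(out, "sizeFactors") <- sf
    out
  }
}

#' Score IP-versus-control enrichment (RIP-seq)
#'
#' For each feature, fold enrichment is the ratio of mean normalized
#' abundance in the immunoprecipitate arm to the mock-control arm, with a
#' pseudocount stabilising low-count features:
#' `fold = (mean_IP + pseudocount) / (mean_control + pseudocount)`.
#' The p-value is an unpaired two-tailed Student's t-test (pooled variance)
#' on `log2(normalized + pseudocount)` per arm, and q is Benjamini-Hochberg
#' across features — the volcano-plot coordinates are `log2_fold` and
#' `-log10(p)`.
#'
#' Features with zero counts in both arms carry no information; they are
#' reported with fold 1, p 1 and `flag = "all_zero"` instead of being
#' dropped.
#'
#' @param counts raw count matrix, features x samples.
#' @param design data.frame `sample`, `arm` with arms `"IP"` and
#'   `"control"`, >= 2 replicates each.
#' @param pseudocount added to normalized means and before logs (default
#'   0.5).
#' @param method normalization method, see [normalizeCounts()].
#' @return `DataFrame` per feature: `mean_IP`, `mean_control`,
#'   `fold_enrichment`, `log2_fold`, `p`, `q`, `flag`.
#' @export
scoreEnrichment <- function(counts, design, pseudocount = 0.5,
                            method = "CPM") {
  stopifnot(all(c("sample", "arm") %in% names(design)))
  counts <- as.matrix(counts)
  idx_ip <- match(design$sample[design$arm == "IP"], colnames(counts))
  idx_ct <- match(design$sample[design$arm == "control"], colnames(counts))
  if (anyNA(idx_ip) || anyNA(idx_ct))
    stop("design samples missing from the count matrix")
  if (length(idx_ip) < 2L || length(idx_ct) < 2L)
    stop("each arm needs >= 2 replicates")
  norm <- normalizeCounts(counts, method)
  mean_ip <- rowMeans(norm[, idx_ip, drop = FALSE])
  mean_ct <- rowMeans(norm[, idx_ct, drop = FALSE])
  fold <- (mean_ip + pseudocount) / (mean_ct + pseudocount)
  tt <- .rowTPooled(log2(norm + pseudocount), idx_ip, idx_ct)
  p <- tt$p
  allzero <- rowSums(counts[, c(idx_ip, idx_ct), drop = FALSE]) == 0
  fold[allzero] <- 1
  p[allzero] <- 1
  DataFrame(feature = rownames(counts),
            mean_IP = unname(mean_ip), mean_control = unname(mean_ct),
            fold_enrichment = unname(fold), log2_fold = unname(log2(fold)),
            p = unname(p), q = unname(stats::p.adjust(p, method = "BH")),
            flag = unname(ifelse(allzero, "all_zero", "")))
}
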