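#' @include AllClasses.R stats-utils.R rip.R
NULL

#' Per-feature differential statistics across genotype contrasts
#'
#' Tests the mutant genotype against each comparator genotype separately,
#' feature by feature: RNA count matrices are transformed to
#' `log2(CPM + 0.5)` and protein abundance matrices to `log2(abundance)`,
#' then each contrast gets an unpaired two-tailed Student's t-test (pooled
#' variance) on the transformed values, with Benjamini-Hochberg adjustment
#' across features within each contrast (and modality). The decision layer
#' ([callDE()]) is kept separate, so statistics from any other engine can be
#' piped into it.
#'
#' @param x matrix, features x samples (raw counts for `"rna"`, abundances
#'   for `"protein"`).
#' @param design data.frame `sample`, `genotype`; every genotype entering a
#'   contrast needs >= 2 replicates (a single-replicate genotype is refused
#'   with an error, not silently tested).
#' @param mutant genotype under test.
#' @param comparators default: all other genotypes in the design.
#' @param modality `"rna"` or `"protein"`.
#' @param pseudocount added to CPM before the log (RNA only).
#' @return `DataFrame`, one row per feature x contrast: `log2fc` (mutant
#'   minus comparator on the log2 scale), `fc`, `t`, `df`, `p`, `adj_p`,
#'   `modality`.
#' @export
testFeatures <- function(x, design, mutant = "mut", comparators = NULL,
                         modality = c("rna", "protein"), pseudocount = 0.5) {
  modality <- match.arg(modality)
  stopifnot(all(c("sample", "genotype") %in% names(design)))
  x <- as.matrix(x)
  if (is.null(comparators))
    comparators <- setdiff(unique(design$genotype), mutant)
  groups <- c(mutant, comparators)
  idx <- lapply(groups, function(g)
    match(design$sample[design$genotype == g], colnames(x)))
  names(idx) <- groups
  for (g in groups) {
    if (anyNA(idx[[g]]))
      stop("samples of genotype '", g, "' missing from the matrix")
    if (length(idx[[g]]) < 2L)
      stop("genotype '", g, "' has fewer than 2 replicates; contrast refused")
  }
  logx <- if (modality == "rna")
    log2(normalizeCounts(x, "CPM") + pseudocount)
  else {
    if (any(x <= 0)) stop("protein abundances must be positive")
    log2(x)
  }
  out <- list()
  for (cmp in comparators) {
    tt <- .rowTPooled(logx, idx[[mutant]], idx[[cmp]])
    lfc <- tt$mean1 - tt$mean2
    out[[cmp]] <- DataFrame(feature = rownames(x),
                            contrast = paste0(mutant, "_vs_", cmp),
                            log2fc = lfc, fc = 2^lfc,
                            t = tt$t, df = tt$df, p = tt$p,
                            adj_p = stats::p.adjust(tt$p, method = "BH"),
                            modality = modality)
  }
  do.call(rbind, unname(out))
}

#' Call differential features from multi-contrast statistics
#'
#' Applies the concordance decision rule: a feature is called only when it
#' passes the thresholds against *every* comparator genotype.
#' For RNA, `up` requires adjusted p < `alpha` and log2 fold-change >
#' `lfcBound` in every contrast, `down` the mirror image with log2
#' fold-change < `-lfcBound`; the bounds are strict (a log2 fold-change of
#' exactly 0.29 does not qualify). For protein, the linear fold-change must
#' exceed `fcBounds[2]` (up) or fall below `fcBounds[1]` (down) in every
#' contrast, again with adjusted p < `alpha`. The default protein bounds
#' 0.7 and 1.43 are near-reciprocal (1/1.43 = 0.699) but are applied as
#' printed, not symmetrized. Features whose contrasts are individually
#' significant but disagree in direction are returned `unchanged` with
#' `discordant = TRUE`.
#'
#' @param stats output of [testFeatures()] (or any table with columns
#'   `feature`, `contrast`, `log2fc`, `fc`, `adj_p`).
#' @param modality `"rna"` or `"protein"`; default taken from `stats`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfcBound RNA log2 fold-change bound (default 0.29).
#' @param fcBounds protein fold-change bounds, `c(down, up)` (default
#'   0.7 and 1.43).
#' @return `DataFrame` per feature: `call` (`"up"`, `"down"`,
#'   `"unchanged"`), `discordant`, `max_adj_p`, `min_abs_log2fc`.
#' @export
callDE <- function(stats, modality = NULL, alpha = 0.05, lfcBound = 0.29,
                   fcBounds = c(0.7, 1.43)) {
  df <- as.data.frame(stats)
  if (is.null(modality)) {
    modality <- unique(df$modality)
    if (length(modality) != 1L)
      stop("stats must carry a single modality, or pass one explicitly")
  }
  stopifnot(modality %in% c("rna", "protein"))
  features <- unique(df$feature)
  contrasts <- unique(df$contrast)
  get_mat <- function(col) {
    m <- matrix(NA_real_, length(features), length(contrasts),
                dimnames = list(features, contrasts))
    m[cbind(match(df$feature, features), match(df$contrast, contrasts))] <-
      df[[col]]
    m
  }
  adj <- get_mat("adj_p")
  if (anyNA(adj)) stop("every feature needs a statistic for every contrast")
  sig <- adj < alpha
  if (modality == "rna") {
    lfc <- get_mat("log2fc")
    up_c <- sig & lfc > lfcBound
    dn_c <- sig & lfc < -lfcBound
    min_eff <- apply(abs(lfc), 1L, min)
  } else {
    fc <- get_mat("fc")
    up_c <- sig & fc > fcBounds[2L]
    dn_c <- sig & fc < fcBounds[1L]
    min_eff <- apply(abs(log2(fc)), 1L, min)
  }
  up <- apply(up_c, 1L, all)
  dn <- apply(dn_c, 1L, all)
  discordant <- !up & !dn & apply(up_c | dn_c, 1L, all)
  DataFrame(feature = features, modality = modality,
            call = unname(ifelse(up, "up", ifelse(dn, "down", "unchanged"))),
            discordant = unname(discordant),
            max_adj_p = unname(apply(adj, 1L, max)),
            min_abs_log2fc = unname(min_eff))
}
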