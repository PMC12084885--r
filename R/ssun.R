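#' @include AllClasses.R AllGenerics.R simulate.R stats-utils.R
NULL

# distinct-read counts per (window, sample); returns a windows x samples
# integer matrix
.windowSampleCounts <- function(reads, windows, minOverlap = 1L) {
  b <- readBlocks(reads)
  samples <- unique(mcols(b)$sample)
  if (length(samples) == 0L) samples <- character()
  hits <- findOverlaps(b, windows, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  rid <- mcols(b)$read_id[q]
  smp <- mcols(b)$sample[q]
  key <- paste(s, smp, rid, sep = "\1")
  keep <- !duplicated(key)
  m <- matrix(0L, nrow = length(windows), ncol = max(length(samples), 1L),
              dimnames = list(NULL, if (length(samples)) samples else "none"))
  if (any(keep)) {
    tab <- table(factor(s[keep], levels = seq_along(windows)),
                 factor(smp[keep], levels = colnames(m)))
    m[] <- as.integer(tab)
  }
  m
}

#' Count reads overlapping a genomic window
#'
#' A read is counted when at least `minOverlap` nt of one of its aligned
#' blocks lies inside the window; alignment gaps (spliced-out segments) are
#' not aligned coverage, so a junction-spanning read whose gap covers the
#' window contributes nothing. Each read counts at most once per window even
#' if several of its blocks overlap it. Strand is ignored.
#'
#' @param reads an [AlignedReadSet-class].
#' @param windows `GRanges` of windows.
#' @param minOverlap minimum aligned overlap in nt (default 1).
#' @return integer vector, one count per window (summed over samples).
#' @export
countWindowReads <- function(reads, windows, minOverlap = 1L) {
  rowSums(.windowSampleCounts(reads, windows, minOverlap))
}

#' Compute the splice-site unusage (SSun) statistic
#'
#' SSun quantifies how much a splice site goes unused, from read counts in
#' the two fixed-width windows meeting at the exon/intron boundary: with the
#' default orientation, `ssun = intronic_count / exonic_count`, so a
#' perfectly spliced site (no intronic boundary reads) scores 0 and the
#' value rises as the intron is retained. The inverse convention
#' (`exonic / intronic`) is available via `orientation` for users of the
#' original ratio direction.
#'
#' A record is evaluable only when its denominator window holds at least
#' `minExonicReads` reads; below that the ratio is reported as `NA` with
#' `evaluable = FALSE` (no pseudocounts, no smoothing), and the exclusion
#' reason is the count itself.
#'
#' @param reads an [AlignedReadSet-class].
#' @param windows output of [boundaryWindows()] (the exonic/intronic pairs).
#' @param minExonicReads minimum denominator-window reads for an evaluable
#'   record (default 10).
#' @param minOverlap minimum aligned overlap for window membership, see
#'   [countWindowReads()].
#' @param orientation `"intronic_over_exonic"` (default; larger = more
#'   retention) or `"exonic_over_intronic"`.
#' @return `DataFrame` with one row per splice site x sample: `gene_id`,
#'   `intron_index`, `intron_class`, `site_kind`, `sample`, `exonic_count`,
#'   `intronic_count`, `ssun`, `evaluable`, `truncated`.
#' @seealso [compareSSun()]
#' @export
computeSSun <- function(reads, windows, minExonicReads = 10L,
                        minOverlap = 1L,
                        orientation = c("intronic_over_exonic",
                                        "exonic_over_intronic")) {
  orientation <- match.arg(orientation)
  need <- c("gene_id", "intron_index", "site_kind", "window_kind")
  if (!all(need %in% names(mcols(windows))))
    stop("windows must come from boundaryWindows()")
  cnt <- .windowSampleCounts(reads, windows, minOverlap)
  wmeta <- as.data.frame(mcols(windows))
  sitekey <- paste(wmeta$gene_id, wmeta$intron_index, wmeta$site_kind,
                   sep = "\1")
  ex_i <- which(wmeta$window_kind == "exonic")
  in_i <- which(wmeta$window_kind == "intronic")
  m <- match(sitekey[in_i], sitekey[ex_i])
  if (anyNA(m) || length(ex_i) != length(in_i))
    stop("each splice site needs exactly one exonic and one intronic window")
  in_i <- in_i[order(m)]  # align intronic rows to exonic rows
  samples <- colnames(cnt)
  rows <- expand.grid(site = seq_along(ex_i), sample = samples,
                      stringsAsFactors = FALSE)
  exc <- cnt[ex_i, , drop = FALSE][cbind(rows$site,
                                         match(rows$sample, samples))]
  inc <- cnt[in_i, , drop = FALSE][cbind(rows$site,
                                         match(rows$sample, samples))]
  num <- if (orientation == "intronic_over_exonic") inc else exc
  den <- if (orientation == "intronic_over_exonic") exc else inc
  evaluable <- den >= minExonicReads
  ssun <- ifelse(evaluable, num / den, NA_real_)
  em <- wmeta[ex_i, , drop = FALSE]
  trunc_pair <- wmeta$truncated[ex_i] | wmeta$truncated[in_i]
  DataFrame(gene_id = em$gene_id[rows$site],
            intron_index = em$intron_index[rows$site],
            intron_class = em$intron_class[rows$site],
            site_kind = em$site_kind[rows$site],
            sample = rows$sample,
            exonic_count = as.integer(exc),
            intronic_count = as.integer(inc),
            ssun = ssun, evaluable = evaluable,
            truncated = trunc_pair[rows$site])
}

#' Compare SSun across genotypes
#'
#' For every splice site, tests the mutant genotype against each comparator
#' genotype with an unpaired two-tailed Student's t-test (pooled variance)
#' on the per-replicate SSun values. A site is flagged significant only when
#' every contrast passes `p < alpha` — the raw per-site p, mirroring
#' per-site asterisks at alpha = 0.05; Benjamini-Hochberg q-values across
#' sites are reported alongside for each contrast.
#'
#' Only evaluable records enter the tests; a contrast with fewer than two
#' evaluable replicates in either group is reported untested with a reason
#' rather than silently dropped.
#'
#' @param records output of [computeSSun()].
#' @param design data.frame with columns `sample`, `genotype`.
#' @param mutant genotype under test.
#' @param comparators genotypes to test against; default all others.
#' @param alpha per-contrast significance level (default 0.05).
#' @return `DataFrame`, one row per site x contrast: group sizes, means and
#'   sds, `t`, `df`, `p`, `q` (BH within contrast), `tested`, `reason`, and
#'   the site-level `site_significant` flag (identical across a site's
#'   rows).
#' @export
compareSSun <- function(records, design, mutant = "mut",
                        comparators = NULL, alpha = 0.05) {
  stopifnot(all(c("sample", "genotype") %in% names(design)))
  gt <- design$genotype[match(records$sample, design$sample)]
  if (anyNA(gt)) stop("records contain samples missing from the design")
  if (is.null(comparators))
    comparators <- setdiff(unique(design$genotype), mutant)
  if (!length(comparators)) stop("no comparator genotypes")
  df <- as.data.frame(records)
  df$genotype <- gt
  sites <- unique(df[, c("gene_id", "intron_index", "intron_class",
                         "site_kind")])
  out <- list()
  for (i in seq_len(nrow(sites))) {
    sel <- df$gene_id == sites$gene_id[i] &
      df$intron_index == sites$intron_index[i] &
      df$site_kind == sites$site_kind[i]
    mutv <- df$ssun[sel & df$genotype == mutant & df$evaluable]
    for (cmp in comparators) {
      cmpv <- df$ssun[sel & df$genotype == cmp & df$evaluable]
      row <- cbind(sites[i, , drop = FALSE],
                   data.frame(contrast = paste0(mutant, "_vs_", cmp),
                              n_mut = length(mutv), n_comp = length(cmpv),
                              mean_mut = NA_real_, sd_mut = NA_real_,
                              mean_comp = NA_real_, sd_comp = NA_real_,
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              tested = FALSE, reason = ""))
      if (length(mutv) >= 2L && length(cmpv) >= 2L) {
        tt <- pooledTTest(mutv, cmpv)
        row$mean_mut <- tt$mean_x; row$sd_mut <- tt$sd_x
        row$mean_comp <- tt$mean_y; row$sd_comp <- tt$sd_y
        row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
        row$tested <- TRUE
      } else {
        row$reason <- "fewer than 2 evaluable replicates in a group"
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (cmp in unique(res$contrast)) {
    k <- res$contrast == cmp & res$tested
    res$q[k] <- stats::p.adjust(res$p[k], method = "BH")
  }
  skey <- paste(res$gene_id, res$intron_index, res$site_kind, sep = "\1")
  sig <- tapply(res$tested & res$p < alpha, skey, all)
  res$site_significant <- as.logical(sig[skey])
  rownames(res) <- NULL
  DataFrame(res)
}

#' Site-level summary of an SSun comparison
#'
#' Collapses [compareSSun()] output to one row per splice site.
#'
#' @param comparison output of [compareSSun()].
#' @return `DataFrame` with per-site `site_significant`, the maximum
#'   per-contrast p, and whether all contrasts were tested.
#' @export
ssunSignificantSites <- function(comparison) {
  df <- as.data.frame(comparison)
  key <- paste(df$gene_id, df$intron_index, df$site_kind, sep = "\1")
  first <- !duplicated(key)
  out <- df[first, c("gene_id", "intron_index", "intron_class", "site_kind")]
  out$all_tested <- as.logical(tapply(df$tested, key, all)[key[first]])
  out$max_p <- as.numeric(tapply(df$p, key, function(p)
    if (anyNA(p)) NA_real_ else max(p))[key[first]])
  out$site_significant <- as.logical(
    tapply(df$site_significant, key, all)[key[first]])
  rownames(out) <- NULL
  DataFrame(out)
}
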