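---
title: "Quantifying minor-intron retention with boundary-window statistics"
author: "minorsplice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying minor-intron retention with boundary-window statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorsplice)
```

## The problem

Fewer than 0.5% of introns in animal genomes belong to the minor (U12-type)
class, excised by the minor spliceosome (U11, U12, U4atac, U5 and U6atac
snRNAs). When a minor-spliceosome component is lost, these introns are
retained in mature transcripts while the vast majority of (major, U2-type)
introns are spliced normally. Detecting that retention from bulk RNA-seq is a
*local* problem: for each affected gene there is typically one minor intron,
and the question is whether reads accumulate inside it at its splice sites.

`minorsplice` implements the splice-site unusage statistic (SSun) for exactly
this situation, together with the companion analyses such a study needs:
junction-usage quantification for cryptic splice-site activation, RIP-seq
enrichment scoring for snRNA association of a candidate protein, ΔΔCt qPCR
quantification, and concordant multi-genotype differential-expression
filters. A seeded simulator provides ground truth for all of them.

## The SSun statistic

For one splice site of one intron, take the `w`-nt exonic window ending at
the exon/intron boundary and the `w`-nt intronic window starting at it
(default `w = 40`). Count the distinct reads whose *aligned* blocks overlap
each window — a junction-spanning read's alignment gap is not coverage, so a
perfectly spliced read never lands in the intronic window. Then

$$\mathrm{SSun} = \frac{n_{\text{intronic}}}{n_{\text{exonic}}}.$$

A fully used (spliced) site has SSun 0; a fully unused site (complete
retention) has SSun near 1, since both windows then see the same read stream.
Under the simulator's uniform placement model the expected SSun is close to
the retention fraction `r` itself, which is what the monotone-recovery
checks exploit.

Choices worth stating explicitly:

* **Orientation.** The ratio is intronic/exonic, so that *larger SSun means
  more retention*; the literal inverse is available via
  `orientation = "exonic_over_intronic"` for users of the opposite
  convention. Descriptions of this statistic in the literature are ambiguous
  about the ratio's direction while consistently treating "elevated" as
  "retained", and internal consistency wins.
* **Window membership.** A read counts if at least `minOverlap` nt
  (default 1) of one of its blocks lies in the window, at most once per
  window. An unspliced read crossing the boundary therefore counts in both
  windows — intended, as it is direct evidence of unusage. The counting rule
  is pinned by brute-force enumeration oracles in the test suite.
* **Evaluability.** A site/sample record is evaluable only when the
  denominator window has at least `minExonicReads` reads (default 10). No
  pseudocounts, no smoothing: undefined ratios are flagged and excluded, and
  the exclusion is reported. This mirrors how published analyses compute the
  statistic only for adequately covered introns (e.g. 14 evaluable of 19
  annotated minor introns in a fly-ovary dataset).
* **Truncation.** If the intron or flanking exon is shorter than `w`, the
  window is truncated to it and flagged — never silently.

## Group comparison

Per splice site, the mutant genotype is compared with *each* comparator
genotype by an unpaired two-tailed Student's t-test with pooled variance on
the per-replicate SSun values; a site is flagged only when every contrast has
p < α (default 0.05). This mirrors the per-site asterisk convention of
small-n (n = 3) genotype panels. Raw p is the flagging criterion by design;
Benjamini–Hochberg q across sites is reported alongside for each contrast.
Identical constant groups are a legitimate degenerate case here (an
unretained intron gives SSun exactly 0 in every replicate), so the t-test is
implemented to return t = 0, p = 1 for them instead of erroring; it is
cross-checked against `stats::t.test(var.equal = TRUE)` wherever defined.

## Junction usage and cryptic splice sites

Impaired minor splicing can activate cryptic donors/acceptors near the
affected intron. Junctions under test are *declared* (this package does not
do transcriptome-wide discovery): a junction is the genomic interval spliced
out between donor and acceptor, and a read supports it when two consecutive
blocks are separated by exactly that gap. Matching is exact by default
because aligners report precise splice gaps and a tolerance would conflate
neighbouring cryptic sites; `tolerance` is config-exposed for noisy input.
Per replicate, usage = cryptic/(cryptic + normal), with zero-total replicates
flagged unevaluable; genotype contrasts reuse the pooled t-test above.

## RIP-seq enrichment

Counts are normalized (CPM by default; median-of-ratios available), fold
enrichment is `(mean IP + c) / (mean control + c)` with pseudocount
`c = 0.5`, and the p-value is a pooled t-test on `log2(normalized + c)`,
BH-adjusted across features. At n = 3 per arm this is the simplest
defensible model; the statistic, the normalization and the pseudocount are
all arguments, so a count-model engine can replace the default without
touching the interface. All-zero features are reported with fold 1, p 1 and
a flag rather than dropped. CPM makes folds invariant to library scaling
(tested as a property); exact recovery of a noise-free planted factor is a
median-of-ratios property, since a strongly enriched feature perturbs CPM
totals themselves.

## qPCR relative quantification

Relative level = $2^{-(Ct_{target} - \overline{Ct}_{ref})}$ with the
arithmetic mean of the reference-gene Cts — equivalently the geometric mean
of per-reference quantifications (an identity the tests verify). The
amplification efficiency is fixed at 2 per cycle, as no standard curves are
modelled. Missing target Cts drop that sample with a warning; missing
reference Cts are a contract violation and error.

## Differential-expression filters

The decision rule is deliberately separated from the test engine. The
engine (`testFeatures`) is a pooled t-test per contrast on `log2(CPM + 0.5)`
(RNA) or `log2(abundance)` (protein) with BH adjustment within contrast;
any other engine's per-contrast statistics can be fed to `callDE`. The rule:
a feature is `up` (or `down`) only if **every** contrast of mutant versus
each comparator genotype has adjusted p < 0.05 **and** clears the effect
bound — RNA |log2FC| > 0.29, protein FC > 1.43 or < 0.7, all strict
inequalities exactly as printed. The protein bounds are treated as printed,
not symmetrized (1/1.43 ≈ 0.699 ≠ 0.7). Contrasts that are individually
significant but disagree in sign yield `unchanged` with a `discordant` flag.

## The simulator

The simulator's job is ground truth, not realism. It generates:

* **Gene models** — one contig per gene, equal-sized exons/introns, one
  intron per gene carrying the `"minor"` label (the designated, retainable
  intron); strands alternate so minus-strand arithmetic is always exercised.
* **Reads** — fixed-length single-end placements, uniform over the template;
  each molecule retains the designated intron with probability `r`
  (per genotype × gene), otherwise splices, and spliced molecules use a
  cryptic acceptor (`crypticOffset` nt into the downstream exon, default 30)
  with the configured fraction. Reads crossing spliced-out segments carry
  multiple blocks. Output as in-memory block sets, SAM and BED12; the truth
  table records template and junction-spanning counts per sample from
  placement geometry, independently of block construction.
* **Count/abundance/Ct tables** — negative-binomial counts (default
  dispersion 0.05 — a documented default, not a claim about any particular
  library) with per-sample library factors and planted IP/control ratios or
  mutant log2 fold-changes; log-normal protein abundances; Ct tables where a
  planted relative level of 2 appears as one cycle.

Deliberately *not* modelled: sequencing errors, base calls, GC/positional
bias, paired ends, fragment-length distributions, overlapping transcripts,
and alignment itself (the package consumes alignments). Consequently,
passing tests demonstrate the statistics and decision rules are implemented
correctly and recover planted effects under clean placement geometry — they
do not certify behaviour under alignment artefacts or biased coverage.

Determinism is a contract: one integer seed drives every generator, and
identical configurations reproduce outputs bit for bit (tested, including
written files).

## Validation conditions and their sizes

The packaged validation uses problem sizes a laptop CPU handles in minutes,
chosen to match the study design they emulate (four genotypes — mutant, wild
type, heterozygote, rescue — with three replicates):

* SSun parameter recovery: one gene, retention 0/0.1/0.25/0.5/0.9, three
  replicates each, depth 5000, read length 100; mean SSun must increase
  strictly with `r` and be exactly 0 at `r = 0` (no retained templates can
  reach the intronic windows).
* Detection: 14 perturbed genes (r = 0.4 in the mutant vs 0.02 elsewhere)
  against 30 background genes (r = 0.02 everywhere), depth 5000; at least
  13/14 designated introns must have both splice sites flagged against all
  three comparators, and 0/30 background introns.
* Counting oracles: every window and junction count on a ≤10,000-read seeded
  fixture must equal an independent brute-force enumerator exactly.
* RIP: planted 16× and 6× features among 100 background features must land
  in the top 5 by fold enrichment in ≥95% of 200 seeded runs.
* Differential expression: 500 features, 40 planted at |log2FC| = 1, across
  100 seeds, sensitivity ≥ 0.9 with empirical FDR ≤ 0.10. This scenario runs
  at dispersion 0.003 with base means 500–5000: a power analysis of the
  pooled t-test at n = 3 with BH over 500 features shows the stated operating
  point requires within-group log2-scale sd ≈ 0.1, i.e. the low-dispersion
  regime of deeply sequenced, technically dominated replicates. The
  simulator's general-purpose default (0.05) corresponds to noisier
  biological replication, under which a |log2FC| = 0.29 threshold at n = 3
  has little power — which is precisely why the decision rule demands
  concordance across three contrasts.

## Known limitations

* SSun is a local ratio, not an isoform quantification; overlapping
  transcripts are handled by choosing one representative transcript per
  gene, and no EM deconvolution is attempted.
* Intron class labels come from a registry or the user; there is no
  sequence-based (AT–AC/branch-point) classifier.
* The minor-intron registry ships gene symbols and the species census;
  coordinates depend on the annotation release and are supplied by the user
  (placeholder entries are flagged `coordinates_unknown`).
* The default enrichment and DE engines are t-test based; at very low counts
  a count model is more appropriate, and the decision layers accept external
  statistics for exactly that reason.
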