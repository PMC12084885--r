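# minorsplice

Quantify **minor (U12-type) intron retention** from aligned RNA-seq reads.

Fewer than 0.5% of introns are excised by the minor spliceosome (U11, U12,
U4atac, U5, U6atac snRNAs). When minor splicing is impaired — for instance by
loss of a minor-spliceosome protein — these introns stay in mature
transcripts while the bulk of (major) introns splice normally. This package
is for transcriptomics researchers who need to measure that retention per
splice site across a small genotype panel, plus the companion analyses such
a study typically includes: cryptic splice-site usage, RIP-seq enrichment of
protein-associated snRNAs, ΔΔCt qPCR quantification, and concordant
differential-expression filters at RNA and protein level.

## The core statistic

For each splice site of an intron, count distinct reads whose *aligned*
blocks overlap the 40-nt exonic window and the 40-nt intronic window meeting
at the exon/intron boundary (a junction-spanning read's gap is not
coverage), and form the splice-site unusage ratio

```
SSun = n_intronic / n_exonic
```

SSun is 0 at a perfectly used (spliced) site and rises toward 1 with
retention; under uniform read placement it approximates the retention
fraction itself. A site/sample record is evaluable only with at least 10
denominator reads (no pseudocounts — undefined ratios are flagged, not
smoothed). Per site, the mutant genotype is tested against *every*
comparator genotype with an unpaired two-tailed Student's t-test (pooled
variance) on per-replicate SSun values; a site is flagged significant only
when all contrasts have p < 0.05.

Everything is validated against a packaged, seeded simulator that generates
gene models, block-structured aligned reads (SAM/BED12) with controlled
retention and cryptic splicing, and count/abundance/Ct tables with planted
effects, so each stage has exact ground truth.

## Worked example

Simulate a four-genotype study (mutant, wild type, heterozygote, rescue;
three replicates each) where the mutant retains one gene's minor intron at
40% against a 2% baseline, then compute and compare SSun:

```r
library(minorsplice)

models <- simulateGeneModels(nGenes = 2)     # one "minor" intron per gene
cfg <- spliceSimConfig(
  seed = 42, depth = 2000,
  retention = data.frame(genotype = c("mut", "wt", "het", "rescue"),
                         gene_id = "gene01", r = c(0.4, 0.02, 0.02, 0.02)))
sim <- simulateReads(cfg, models)
sim$reads
#> AlignedReadSet: 48000 read(s), 60704 block(s), 12 sample(s)

rec <- computeSSun(sim$reads, boundaryWindows(models, w = 40))
cmp <- compareSSun(rec, sim$design, mutant = "mut")
ssunSignificantSites(cmp)   # gene01 rows:
#>   gene_id intron_index intron_class   site_kind all_tested    max_p site_significant
#> 1  gene01            1        major  five_prime       TRUE 1.00e+00            FALSE
#> 2  gene01            1        major three_prime       TRUE 1.00e+00            FALSE
#> 3  gene01            2        minor  five_prime       TRUE 4.60e-04             TRUE
#> 4  gene01            2        minor three_prime       TRUE 6.18e-06             TRUE
#> 5  gene01            3        major  five_prime       TRUE 1.00e+00            FALSE
#> 6  gene01            3        major three_prime       TRUE 1.00e+00            FALSE
```

Only the designated minor intron (transcription-order index 2) is flagged:
both its splice sites pass p < 0.05 against all three comparators, while the
two major introns — spliced in every genotype — sit at SSun 0 everywhere
(identical groups give t = 0, p = 1 by construction). The per-contrast
detail for the flagged 5' site shows the effect size:

```r
as.data.frame(cmp)[cmp$gene_id == "gene01" & cmp$intron_index == 2 &
                   cmp$site_kind == "five_prime",
                   c("contrast", "mean_mut", "mean_comp", "t", "p")]
#>        contrast mean_mut mean_comp    t        p
#> 7     mut_vs_wt    0.333    0.0172 10.7 0.000440
#> 8    mut_vs_het    0.333    0.0163 10.5 0.000460
#> 9 mut_vs_rescue    0.333    0.0181 10.6 0.000442
```

Mean SSun ≈ 0.33 in the mutant versus ≈ 0.017 at baseline — the read-level
signature of 40% versus 2% intron retention at depth 2000. `demoPipeline()`
runs all stages (SSun, junction usage, RIP enrichment, qPCR, RNA/protein DE
calls) end to end and writes TSV/BED/SAM outputs with provenance headers.

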