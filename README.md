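# apatail

Sample-specific polyadenylation-site prediction and transcript 3'-end
refinement from RNA-Seq.

## The problem

RNA-Seq–based transcriptome assemblies routinely misplace transcript 3'
ends: read-through from precursor mRNA pushes assembled termini past the true
cleavage site, and alternative polyadenylation (APA) isoforms that share
an intron chain but differ in 3' terminus are collapsed. `apatail` refines
the 3' ends of an existing transcriptome ("original transcriptome", e.g. a
StringTie assembly or a reference annotation) using only data the analyst
already has — the genome FASTA, the per-base RNA-Seq coverage, and the GTF —
plus, for training, a set of "true" polyA sites from 3'-end sequencing
(PolyA-Seq style).

## The method

Each transcript's 3' terminal exon is isolated, extended `10000 + 2 * b`
bases downstream (10,200 for the default bin size `b = 100`), trimmed
against same-strand neighbours, and truncated where read coverage drops
below `max(5, 0.05 * D0)` per `b`-base window (`D0` = mean depth at the
annotated stop). The resulting *modified 3' terminal exon* is cut into
`b`-base bins, and every bin is described by 27 features computed from the
bin plus 100 bases of flanking context:

* **4 polyA-signal (PAS) features** — presence (±1) of the canonical
  hexamer AATAAA, the variants ATTAAA and AGTAAA, and a class of minor
  variants, scanned from 35 nt upstream of the bin through its 3' edge
  (a PAS sits ~10–35 nt upstream of a cleavage site);
* **8 sequence-element features** — G-rich, TTT, GT/TG, GTGT/TGTG, and
  T-rich elements downstream of the PAS, T-rich and TGTA/TATA elements
  upstream, and overall AT-richness (±1 at configurable enrichment
  thresholds);
* **14 coverage features** — bounded contrasts `s(a,b) = (a−b)/(a+b+1)`
  and `log1p` differences of median read depth over upstream/middle/
  downstream regions, intra-bin (the window thirds) and inter-bin (the
  neighbouring bins);
* **1 annotation feature** — whether an original transcript's 3' stop
  falls in the bin.

Bin sequences (masked to 300 bins per sequence) are classified by a
bidirectional LSTM — 20 units per direction feeding a per-bin sigmoid —
trained with class-weighted, masked binary cross entropy (weights
`N/(2 N_class)`), the Adam optimizer, a region-level 60/20/20
train/validation/test split, and minimum-validation-loss checkpointing
over 25 epochs. Performance is summarized by precision, recall,
F-measure (`F = 2PR/(P+R)`) at probability 0.5, and average precision
`AP = Σ (R_n − R_{n−1}) P_n` over the descending threshold sweep.

Positive bins become new 3' termini at the bin's 3'-most base, except
where the original stop lies in the bin or within 100 bases; every
accepted site adds a *new* isoform (original transcripts are never
altered or removed), and the modified transcriptome is written as GTF
with predicted transcripts tagged `source_tag "apatail"`.

## Worked example

Everything below runs on a synthetic data set with planted PAS grammar and
staircase coverage (no downloads):

```r
library(apatail)

fx  <- sim_apa_data(sim_config(seed = 42))       # 200 transcripts, 2 chroms
g   <- read_fasta(fx$paths$fasta)
cov <- load_coverage(c(plus = fx$paths$coverage_plus,
                       minus = fx$paths$coverage_minus),
                     stranded = TRUE, chrom_lengths = g$lengths)
txs   <- read_gtf(fx$paths$gtf)
sites <- read_polya_bed(fx$paths$truth_bed)

res <- run_train(g, cov, txs, sites, out_dir = "out")
print(res$model)
#> apa_model (bilstm engine)
#>   features: 27 of 27 (config 2539a7bc); bin 100 bases, 300 bins/seq
#>   sequences: 120 train / 40 val / 40 test
#>   best epoch 15 (val loss 0.0402) of 25
#>   test: P 0.899 R 0.984 F 0.939 AP 0.984

pred <- run_predict(g, cov, txs, res$model, out_gtf = "out/modified.gtf")
benchmark_termini(pred$transcripts, sites, 100)
#> apa_terminus_benchmark (+/-100 bases):
#>   377/390 transcript termini match a true site (PPV 0.967)
#>   369 unique true sites captured; 377/390 unique termini match
```

The model object answers to `summary()`, `plot()` (loss curves), `coef()`
and `predict()`; the held-out test report says how well bins were
classified (`P`/`R`/`F` at the 0.5 threshold, `AP` over all thresholds),
and the terminus benchmark counts how many transcript 3' ends land within
±100 bases of a true polyA site and how many distinct true sites the
transcriptome captures. A command-line front end with `simulate`, `train`,
`predict` (stdin/stdout-pipeable GTF) and `evaluate` subcommands is
installed at `inst/cli/apatail`.

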