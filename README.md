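# riscload

Most sequencing surveys of microRNAs profile the *total* small-RNA pool and
implicitly assume it mirrors the pool of miRNAs loaded into the RNA-induced
silencing complex (RISC) — the Argonaute-containing effector that actually
represses targets. That assumption fails: endogenous miRNAs differ by orders
of magnitude in how strongly they are RISC associated, and it is the
RISC-associated level, not the total level, that predicts a miRNA's
inhibitory potential.

`riscload` implements the analysis that quantifies this, for anyone with a
pair of small-RNA sequencing libraries from the same cells: a **total**
library (all small RNAs ≤ 200 nt) and an **IP** library (RNAs co-purified
with a pan-Ago immunoprecipitation).

## The statistic

Reads are trimmed, length-filtered (≥ 15 nt) and assigned to mature miRNAs
by exact, 0-mismatch substring matching (fractional 1/k weights for
multi-mapping reads). Counts are normalized within each library to percent
of all miRNA-aligned reads, giving shares `s_total(i)` and `s_ip(i)` that
each sum to 100%. The per-miRNA **RISC-association ratio** is

    R_i = s_ip(i) / s_total(i)

Because both share vectors sum to 100%, `R_i = 1` is the "average miRNA";
`R_i > 2` and `R_i < 1/2` define the over- and under-associated classes
(strict inequalities), assessed among miRNAs passing an inclusive 0.1%
expression gate in either pool. Derived quantities include the extreme
spread `max(R)/min(R)`, the implied percent-in-RISC
`100 · R_i / max(R)` (under the assumption that the top miRNA is 100%
RISC-bound), pooled same-seed families (sharing nucleotides 2–8), and
Pearson correlations of reporter repression against RISC versus total
shares.

A second component classifies **non-templated 3′ tails**: reads that fail
to align to any pre-miRNA hairpin are assigned to the mature miRNA whose
full sequence is a prefix of the read (closest length wins), and the 3′
extension is checked against every hairpin capable of generating that
mature; only extensions no hairpin can template are called tails.

Because public accessions for the original libraries are unavailable, the
package ships a synthetic generator (`simulate_reference()`,
`simulate_libraries()`) that emits paired FASTQ libraries with per-read
ground truth — known abundances, loading fractions, tailing rates and an
A/T-rich tail law — so the entire pipeline is validated end to end.

## Worked example

```r
library(riscload)

ref <- simulate_reference(25, shared_fraction = 0.2, seed = 42)
man <- truth_manifest(ref$matures, depth = 50000, seed = 42)
sim <- simulate_libraries(ref, man)
dir <- file.path(tempdir(), "demo")
write_simulation(sim, ref, dir)

res <- run_pipeline(list(
  mature_fa   = file.path(dir, "mature.fa"),
  hairpin_fa  = file.path(dir, "hairpin.fa"),
  fastq_total = file.path(dir, "total.fastq.gz"),
  fastq_ip    = file.path(dir, "ip.fastq.gz"),
  outdir      = file.path(dir, "out")
))

q <- res$quant[res$quant$expressed, ]
head(q[order(-q$ratio), c("mirna_id", "share_total", "share_ip",
                          "ratio", "log2_ratio", "assoc_class")], 5)
#>     mirna_id share_total share_ip  ratio log2_ratio assoc_class
#>  syn-miR-012      47.960   97.159 2.0258      1.019        over
#>  syn-miR-004       0.399    0.212 0.5309     -0.913     average
#>  syn-miR-011       2.606    0.667 0.2560     -1.966       under
#>  syn-miR-007       4.966    1.240 0.2498     -2.001       under
#>  syn-miR-024       2.070    0.122 0.0589     -4.086       under
```

Of the 21 miRNAs detected here, 12 pass the 0.1% gate; 1 is > 2-fold over-
and 10 are > 2-fold under-associated, i.e. 11 of 12 expressed miRNAs are
discrepant between the two libraries:

```r
es <- extreme_spread(res$quant)
sprintf("%.0f-fold spread between %s and %s", es$spread, es$max_id, es$min_id)
#> "236-fold spread between syn-miR-012 and syn-miR-025"
implied_risc_fraction(es$ratio_min, es$ratio_max)
#> 0.4242  # percent of syn-miR-025 in RISC if syn-miR-012 is 100% bound
```

Tail calling on the same run (total pool, well-covered miRNAs):

```r
head(subset(res$tail_summary, pool == "total" & n_reads > 500), 4)
#>     mirna_id  pool n_reads n_tailed pct_tailed
#>  syn-miR-001 total    1634       96      5.875
#>  syn-miR-007 total    2378       15      0.631
#>  syn-miR-009 total   10337      407      3.937
#>  syn-miR-011 total    1265       34      2.688
```

`run_pipeline()` also writes `quant.tsv`, `tails_summary.tsv`,
`tail_composition.tsv`, a log2–log2 `scatter.tsv` and a `stats.json`
embedding the fully resolved configuration.

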