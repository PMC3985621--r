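---
title: "Quantifying differential RISC association of miRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential RISC association of miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscload)
```

## The measurement model

A cell's mature miRNAs partition into a RISC-bound fraction and a free (or
mRNA-bound, non-Ago) fraction. Sequencing the total small-RNA pool measures
the sum; sequencing an Ago immunoprecipitate measures the bound part.
`riscload` models each library as a multinomial sample over miRNA species:
the total library samples species $i$ with probability proportional to its
cellular abundance $a_i$, the IP library with probability proportional to
$a_i L_i$, where $L_i \in (0, 1]$ is the fraction of that miRNA loaded in
RISC.

Within each library, counts are normalized to *percent of miRNA-aligned
reads* — shares $s^{tot}_i$ and $s^{ip}_i$, each summing to 100. The
association ratio

$$R_i = \frac{s^{ip}_i}{s^{tot}_i}
      = L_i \cdot \frac{\sum_j a_j}{\sum_j a_j L_j}$$

therefore estimates the loading fraction up to a single global constant.
Absolute $L_i$ is not identifiable from sequencing alone, which is why the
analysis anchors statements like "x% in RISC" to the assumption that the
most-associated miRNA is fully bound (`implied_risc_fraction()`). Because
both share vectors sum to 100%, $R = 1$ is the natural "average miRNA"
line; we deliberately do not re-center on the mean of log ratios (a
`center = "log_mean"` style correction would move the line with the
composition of the expressed set, making thresholds data-dependent).

Assumptions worth stating explicitly: the IP recovers the Ago-bound pool
without strong sequence bias *relative to the total library* (both
libraries share the ligation chemistry, so sequence-specific ligation bias
largely cancels in the ratio, though it never cancels exactly); and a
read's species assignment is unambiguous at 0 mismatches (enforced by the
matcher, with fractional weights where it is not).

## Read processing and exact matching

Reads are adapter-trimmed, then filtered to ≥ 15 nt (`min_len`, the
shortest insert that still identifies a miRNA reliably at 0 mismatches).
Trimming removes everything from the left-most occurrence of the full 3′
adapter; when the adapter is only partially contained (insert nearly as
long as the read), the longest read suffix equal to an adapter prefix of at
least `min_overlap = 5` nt is removed. Reads with no adapter evidence are
dropped by default (`keep_untrimmed = FALSE`): a genuine short insert must
exhibit the adapter, so an adapterless read is most plausibly junk or an
insert longer than the read.

Alignment is exact substring matching against the mature catalogue —
the 0-mismatch criterion taken literally: no indels, no soft-clipping, and
reads containing `N` match nothing. A read contained in $k$ matures
contributes $1/k$ to each (`weight`), preserving count conservation
(`total_aligned + unaligned` equals the number of input reads exactly).
The index is a hash of all ≥ 15-nt substrings of the catalogue, so each
read resolves in one lookup; correctness is pinned to a naive all-pairs
substring oracle in the test suite, making the index an implementation
detail rather than a semantic choice.

## Quantification choices

* **Expression gate**: share ≥ 0.1% (inclusive), by default in *either*
  pool (`gate_mode = "either_pool"`); `"total"` restricts the gate to the
  total library. Both modes are exposed because the two phrasings of the
  gate in common use differ, and the choice changes which borderline
  species enter downstream counts.
* **Classification**: `over` iff $R > 2$, `under` iff $R < 1/2$, both
  strict; a species exactly on a fold line is `average`. Strictness makes
  the boundary rule reproducible rather than platform-dependent.
* **One-sided detections**: a miRNA seen in only one pool gets a
  pseudocount of 0.5 reads (half the smallest observable count) in the
  empty pool before shares, keeping $\log_2 R$ finite, and is flagged
  `one_pool_only`. Flagged species are excluded from `extreme_spread()`,
  since their ratios are floor artifacts. The floor is deliberately
  scale-bound: rescaling one pool's counts leaves every statistic of
  two-sided detections unchanged (exactly), while pseudocounted species
  shift — the flag marks exactly the rows for which scale invariance
  cannot hold.
* **Families**: same-seed miRNAs (nucleotides 2–8) repress the same
  targets, so reporter assays cannot attribute repression to a single
  member. `pool_families()` sums member shares per pool and recomputes the
  ratio from the pooled shares — a read-weighted aggregate — rather than
  averaging member ratios, which would weight rare members equally with
  abundant ones.
* **Degenerate inputs**: both-pool-zero species are dropped; an empty pool
  is an error (shares undefined); `extreme_spread()` requires at least two
  eligible species.

## Tail calling

The tail classifier asks whether a read's 3′ extension beyond a mature
miRNA could have been templated by genomic (hairpin) sequence; only
untemplatable extensions are tails.

1. A read aligning exactly anywhere in any hairpin is templated by
   definition and can never be tailed.
2. Otherwise the read is assigned to a mature whose *full* sequence is an
   exact prefix — our operationalization of a "discrete 5′ start site",
   the strictest available reading: 5′-shifted isomiRs are deliberately
   left uncalled rather than guessed. Among candidate prefixes, the mature
   of length closest to the read's (the shortest extension) wins; ties —
   only possible between identical sequences catalogued under different
   ids — break lexicographically by id, which makes calls invariant to the
   order of the catalogue.
3. The extension is compared against the sequence immediately 3′ of the
   mature's occurrence in *every* hairpin that can generate it
   (`extension_check = "positional"`). The alternative, accepting the
   extension if it occurs *anywhere* in those hairpins
   (`"anywhere"`), is more conservative about calling tails but lets
   coincidental distal matches veto genuine tails; the positional check is
   the default because templated extension is a positional phenomenon.

Extensions containing `N` are classified `tailed = NA` (undetermined) and
excluded from tailing-percentage denominators: exact matching cannot
adjudicate them either way. The classifier places no upper bound on tail
length; reporting bins tails at 1, 2, 3 and ≥ 4 nt, since observed
non-templated tails are short (≤ 3 nt) and A/T-rich. Matures with no
generating hairpin are excluded as assignment targets (the algorithm has no
context to check against) but remain quantifiable upstream.

Per-miRNA tailing is summarized as `pct_tailed` per pool, compared between
pools as `tail_ratio = pct_total / pct_ip` (values > 1 meaning tailing
enriched in the total pool, as expected if the free pool were
degradation-bound), and per tail sequence as the fold prevalence among
tailed reads in total versus IP.

## Downstream statistics

Pearson correlations use the product-moment estimator with a two-sided
t-transform p-value on $n - 2$ df and no multiple-testing correction (the
analyses involve single planned comparisons). `function_correlation()`
correlates reporter repression against shares on a linear scale by default
— reported correlations of this kind rarely state a transform, so both are
provided (`log2_shares = TRUE` for the log scale) and the package's own
validation uses the log scale, where the heavy-tailed share distribution
does not let single species dominate the estimator. qPCR normalization
divides by a reference miRNA chosen to show neither selective loading nor
exclusion from RISC (so the reference cancels in IP/total contrasts), with
`2^-Ct` linearization when inputs are cycle thresholds.

## What the synthetic generator emulates

`simulate_reference()` builds random matures embedded in hairpins with
≥ 4 nt of 3′ context (20% of matures in two hairpins, exercising the
multi-hairpin check), rejection-sampled so no mature occurs in an
unrelated hairpin, twice in its own, or inside another mature — read-level
truth stays unambiguous by construction. `simulate_libraries()` then draws
the two multinomial libraries under a `truth_manifest()`:

* abundance $a_i \sim \mathrm{LogNormal}(0,\ 2.9)$ — the sdlog is chosen
  analytically so that with ~1000 species roughly
  $P(Z > \sigma/2) \approx 7.5\%$ of them clear the 0.1% gate, the
  expressed-minority structure of real libraries;
* loading fraction $L_i$ log-uniform on $[10^{-3}, 1]$ (three orders of
  magnitude);
* per-miRNA tail rate $t_i$ log-uniform on $[0.002, 0.2]$, spanning the
  observed sub-0.3% to >20% range, with tail bases drawn A 0.4 / T 0.4 /
  C 0.15 / G 0.05;
* templated 3′-extension isomiRs at rate 0.05 and ±1 nt 5′ jitter at rate
  0.02 (neither rate is published; both are declared generator defaults);
* reads are insert + the Illumina TruSeq small-RNA 3′ adapter
  (`TGGAATTCTCGGGTGCCAAGG`), depth $10^5$ per pool, one RNG stream per
  pool derived from the manifest seed so pools are independently
  reproducible and outputs are byte-identical under a fixed seed.

The generator resamples a tail's first base whenever it would coincide
with the templated continuation of any generating hairpin, so a
truth-tailed read is never explainable as templated; the count of avoided
collisions is returned rather than silently discarded.

What it does **not** emulate: sequencing error (an exact-match pipeline
would simply discard erroneous reads, so error injection only dilutes
depth), ligation bias (a caveat of the assay, not a step of the analysis),
5′ isomiRs beyond ±1 nt, cross-mapping between near-identical paralogs
(synthetic matures are mutually non-contained, real families are not), and
any dependence between $a_i$, $L_i$ and $t_i$. Passing tests on synthetic
data therefore validate the *computational* chain — trimming, matching,
normalization, ratio recovery, tail logic — not the biochemical
assumptions of the assay.

## Validation scales and numerical notes

The end-to-end recovery checks run at 60 miRNAs × $10^5$ reads per pool,
with loading fractions fixed on a $10^{-3}$–$1$ grid: large enough that
every ratio has meaningful binomial error bars, small enough that each
species is well covered. Estimated ratios are required to sit within 3
delta-method binomial standard errors of
$L_i \sum a / \sum a L$ (on the log scale,
$\mathrm{SE} \approx \sqrt{1/c_{ip} + 1/c_{tot}}$), for species with ≥ 5
reads in both pools — below that the normal approximation is
uninformative. Ratio-recovery runs disable 3′ modification and jitter so
the closed-form expectation holds exactly; with modifications on, a
miRNA's modified reads drop out of the exact matcher identically in both
pools, leaving ratios unbiased but shifting the global normalizer. The
correlation-contrast check assigns abundance and loading independently on
moderate grids so every species is detected in both pools — detection
filtering would otherwise couple $a_i$ and $L_i$ and confound the
RISC-versus-total comparison. Tail-flag recovery is exact by construction
on non-jittered reads and is asserted as such.

## Known limitations

* Substring (rather than full-length or 5′-anchored) matching for
  quantification means a templated-extension isomiR read is *unaligned* to
  the mature catalogue and drops out of counts, as any 0-mismatch
  end-to-end aligner-based pipeline would drop it.
* Tail calls on reads from near-identical paralogs inherit the prefix
  rule's tie-breaks; with real miRBase catalogues, family members that are
  strict prefixes of one another resolve to the longest prefix, which is
  the minimal-extension reading but not the only defensible one.
* The implied-percent-in-RISC calculation is an upper-anchored
  extrapolation, exact only if the reference miRNA is truly 100% bound.
* Pearson correlations on linear shares are sensitive to the heavy tail of
  share distributions; prefer `log2_shares = TRUE` when a few species
  dominate.
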