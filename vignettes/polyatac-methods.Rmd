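---
title: "polyatac: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyatac: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters with
their defaults and units, what the synthetic-data generator does and does
not emulate, the numerical choices, and the known limitations.  It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Coordinates and the data model

Everything inside the package is 0-based half-open (BED convention); GFF3
input (1-based inclusive) is converted at the reader boundary and
reproduced exactly on write.  The atomic event is the Tn5 *tag*: one
insertion with a strand-specific 5' cut coordinate (`start` for `+`,
`end - 1` for `-`).  Fragments (BEDPE) are the paired view; each fragment
contributes two tags.  Organelle chromosomes — recognised by a
configurable name regex, default `"Mt|Pt"` case-insensitive — are tracked
because organelle DNA is nucleosome-free, is cut indiscriminately by Tn5,
and must be excluded from background-rate estimation and peak calling.

## Read processing

Filtering drops tags with `mapq < mapq_min` (default 5, i.e. "MAPQ < 5
removed"; the threshold is strict, so MAPQ 5 is kept) and tags on unknown
chromosomes.  Duplicates are tags sharing (chromosome, strand, 5' cut):
the key a position-and-strand duplicate marker uses.  For fragment-derived
input a flag switches to full-interval keys.  Library complexity follows
the ENCODE definitions on the pre-deduplication multiset:
`NRF = distinct/total`, `PBC1 = m1/distinct`, `PBC2 = m1/m2` (reported as
`Inf` when no position occurs exactly twice) — the source workflow names
"library complexity" as a metric without formulas, and its QC battery is
explicitly modelled on the ENCODE pipeline, so the ENCODE definitions are
adopted.

## Signal tracks

The pileup gives each cut site a unit-mass window of `extsize` bp placed
`shift` bp from the cut in read orientation; the defaults
(`shift = -75`, `extsize = 150`) centre a 150 bp window on every cut, the
standard single-end smoothing for ATAC-seq where the insertion point — not
the fragment — is the signal.  `-` strand windows are mirror images, so
both strands centre the same window on the cut.  With SPMR the track is
divided by (library size / 10^6); total mass is then exactly
`extsize * 1e6` absent end-clipping (a tested conservation law).

*TSS enrichment* has no universal formula; the ENCODE-style
flank-normalised maximum is used: aggregate the strand-oriented signal
over ±1000 bp of every TSS, divide by the mean of the two outer 100 bp
flanks, smooth with a 51 bp moving average, report the maximum.  A flat
track scores exactly 1 — a useful calibration point that the tests
assert.  *Track correlation* tiles the genome into fixed bins (default
10 kb, the common summary-bin default; it is a parameter because the
choice is not derivable from first principles) and computes Pearson r of
per-bin means; r > 0.8 is conventionally read as good replicate
agreement.  *Metagene matrices* follow scale-regions semantics: upstream
and downstream flanks (3000 bp each) at native 10 bp bins, gene body
linearly rescaled to 5000 bp, `-` strand rows reversed, all-zero rows
dropped when `skip_zeros`.

## Peak calling

The caller reproduces the semantics of local-background Poisson peak
detection with `--nomodel` smoothing:

* background rate `lambda_BG = n_tags * extsize / L` with `L` the
  non-organelle genome length (no mappability track is in scope);
* local rate per base: `lambda_local = max(lambda_BG, mean pileup in a
  sliding 10 kb window)`.  A single window size (configurable) replaces
  the 1k/5k/10k cascade of the reference caller: the source fixes no
  window, and one window keeps the independent brute-force oracle exact
  and tractable while preserving the local-background behaviour;
* per-base p-value `P(X >= k)` with `k` the pileup, computed by
  `ppois(k - 1, lambda, lower.tail = FALSE)` (exact: at `k = 1` it is
  bit-identical to `1 - exp(-lambda)`);
* Benjamini–Hochberg over **all** scored positions, significant positions
  (`q <= 0.05` by default; the source does not state its cutoff, so the
  caller default is exposed) merged across gaps ≤ 30 bp, peaks shorter
  than `extsize` dropped, summit = leftmost pileup maximum
  (determinism), peak p/q/fold-enrichment reported at the summit.

The acceptance suite proves the caller equal to a per-base brute-force
oracle (direct counting, naive window means, hand-rolled BH, term-by-term
Poisson tails) on 20 random toy instances.

## Reproducibility (IDR)

Matched peak pairs (≥ 1 bp overlap, one-to-one by best mutual overlap,
ties to the higher-scoring partner; unmatched peaks are excluded from the
fit and reported) contribute score pairs ranked by −log10 p.  Mid-ranks
are mapped to uniform quantiles and then through the inverse of the
fitted marginal mixture CDF to pseudo-values `z`.  The pair model is a
two-component copula mixture: with probability `pi` bivariate normal
(mean `mu`, sd `sigma`, correlation `rho`); otherwise independent
standard normal.  EM alternates with pseudo-value refreshes (inner EM is
monotone at fixed pseudo-values; the outer loop stops when parameters
move < 5e-3, which is below their sampling error at the n where the fit
is trusted).  Local idr = posterior probability of the null; global
IDR(i) = running mean of the i smallest local idrs (monotone by
construction, asserted per fit).

Three robustness devices, all package design choices:

* **Degeneracy guard.** On data with no reproducible component the EM
  drifts onto an identifiability ridge (`rho -> 0`, components merge,
  `pi` arbitrary).  The fitted copula is then indistinguishable from
  independence, which a copula likelihood-ratio statistic detects (the
  independence model has copula log-likelihood exactly 0; threshold:
  chi-square(4) at 99%).  Below threshold the fit is declared signal-free:
  `pi = 0`, every pair irreproducible.
* **Restarts.** The EM runs from three starts and the best fit by that
  same LRT is kept.
* **Variance floor.** `sigma >= 0.1` blocks point-mass collapse of the
  reproducible component.

Known limitation: when essentially *every* matched pair is reproducible
and peak strengths are homogeneous (small matched sets from very clean
replicates), the rank-based fit has no null subpopulation to anchor the
null component and underestimates `pi`, passing only the top ranks.  The
reference implementation pads unmatched peaks at worst rank, which
manufactures that anchor; here unmatched peaks are excluded by contract.
The ENCODE optimal-set rule compensates operationally (below).

The consistent-peak procedure runs three analyses with the recommended
cutoffs — true replicates at 0.05, self-pseudo-replicates (random
half-splits of each library) at 0.02, pooled pseudo-replicates at 0.01 —
and takes the top `max(N_t, N_p)` pooled peaks by score (the "optimal"
set; `--conservative` gives `N_t`).  Whether a published final set is
optimal or conservative is generally unstated; optimal is the default
because the rescue by pooled pseudo-replication is the point of the
three-stage design.  Rescue and self-consistency ratios outside [0.5, 2]
are flagged as replicate imbalance.

## QC metrics

*FRiP* counts cut sites inside merged peaks (a flag switches to
fragment-overlap counting); merging first makes it invariant to how a
region is split into abutting peaks.  *SPOT* tiles the genome into 250 bp
windows and tests each against a binomial local background: of the tags
in the surrounding 50 kb, each falls in the focal window with probability
`w/W`, so `z = (obs − exp)/sqrt(exp(1 − w/W))`; windows with `z >= 2` are
hotspots and SPOT is the tag fraction inside them.  The three constants
are Hotspot-style conventions (none are given in the source) and all are
configurable.  *Fragment-length profiles* report the 1–1000 bp histogram,
the NFR (< 100 bp) and mono-nucleosome (180–247 bp) band fractions
(common ATAC conventions; the bands are visible in gel/histogram figures
but no boundaries are printed), and a periodicity score: the maximum
autocorrelation of the detrended histogram in the 150–230 bp lag band,
clamped to [0, 1] — high values indicate the ~190 bp nucleosome repeat of
properly tagmented chromatin.

## Saturation

Observed fractions 10%…100% are drawn by binomial thinning (O(1) memory;
an exact mode exists), peaks are called per depth, and
`N(f) = Vmax·f/(K + f)` is fitted by `nls` with an `optim` fallback for
degenerate (near-constant) counts.  The Michaelis–Menten form and the 1%
marginal-gain stopping rule are this package's explicit stand-in for the
unpublished internals of the plotting function the source cites; both the
form and the threshold are config options, and the fit is validated by
parameter recovery (Vmax within 10%, K within 15% at 2% noise).  The
saturation fraction `f*` is the smallest grid fraction (grid extends
virtually to 200%) where the relative gain per 10% step drops below 1%;
`f* > 1` is flagged "not saturated at observed depth", and `f*` is also
reported in gigabases when the full-library yield is supplied.

## Annotation

The promoter is `[TSS − 4000, TSS + 1500]` in gene orientation, closed at
both ends ("within 4 kb" is read as inclusive).  Categories are assigned
with promoter precedence — the +1.5 kb limb overlaps the gene body, and
precedence is the only reading that keeps the stated window meaningful
when the categories must be disjoint.  The nearest gene is chosen by
absolute summit-to-TSS distance (ties to the lexicographically smaller
gene id, for determinism); a summit between two genes is anchored to the
nearest TSS, which also decides whether it is "upstream" or "downstream"
intergenic.  Boundary exactness (category changes at exactly TSS−4000,
TSS+1501, TES+1 on both strands) and strand-mirror invariance are tested
exhaustively.  Genes with ≥ 1 summit in the promoter window are labelled
accessibility-related; the per-gene counts feed the expression join,
which groups genes by promoter-peak count (0/1/2/≥3) and emits per-group
medians and quartiles — the statistical comparison itself is left to
downstream tools by design.

## The simulator: a stated world

`sim_config()` defaults *are* the world the tests assume; none of them is
tuned against test outcomes:

* genome 2 × 2 Mb nuclear + 100 kb "chrMt" — large enough for ~200
  non-colliding promoter windows, small enough for the full pipeline on
  one CPU in minutes;
* 200 genes, lengths U(1500, 4000) bp, placed on a jittered grid with
  ≥ 12 kb between spans so promoter windows never collide;
* one truth peak (300 bp) per promoter, centred uniformly within
  [TSS−3000, TSS+1000] in gene orientation; optional distal peaks
  (default 0, so the default truth count is exactly 200);
* per-peak lognormal intensity weights (sdlog 1).  This field goes beyond
  the original configuration sketch for a structural reason: with
  equal-strength peaks, replicate score ranks are pure sampling noise and
  carry no reproducibility signal, so rank-based IDR is (correctly)
  degenerate on such data.  Real accessibility peaks span roughly two
  orders of magnitude; the weights are part of the world and shared
  across replicates;
* in-peak cut-site fraction α = 0.4; fragment lengths from the
  nucleosome mixture 0.55·N(75,15) + 0.35·N(265,20) + 0.10·N(460,25)
  truncated to [20, 1000];
* duplicate rate 0.10 (a typical well-made library) and organelle
  contamination 0.05 (the reported contamination of a well-prepared wheat
  library) — the two values the configuration sketch left open;
* 200,000 fragments → 400,000 tags per library; expression
  `TPM = exp(1.5 · promoter-peak indicator + N(0,1))`.

What the generator does **not** emulate: sequence (coordinates only, no
FASTA/FASTQ), mappability structure and homoeologous-subgenome ambiguity,
per-position Tn5 sequence bias, chromosome-scale coverage waves, and
fragment-level strand asymmetries.  A green end-to-end test therefore
establishes that the *algorithms* recover a known truth under realistic
count statistics — not that any biological conclusion about real wheat
data is reproduced.

Determinism: every stochastic operation draws inside `with_seed()`, so
nothing touches the caller's RNG state, identical seeds give
byte-identical output files, and sub-seeds are derived arithmetically
from one master seed.

## Numerical choices

* Poisson tails via R's incomplete-gamma `ppois` (upper tail), exact at
  `k = 1`; the acceptance oracle is an independent term-by-term summation.
* BH over all genome positions in one pass; peaks report −log10 p/q
  floored at the smallest positive double.
* Summit ties broken leftmost; gene ties broken by id; both for
  determinism.
* Pipeline TSV output fixed at 6 significant digits, making re-runs
  byte-identical.
* `fit_idr` requires ≥ 50 matched pairs (stages with fewer are skipped
  and flagged) — below that the four-parameter copula fit is not
  trustworthy.

## Known limitations

* Exactly two true replicates; the pairwise-best extension to more is
  noted but unimplemented.
* No control-lane subtraction, broad-peak mode, or fragment-model
  building (`--nomodel` semantics only, as in the workflow this package
  operationalises).
* bedGraph, not bigWig, is the native track output; binary conversion is
  delegated to external tools.
* The IDR small-n/homogeneous-strength caveat described above.
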