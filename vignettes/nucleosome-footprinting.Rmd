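---
title: "Single-molecule nucleosome footprinting: models, decoder, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule nucleosome footprinting: models, decoder, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nucfoot` reconstructs nucleosome positions and chromatin accessibility on
individual DNA molecules from methyltransferase footprinting read out by
nanopore sequencing. An exogenous GpC methyltransferase (M.CviPI) methylates
accessible cytosines in GpC dinucleotides; DNA wrapped in a nucleosome is
protected. After sequencing, the per-event current levels carry the
methylation signal, so each long read is a single-cell, single-molecule
snapshot of chromatin: methylated (high-score) GpC sites mark linkers and
open regulatory regions, unmethylated (low-score) sites mark
nucleosome-protected DNA. In organisms without endogenous CpG-context
confounders (the method was developed in budding yeast), this gives direct
joint observations of nucleosome phasing and promoter state per cell.

This vignette is the package's methods account: the signal models, the
decoding dynamic program, the accessibility rules, the downstream
statistics, the simulation framework, and the numerical and design choices
behind each.

# Per-6-mer signal models and the methylation score

The nanopore current of an event depends on the ~6-mer occupying the pore,
so all models are trained per 6-mer, restricted to 6-mers containing a GpC.
Two class-conditional event-level densities are fitted per 6-mer `k`:

* unmethylated (negative control, no methyltransferase):
  `f_N(x; k) = N(mu0, sigma0^2)`, estimated by the sample mean and the
  unbiased (n−1) sample variance;
* methylated (positive control, purified DNA treated at near-complete
  efficiency): a two-component Gaussian mixture
  `f_P(x; k) = rho N(mu1, sigma1^2) + (1 - rho) N(mu2, sigma2^2)`. The
  second component absorbs the residual unconverted fraction — measured
  bisulfite efficiency of a positive control is high but not perfect
  (`methylation_efficiency(53, 3, 1)` = 99.37%) — so a single Gaussian
  would be misspecified.

The mixture is fitted by EM (`fit_positive_model()`): initialization puts
the component means at the 25th/75th percentiles with a shared variance;
convergence is declared when the observed-data log-likelihood improves by
less than `1e-6` (it is monotone along the iterations, which the tests
assert); `max_iter = 500`; a component variance collapsing below `1e-3` pA
triggers up to 3 jittered restarts before the 6-mer is marked untrained.
Components are reordered so `mu1 >= mu2`, making fits deterministic up to
the seed.

The *discrimination* of a 6-mer is `1 -` the overlap area of `f_N` and
`f_P`, computed by the trapezoid rule on 4001 points spanning
`[min(mu) - 6 max(sigma), max(mu) + 6 max(sigma)]` over all three
components and clipped to `[0, 1]`. For two equal-variance Gaussians a
separation of 6 SD gives `1 - 2 * pnorm(-3) = 0.9973`, which the tests use
as a closed-form anchor.

Scoring a GpC site on one molecule (`select_kmer()`,
`methylation_score()`):

1. enumerate the six reference 6-mers covering the site's cytosine;
2. exclude any containing more than one GpC (its signal mixes two sites'
   methylation states), any with more than 10 event levels aligned from
   this molecule (a sign of noisy alignment), and any untrained 6-mer
   (treated exactly like an excluded one — the training data simply has
   nothing to say about it);
3. keep the survivor with maximal discrimination, ties going to the
   leftmost 6-mer start;
4. drop each aligned event whose log-likelihood under either class model is
   below −10 (natural log — both choices are this package's, stated here
   because "log" alone is ambiguous); if all events are dropped the site is
   *filtered* (reported with an `NA` score);
5. the methylation score is the flat-prior posterior
   `s = prod f_P / (prod f_P + prod f_N)` over the retained events,
   evaluated in log space.

GpC is its own reverse complement, so forward- and reverse-strand molecules
interrogate the same dinucleotides but through opposite-strand 6-mer
contexts; the two strand groups are therefore trained, scored, and peak-
called separately throughout, and merged only by explicit intersection
(`concordant_peaks()`). A consequence used by `gpc_sites()`: on a reverse
molecule the methylated C faces the forward-strand G, one base left of the
forward C.

Overlapping sites such as `GCGC` count as two independent sites; 6-mers
covering both are excluded by the >1-GpC rule, so such sites are scored
only through flanking contexts that see exactly one of them.

# The nucleosome decoder

Each base of a molecule is in one of 148 states: linker `L` or `N_m`, the
m-th base of a 147-bp nucleosome. Transitions are rigid: `N_m -> N_{m+1}`,
`N_147 -> L`, `L -> {L, N_1}` — a nucleosome, once entered, must run its
full 147 bp (unless the molecule ends first), and two nucleosomes are
separated by at least one linker base. Emissions live only on called GpC
sites: a linker base emits `q_P(s)`, a nucleosomal base `q_N(s)`, where
`q_P`/`q_N` are the methylation-score densities of the methylated/
unmethylated classes; every other base carries an implicit dummy score and
emits factor 1. The decoder (`decode()`) returns the joint
maximum-likelihood state path by a Viterbi-style dynamic program over an
`l x 148` table, in natural-log space throughout.

Score densities (`fit_score_densities()`) are Gaussian-kernel KDEs with the
rule-of-thumb bandwidth (the `stats::density()` default), evaluated on a
512-point grid over `[-0.05, 1.05]` and floored at `1e-8` so logs stay
finite; scores are interpolated linearly on the grid. Each floored curve
still integrates to 1 within 1%.

Numerical and structural choices that the recursion itself does not fix:

* **Linker entry.** The linker column is entered from the previous linker
  or from `N_147` — the last nucleosomal state — matching the transition
  grammar. (A literal reading of writing the recursion over a 148-column
  table can suggest entering from column 147 = `N_146`; that conflicts
  with the grammar, and the grammar wins here.)
* **Boundary handling.** Paths may start and end mid-nucleosome: row 1 is
  initialized in every state, and the terminal maximum is taken over the
  whole last row. Boundary-truncated nucleosomes are emitted clipped to
  the molecule span with `truncated_start`/`truncated_end` flags;
  `complete_only = TRUE` drops them. Complete calls are exactly 147 bp by
  construction.
* **Tie-breaking.** Ties are resolved deterministically, preferring `L`
  over nucleosomal states and lower nucleosome index over higher, applied
  from the molecule end backwards. This makes the decoded path unique and
  reproducible.
* **Zero-site molecules.** With no called GpC site every path has
  likelihood 1; the all-linker path with log-likelihood 0 is returned by
  convention.

`brute_force_decode()` is an independent correctness oracle: it enumerates
every transition-valid nucleosome placement (compiled recursion; up to
~10^6 placements at 600 bp) under the same tie-break order. Both routes
accumulate site emissions strictly left-to-right, so the test suite can
require the two log-likelihoods to be *bit-identical*, not merely close;
the suite checks path identity on hundreds (the acceptance suite: 1000) of
random molecules.

The Viterbi path maximizes the joint path likelihood, not per-base
posterior accuracy; this is a deliberate scope choice (single argmax path,
no posterior or sampling decoders).

# Accessibility calling

All rules operate on called sites only — filtered and uncalled sites are
invisible, and "adjacent" always means consecutive called sites.

* **Single-molecule accessible regions**
  (`molecule_accessible_regions()`): two adjacent sites qualify when both
  scores exceed 0.5 (strict) and their distance is below 100 bp (strict);
  chains sharing a site merge; merged regions shorter than 100 bp
  (inclusive threshold on `end - start` over the flanking C positions) are
  dropped. The region score is the median score of all sites it contains,
  flanking sites included.
* **Bulk peaks** (`bulk_peaks()`): per site, `r` = fraction of covering
  molecules with score > 0.5 among molecules contributing a called score
  (coverage proxy `M`); sites with `M >= min_cov` (default 5 — a choice
  this package had to make) enter; the pairing threshold is
  `1.5 * rbar` with `rbar` the mean `r` over participating sites of the
  strand group. Geometry rules are identical to the single-molecule case.
  `rbar` is computed per strand by default, matching the separate
  strand-group peak calling; the forward/reverse peak intersection gives
  strand-concordant peaks.
* **Promoters** (`define_promoter()`): the search window is
  "−500, +100" around the TSS *oriented by gene strand* (the
  `unstranded` switch reproduces a strand-naive reading). One overlapping
  peak: that peak. Several: longest overlap, ties to the peak nearer the
  TSS. None: the window itself. The function accepts any merged peak set
  and stays agnostic about its provenance.
* **Promoter status** (`call_promoter_status()`): on molecules fully
  covering the promoter, the median site score inside it; open iff
  strictly above 0.5 (a median of exactly 0.5 is closed). Zero contained
  sites is a no-call. Site containment for medians is inclusive of both
  interval endpoints, consistent with region scoring. `bulk_openness()` is
  the open fraction among called molecules;
  `differential_accessibility()` their condition difference (A − B).

# Downstream statistics

* `plus_one_distance()`: the +1 nucleosome is the one whose center is
  downstream of and closest to the TSS; a center exactly at the TSS counts
  as downstream. `positioning_heterogeneity()` drops the top
  `floor(0.1 n)` distances and returns the unbiased SD of the rest (SD, so
  the statistic is in bp), requiring at least 10 cells.
* `spacing_uniformity()`: mean absolute pairwise deviation of the linker
  lengths within the −500/+100 window; linkers partially overlapping the
  window are clipped to it by default (`clip = FALSE` takes whole
  overlapping linkers).
* `score_autocorrelation()`: all within-molecule site pairs, binned by
  distance, Pearson correlation per bin pooled over molecules, both pair
  orders included so the statistic is symmetric; bins with fewer than 100
  pairs are reported missing. Raw scores are used rather than binarized
  status — the correlogram's periodicity (repeat length = 147 bp + mean
  linker) is the point, and binarization only discards information.
* `cluster_openness()`: per-base occupancy vectors binned to 10-bp means,
  k-means (default k = 3 — closed / narrow open / wide open — with 20
  restarts and a fixed seed), clusters relabeled by decreasing openness.
* `combinatorial_patterns()` tabulates joint open/closed promoter patterns
  over molecules covering all listed genes (`2^n` possible);
  `nucleosomes_per_molecule()` summarizes complete-call counts.
* Expression-based gene stratification (silent / active) is accepted as
  input labels only; expression quantification is out of scope.

# The simulation framework

`simulate_layout()` builds a molecule as alternating linkers and 147-bp
nucleosomes, starting with a linker (the first element is otherwise
arbitrary; starting protected would bias boundary truth). Linker lengths
are drawn from `N(nu1, gamma1^2)` with probability `tau` and
`N(nu2, gamma2^2)` with probability `1 - tau`, rounded to integers and
truncated below at 0; the final nucleosome is clipped at the molecule end
and the clipping carried into the truth labels. The defaults are the study
conditions: 3000-bp molecules, `gpc_freq = 0.0375`, `nu1 = 15`,
`gamma1 = 5`, `gamma2 = 10`, `tau = 0.1`, with `nu2` swept over
{15, 50, 100, 200, 300, 400, 500, 600} to move nucleosome coverage across
roughly 21–91% (`nu2 = 100` is the single-molecule default). Note the
mixture weighting as specified makes the *long*-linker component dominant
(`tau` weights the regular-array component); it is implemented exactly as
stated because the resulting coverage range is the one the sweep needs.

`simulate_scores()` places GpC sites by independent per-base Bernoulli
draws and assigns each site a score from its true class's distribution.
The default class-conditional score model is a mirrored Beta pair:
linker sites `Beta(c, 1)`, nucleosomal sites `Beta(1, c)` with
`c = 2.1486`. The shape was fixed once, by root-finding, so that the
two-class single-site AUC equals 0.86 — anchoring the synthetic score
noise to realistic nanopore 5mC-detection performance — and is not a
tuning knob; the package's calibration check re-verifies the AUC by a
large seeded rank statistic. Alternatively scores can be drawn from fitted
`score_density` objects (grid draw plus sub-grid jitter).

`accuracy_grid()` simulates `reps` molecules per (frequency, `nu2`) cell,
decodes each with the simulation's own densities, and averages the
per-base accuracy `A` = fraction of bases whose in-nucleosome indicator
matches the truth. The packaged acceptance run uses 200 replicates per
cell (1600 molecules over the 8-cell sweep, about a minute of CPU); the
per-cell means are stable to ~0.004 at that depth.

What the simulator emulates and what it does not: it reproduces the layout
statistics, site placement, and class-conditional score noise of the
footprinting readout, which is what the decoder consumes. It does not
simulate raw squiggles, base-calling or alignment error, coverage bias,
chimeric reads, or methyltransferase sequence preference. Passing tests on
synthetic molecules therefore validate the decoding and rule logic under
the stated noise model — not end-to-end performance on any particular
sequencing run.

Two empirical notes the test suite encodes:

* Decoded accuracy under these conditions clears 80% in the low-coverage
  cells but sits at ~78–80% in the highest-coverage cells
  (`nu2 <= 100`). The decoder is exact-MAP (oracle-verified) and decodes
  with the exact generating densities, so this ceiling is a property of
  the smooth Beta score model: a real score distribution with the same
  single-site AUC but more mass near 0 and 1 carries more per-site
  information and decodes better. The acceptance test states the 80%
  bound for every cell and is allowed to fail honestly on those cells
  rather than the calibration being revisited.
* The closed-form coverage `147 / (147 + tau nu1 + (1 - tau) nu2)` is an
  asymptotic renewal statement. On 3-kb molecules the leading linker and
  the clipped tail depress realized coverage by a few percent (and the
  truncation of negative linker draws at 0 inflates the effective mean
  linker when `nu2` is small relative to `gamma2`), so the consistency
  check runs on 50-kb molecules at the default `nu2 = 100`, where both
  boundary terms are negligible against sampling error.

# Interfaces

Coordinates are 0-based half-open internally and in every file written
(BED, bedGraph, TSV; "." for missing). Event-alignment input follows the
`nanopolish eventalign` TSV dialect; reference sequence comes from FASTA;
gene annotation from 6-column BED with strand-aware TSS. The `exec/nucfoot`
script exposes the pipeline as subcommands (`train`, `score`,
`nucleosomes`, `access`, `peaks`, `promoters`, `metrics`, `simulate`,
`evaluate`); every subcommand writes a run manifest (package version,
configuration hash, seed), and identical seeds plus flags give
byte-identical outputs.

# Known limitations

* The decoder fixes the nucleosome footprint at exactly 147 bp;
  sub-nucleosomal particles and over-wound footprints are forced into
  linker or full-nucleosome calls.
* KDE emission densities are global, not position- or context-specific;
  6-mers with low discrimination contribute noisy scores that the decoder
  weighs like any other.
* Bulk peak calling uses the molecule count with called scores as the
  coverage proxy; heavily filtered sites are under-covered rather than
  missing.
* The simulation's score model is a calibrated stand-in (see above); use
  `score_model = "densities"` with densities fitted from real control
  scores when such data is available.
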