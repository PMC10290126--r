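---
title: "Methods: models, parameters and design choices in calciproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in calciproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciproteo)
```

# The problem

Coccolithophores such as *Emiliania huxleyi* precipitate intricately
patterned CaCO~3~ scales (coccoliths) inside a Golgi-derived coccolith
vesicle (CV) and exocytose them to form the coccosphere. The proteins
controlling nucleation and morphogenesis of the calcite are largely
unknown, and many are expected to be young, low-complexity, disordered
and compositionally biased — exactly the sequences that ordinary gene
prediction and database searching handle worst. `calciproteo`
implements the downstream computational machinery of a proteogenomic
candidate-discovery workflow around that problem: evolutionary age
assignment of gene families, quality metrics for the search database,
sequence-property scanning, quantitative differential abundance, and
rule-based candidate filters combined across orthogonal experiments.

This vignette records the models, the parameters that matter, and the
choices made where the design was genuinely open.

# Phylostratigraphy

## Origin model

Orthogroups (gene families inferred across a species panel) are placed
on a rooted, user-supplied guide tree whose internal nodes name
phylostrata. We assume **single-gain parsimony**: an orthogroup arises
exactly once, and its origin is the last common ancestor (LCA) of the
species in which it is observed. Convergent gain is not modelled.
Under this model lineage-specific losses can only make a family look
*younger* (the observed LCA is always a descendant-or-equal of the true
origin), never older; `run_demo()` checks exactly this property against
planted truth, and the test suite checks `assign_origin()` against a
brute-force path-intersection LCA on random trees.

Species present in the tree but absent from the orthogroup table are
treated as genuine absences. For transcriptome-only species, absence
may instead reflect sampling; we deliberately do not reweight for this
(there is no principled correction without expression data) and rely on
the guide tree's breadth instead.

## Loss detection

A family counts as *lost* in lineage `l` (e.g. a non-calcifying
relative) when (i) the focal species retains it, (ii) `l` lacks it, and
(iii) its origin lies on the path between a user-chosen minimum-age
node and the LCA of `l` and the focal species — i.e. the family is old
enough that `l` descends from its origin, so absence is loss rather
than never-present. Families at or below Calcihaptophycidae age that
are retained by calcifiers but lost in non-calcifying lineages are the
prime candidates this stage exists to surface.

## Domain enrichment

Within each stratum, Pfam-style domains are tested for
over-representation with the upper-tail hypergeometric
$P(X \ge k \mid N, K, n)$ where the urn is over *proteins*: a protein
carrying several copies of a domain counts once, avoiding
repeat-domain inflation. Only hits with i-Evalue $< 10^{-3}$ enter.
With at least 50 tested domains, enrichment is called by a local
false-discovery estimate: $\widehat{\pi}_0$ from the flat tail of the
p-value histogram ($\lambda = 0.5$), density by a 20-bin histogram,
$\mathrm{lfdr} = \widehat{\pi}_0 / \widehat{f}(p)$ capped at 1 and made
monotone in $p$; the threshold is lfdr $< 0.05$. Below 50 tests the
histogram is too coarse to trust, and the code falls back to BH
$q < 0.05$ with a logged notice. The exact truncated q-value variant
used historically for this kind of analysis is not fully specified
anywhere we could verify, so our rule is documented here as an
interpretation and isolated in one internal function.

# Sequence properties

## Low complexity

`seg_mask()` is a Wootton–Federhen-style segmentation: Shannon entropy
(bits) of every length-12 window, seeds at $K_2 \le 2.2$, extension
across adjacent windows at $K_2 \le 2.5$, maximal runs reported as
0-based half-open intervals. The 12/2.2/2.5 defaults are the canonical
ones; they are configurable because no single parameterization is
standard across studies. `X` residues are excluded from both the counts
and the denominator. An exhaustive all-windows oracle reproduces the
masked fraction on hundreds of random sequences in the tests, and the
fraction is invariant under sequence reversal.

## Disorder

A trained disorder predictor is deliberately **not** re-implemented.
The pipeline consumes only the *disordered fraction*, and only for
comparing distributions between strata, so a transparent proxy
suffices: the per-residue TOP-IDP propensity scale, smoothed by a
centered 21-residue moving average (shrunk at the ends), thresholded at
0. Poly-E scores fully disordered, poly-I fully ordered, and a
half/half chimera lands near 0.5. Absolute disorder fractions from this
proxy are *not* comparable to VSL2-style predictor output; only
relative, distributional statements should be made.

## Compositional bias and motifs

`bias_regions()` slides a 15-residue window and tests each residue's
count against a background composition with the upper-tail binomial;
overlapping significant windows for one residue merge into maximal
runs, keeping the smallest p. A residue observed despite background
frequency zero is reported with a p = 0 sentinel and a flag rather than
silently dropped.

`motif_enrich()` is a greedy motif-x style recursion over aligned
fixed-width windows: repeatedly fix the (position, residue) pair with
the smallest binomial p against the background, accept while
$p < 10^{-6}$ and at least 20 foreground windows match, then remove the
matched windows from both sets and restart. The window width and
central-residue convention are the caller's; the permutation tests in
the suite confirm the type-I rate of the default thresholds. The
`S(P){3,4}` tandem-repeat finder exists because that extensin-like
repeat is a recurring signature of candidate coccolith-matrix proteins.

## Targeting gate

Luminal CV proteins are expected to enter the secretory pathway, so
candidate status requires a signal peptide (SP), signal anchor (SA), or
a transmembrane domain (TM) that could embed the protein in the CV
membrane. The gate applies the precedence SP > SA > TM and treats a
missing annotation row conservatively as no signal. Real analyses
should supply external predictor tables; the built-in N-terminal
hydrophobic-run heuristic exists only so synthetic tests run
self-contained, and its quality is explicitly not a goal.

# Spectral database quality

Search-database completeness is measured on spectra, not proteins:
(1) de novo quality gating — spectra scoring below 60 on the de novo
scale are discarded (the retain-at-cutoff rule: a score of exactly 60
is kept); (2) clustering, so that abundant peptides do not dominate the
rate; (3) per-database identification rate = clusters with at least one
member matched at peptide probability $\ge 0.95$, over all clusters.

The clustering kernel is a documented stand-in for production spectrum
clusterers, whose internals are not reproducible from literature:
square-root intensity transform, 0.5 m/z binning, cosine similarity,
greedy single-pass assignment to the best cluster consensus within a
2.0 m/z precursor window (charge-aware when annotated), threshold 0.7.
Determinism comes from pre-sorting by (precursor m/z, id) instead of a
random seed. It is validated only on planted truth — adjusted Rand
$\ge 0.95$ at low noise — which is sufficient for its role of comparing
databases on the *same* clustering.

`match_score_distribution()` supports fair cross-organism comparisons:
a control dataset is stratified-resampled so its de novo score
histogram matches a reference (20 bins over the pooled range, largest
achievable subset without replacement), with before/after KS statistics
reported and under-filled bins surfaced rather than silently imputed.

# Differential abundance

Reporter intensities arrive as a protein × channel matrix of log2
values. `normalize_md()` takes the log-ratio to a reference channel —
an explicit one, or an "artificial reference" (rowwise mean across
channels) — then median-centers each channel. The transform is
idempotent and removes constant channel offsets exactly. The exact
arithmetic used by external TMT pipelines for their median-centered
abundance option is not published in detail; this interpretation is
isolated in one function.

`moderated_t()` implements the empirical-Bayes moderated t-test:
per-protein sample variances $s^2$ with $d$ degrees of freedom are
modelled as $s_0^2 F(d, d_0)$; $(d_0, s_0^2)$ are estimated by
closed-form moment matching on $\log s^2$ (digamma/trigamma moments,
Newton inversion of the trigamma), the posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ replaces $s^2$, and $t$ is
referred to $d_0 + d$ degrees of freedom. At $d_0 = 0$ this is exactly
the ordinary pooled t-test (verified to $|\Delta p| < 10^{-10}$); at
$d_0 = \infty$ all proteins share one variance. The test suite
cross-checks the hyperparameters and statistics against the standard
limma implementation on simulated data — limma is used there as an
independent oracle, never as the computation. Missing values are
handled pairwise-complete; proteins with fewer than two complete values
per group are untestable and excluded from the BH denominator.
"Adjusted p" means Benjamini–Hochberg throughout (the least-surprise
default for this family of analyses; configurable), and "regulated"
means adjusted $p <$ 0.05, strictly.

# Candidate filters

All filters run at protein-group level: a group is identified in a
replicate when it has at least one identification at posterior error
probability (PEP) $\le 0.01$ there.

* **Coccolith (COPRO) filter** — identified in $\ge 2$ of 3 replicates
  of the dissolved-coccolith dataset; contaminants removed; the
  targeting gate splits survivors into COPROs (SP/SA/TM) and an
  *expanded pool* retained for non-canonical targeting.
* **Coccosphere filter** — identified in $\ge 3$ of 4 replicates per
  condition; candidates are non-contaminant proteins included under
  standard calcium with *zero* detections in any low-calcium sample
  (the strictest exclusivity reading; a config switch relaxes this to
  "fails the low-Ca inclusion rule"). The shared and low-Ca-only sets
  are reported separately.
* **CV filter** — non-contaminant proteins identified in the bottom
  fractions of calcifying-cell density gradients and absent from every
  non-calcifying control fraction. The rule is defined relative to the
  control, so a missing control is an error, not an empty set.

Contaminant judgment — a manual step in practice — is mechanized as a
rule: a homology hit in a configured category (common laboratory
contaminants, or conserved housekeeping processes) below e-value
1e-10. Every flag carries its justification row and every exclusion a
machine-readable reason; input = kept + excluded reconciles exactly, by
construction and by test. The rule cannot reproduce borderline manual
judgments, which is a stated limitation.

`overlap_analysis()` computes all pairwise and observed higher-order
intersections and the union of proteins in $\ge 2$ sets, verified
internally by inclusion–exclusion. The final report's priority tiers
mechanize the "orthogonal datasets" logic: tier 1 = membership in at
least two datasets; tier 2 = single-dataset membership with a stratum
at or below Calcihaptophycidae (the coccolithophore-containing clade);
tier 3 = the rest.

# Synthetic data: what it emulates, and what it does not

Every stage has a seeded generator that emits data *and* planted truth
side by side; no test reads truth from anywhere else, and the same seed
reproduces byte-identical output.

* `gen_orthogroups()` — single-gain/multiple-loss (Dollo-style)
  evolution on the guide tree; per-branch loss probability; the focal
  species is never lost (the analysis conditions on focal-containing
  families).
* `gen_spectra()` — 20–60 peaks per spectrum on a 0.05 m/z grid,
  clones jittered within half a grid bin scaled by the noise level;
  de novo scores from the mixture Normal(75, 8) for peptide-derived
  spectra vs Normal(40, 10) for junk, truncated at zero, chosen to
  straddle the score-60 gate; each database covers a chosen fraction of
  peptides and its PSM table assigns probability $\ge 0.95$ exactly to
  covered spectra.
* `gen_detection_tables()` — planted candidate classes that satisfy
  their filter's rule with margin (e.g. coccosphere candidates in
  $\ge 3$/4 std-Ca replicates and zero low-Ca detections), planted
  contaminants with homology flags, and sporadic sub-threshold
  background detections that exercise, but never pass, the rules.
* `gen_tmt()` — log2 intensity = baseline + condition effect
  ($\pm$ lfc, alternating sign) + Gaussian noise, with per-protein
  variances from a scaled inverse-chi-square prior so variance
  shrinkage is genuinely exercised and $(d_0, s_0^2)$ are recoverable.

None of this simulates real fragmentation chemistry, retention time,
TMT ratio compression, or the correlation structure of real proteomes.
Passing tests therefore demonstrate that the *rules and statistics* are
implemented correctly and behave as specified under their stated
models — not that the pipeline's biological output on real data is
correct.

# Numerical choices and problem sizes

Tie-breaks and degenerate inputs are pinned down deliberately: the
de novo gate retains scores exactly at the cutoff; N50 uses the
inclusive rule when the cumulative length hits exactly half; BH
adjustment excludes NA p-values from the denominator and propagates
them; clustering determinism comes from input sorting; strata with
fewer than two proteins report distributions but an NA KS statistic;
trailing stop codons are stripped on load with a warning; coordinates
are 0-based half-open internally and 1-based inclusive only in
human-readable reports.

The demo and test problem sizes — 20-leaf random trees with 1,000
presence sets, 150 peptides × 3 clones, 250-protein evidence tables,
2,000-protein null and 50 × 300-protein signal TMT simulations — were
chosen so the full suite exercises every property at comfortable Monte
Carlo resolution while remaining quick on a laptop. The demo's
quantitative comparisons use the clear-separation regime (lfc 3, noise
SD 0.3) so its pass/fail scorecard is a deterministic round-trip check
across seeds rather than a power study; power behaviour at weaker
effects is covered by the dedicated simulation tests instead.

# Known limitations

* Orthology inference itself is out of scope; the package consumes
  orthogroup tables.
* The disorder proxy is distributional only (see above).
* The spectral clustering kernel is a stand-in, validated on planted
  truth, not a re-implementation of any production clusterer.
* The mechanized contaminant rule cannot reproduce borderline manual
  exclusions.
* Full-scale reproduction of published resource numbers (multi-genome
  orthology runs, deposited raw spectra) requires external downloads
  and cluster-scale computation and is not part of the test suite.
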