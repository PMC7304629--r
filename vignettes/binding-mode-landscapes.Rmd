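---
title: "Predicting binding-mode landscapes of disordered protein regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding-mode landscapes of disordered protein regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
```

## The problem

Intrinsically disordered regions (IDRs) bind their partners in two
qualitatively different ways. Some fold into a well-defined structure upon
binding (a disorder-to-order transition, DO); others remain conformationally
heterogeneous in the complex (disorder-to-disorder, DD), forming so-called
fuzzy interactions. The same region may even switch between these modes
depending on the partner, post-translational state or cellular context.
`bindmode` predicts, from sequence alone, (i) the probability that each
residue becomes ordered upon binding, and (ii) how context-dependent that
choice is, quantified as the Shannon entropy of the residue's distribution
of binding modes across all candidate binding sites that contain it.

## The model

### Window-level score

A candidate binding region $R$ is a contiguous window of 5 to 9 residues.
Its propensity to fold upon binding is scored by a logistic model of three
*local biases* -- each the difference between the window and its flanking
sequence (up to 20 residues on each side, pooled into one mean):

$$S_F(R) = \lambda_1\,\Delta ID_{R,Fl} + \lambda_2\,\Delta A_{R,Fl} +
  \lambda_3\,\Delta H_{R,Fl} + \gamma,$$

$$p_{DO}(R) = \frac{e^{S_F(R)}}{1 + e^{S_F(R)}},$$

where $\Delta ID$ is the difference in mean per-residue disorder score,
$\Delta A$ the difference in amino-acid composition, and $\Delta H$ the
difference in mean Kyte--Doolittle hydropathy. The intuition is physical:
a segment that is locally more hydrophobic, less disorder-prone and
compositionally distinct from its flanks carries an autonomous folding
signal; a segment indistinguishable from its context has no reason to
order selectively and tends to remain fuzzy when bound.

Two conventions in this package are deliberate choices where the method
description leaves room:

* **Composition bias $\Delta A$.** The exact composition statistic is not
  specified in the main method description. The default here is the
  difference in mean TOP-IDP disorder propensity between window and
  flanks; an L1 distance between the two composition frequency vectors is
  selectable (`composition_stat = "l1"`). A fitted model records which
  statistic it was trained with in its `feature_config`, and
  `predict_binding_modes()` reads the configuration from the model, so
  parameters can never be silently applied to features computed under a
  different convention.
* **Flank pooling.** Left and right flank residues are pooled into a
  single mean rather than averaged per side, so a flank truncated at a
  terminus contributes in proportion to its actual residue count. Windows
  are kept as long as at least one flank residue exists; only a window
  spanning the entire sequence is rejected.

### Residue-level aggregation

Every residue $A_i$ sits inside up to $5+6+7+8+9 = 35$ windows (fewer
within 8 residues of a terminus; the first and last residue each have 5).
The per-residue probability is the **median** of the window set,

$$p_{DO}(A_i) = \mathrm{median}\{p_{DO}(R_i)\}_N, \qquad
  p_{DD}(A_i) = 1 - p_{DO}(A_i),$$

with the standard sample-median convention for even counts (midpoint of
the two central order statistics). Terminal residues keep their truncated
window sets rather than being dropped; the reduced count is reported in
the `n_windows` column. Windows whose features cannot be computed
(nonstandard residues mapped to `X`, or no flank) are removed from the
set, not imputed.

### Binding-mode entropy

The window set is binned into 10 intervals of width 0.1 on $[0,1]$ and the
Shannon entropy of the bin frequencies $f$ is computed in bits:

$$S_{A_i} = -\sum_{b=1}^{10} f_b \log_2 f_b, \qquad 0 \le S_{A_i} \le
\log_2 10 \approx 3.32.$$

A residue whose windows all predict the same mode has $S_{A_i} = 0$; a
residue whose candidate sites spread over many modes has high entropy and
is predicted to bind in a context-dependent, fuzzy way. Bin edges are
half-open $[0, 0.1), \ldots, [0.8, 0.9)$ with the last bin $[0.9, 1.0]$
closed -- the convention is frozen in the tests because the boundary
behaviour is not otherwise fixed. Ten bins are used because a finer
binning would only be meaningful with more (hence longer) candidate
windows than short linear binding motifs justify.

### The landscape

Each residue is placed on the $(p_{DD}, S_{A_i})$ plane and classified:

| class | box |
|---|---|
| disorder-to-order | $p_{DD} < 0.25$ and $S < 1.8$ |
| disorder-to-disorder | $p_{DD} > 0.65$ and $S < 1.8$ |
| polymorphic | $p_{DD} \le 0.25$ and $S > 2.25$ |
| conditional-folding | $0.25 < p_{DD} \le 0.45$ and $S > 2.25$ |
| disordered-binding | $0.45 < p_{DD} \le 0.75$ and $S > 2.25$ |
| continuum | everything else |

The five boxes deliberately do not tile the plane: the strips between them
(e.g. $1.8 \le S \le 2.25$) are labelled `continuum`, reflecting that the
landscape is a continuum of interaction behaviour with the boxes marking
its recognisable corners. Boundary equalities follow the box definitions
literally (strict inequalities for the two bottom boxes, `<=` on the
right edges of the top boxes). The thresholds are exposed through
`landscape_thresholds()` so users can tighten or loosen the boxes.

## Parametrisation

`fit_binding_model()` estimates $(\lambda_1, \lambda_2, \lambda_3,
\gamma)$ by maximum likelihood from labelled regions -- DO regions coded 1,
DD regions coded 0, one training example per *region* (not per residue),
with features computed for the whole annotated region against its
20-residue flanks. Context-dependent regions are excluded from training by
construction. Numerical choices:

* Newton/IRLS scoring, convergence when the log-likelihood changes by less
  than $10^{-8}$, at most 100 iterations.
* Complete separation is detected (all fitted probabilities at the
  boundary) and handled by refitting with a small L2 ridge
  ($10^{-4}$) plus a warning, so finite coefficients and standard errors
  are always returned.
* Standard errors come from the inverse Fisher information; `confint()`
  gives Wald intervals.

The implementation is cross-checked in the test suite against
`stats::glm(family = binomial())` as an independent oracle (agreement to
$10^{-6}$ on coefficients), and against simulation: data generated at
known coefficients are refitted, each true coefficient is required to lie
in its 95% interval, and across 100 replicates at $n = 1000$ the
per-coefficient coverage of the nominal-95% intervals must be at least
90%. Coverage is assessed per coefficient: the joint event that all four
intervals cover simultaneously has nominal probability well below 95%
($\approx 0.95^4$ if independent) and is not the quantity the interval
procedure calibrates.

**The packaged default model is not the published parametrisation.** The
original coefficients were trained on structure-curated region sets with
an external NMR-trained disorder predictor and were not published. The
JSON shipped in `inst/extdata/default_model.json` is fitted on synthetic
example regions and is clearly labelled non-canonical in its provenance
block; it exists so the pipeline runs end to end. For production use,
retrain on curated regions via `featurize_regions()` +
`fit_binding_model()` and save with `write_model_json()`.

## Disorder scores

The method needs a per-residue disorder score in $[0,1]$. Any external
predictor's output can be supplied as a TSV (`read_score_table()`). The
built-in fallback (`builtin_disorder()`) is a charge/hydropathy
unfoldability index: on a sliding window (default 21 residues, odd), $u =
2.785\langle H\rangle - |\langle q\rangle| - 1.151$ with $\langle
H\rangle$ the mean Kyte--Doolittle hydropathy rescaled to $[0,1]$ and
$\langle q \rangle$ the mean formal charge; the disorder score is $0.5 -
u$ clipped to $[0,1]$. It was chosen because it needs only quantities the
package already computes and has well-understood behaviour (hydrophobic
uncharged segments score low, charged hydrophilic ones high). It is a
coarse stand-in: predictions intended for comparison with published
benchmarks must use externally supplied scores, and every trained model
records its score source in `feature_config$disorder_source`.

## Structure-based dataset curation

`residue_order_states()` assigns each position of a declared full-length
sequence O (any non-hydrogen atom modelled) or M (missing) from a PDB or
mmCIF file, mapping by author residue numbering. A residue with only
partial side-chain density still counts as O -- the O/M call is about
presence in the model, not completeness. Resolution is parsed from the
file and a worse-than-3-Angstrom filter can be enabled
(`max_resolution = 3`). Terminal M-runs are flagged so construct
truncation artefacts can be screened out of disorder calls;
`disordered_segments()` extracts maximal M-runs of at least 5 residues.
`interface_residues()` applies the 4.5-Angstrom heavy-atom contact rule
between different chain identifiers, which makes homotypic (dimerisation)
contacts count. `classify_region()` then labels a region that is
disordered in the monomer as:

* **DOR** -- at least 5 consecutive residues ordered in *every* complex,
  with at least one residue at an interface;
* **DDR** -- missing in the monomer and in every complex;
* **CDR** -- at least 5 consecutive residues ordered (with interface
  contact) in some complex and missing in another;
* **unclassified** -- anything else, with the per-complex evidence kept so
  the call is auditable.

Redundancy reduction of the input structure list (e.g. at 75% sequence
similarity) is out of scope; the curator assumes a pre-clustered list.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without downloads.

* `simulate_training_set()` draws feature triples from independent normals
  (sd 0.2, 0.3, 1.5 for $\Delta ID$, $\Delta A$, $\Delta H$ -- the
  magnitudes these biases take on real sequences, where disorder and
  propensity differences live on sub-unit scales and hydropathy
  differences on the Kyte--Doolittle scale) and labels regions by a
  Bernoulli draw at the true-model probability. An optional Cholesky
  factor induces feature correlations for robustness checks.
* `synth_sequence()` plants regions with target hydropathy, composition
  and disorder-score shifts inside a flat-composition background,
  realising composition targets by exponential tilting of the sampling
  weights plus rejection (tolerance 0.2 hydropathy units, 0.15 TOP-IDP
  units) and disorder targets exactly by recentring.
* `synth_structures()` writes minimal PDB files on an idealised extended
  backbone, with a partner chain placed 4.0 Angstrom from a designated
  residue when an interface is wanted (30 Angstrom otherwise), realising
  any observed/missing plan.

None of this mimics real proteome composition statistics, realistic 3-D
geometry, or the correlated, predictor-specific error structure of real
disorder scores. Passing tests therefore demonstrate that the machinery
implements its stated contracts -- combinatorics, probability algebra,
entropy, classification rules, estimator calibration -- not that the
default model discriminates real DO from DD regions; that claim would
require the curated structural datasets and external disorder scores.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
stochastic checks stable while keeping a full run in tens of seconds:
brute-force window enumeration over all $(i, n)$ with $n \le 60$;
1000 random window sets against the entropy oracle; logistic recovery at
$n = 5000$ with 100 replicates of $n = 1000$ for coverage; AUC sanity at
1000 scores per class; and end-to-end profiles on sequences of 80--120
residues.

## Known limitations

* The default model is demonstrative; all quantitative claims depend on
  the model file supplied.
* The built-in disorder score is much cruder than trained predictors;
  $\Delta ID$ computed from it is correspondingly noisy.
* Author residue numbering is trusted when mapping structures to the
  declared sequence; misnumbered PDB files need pre-processing.
* Entropy values at the first and last ~8 residues rest on fewer than 35
  windows and are comparatively coarse, though empirically terminal
  truncation does not shift entropies systematically.
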