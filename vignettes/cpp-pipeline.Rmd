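---
title: "Place-cell remapping and population decoding in a two-compartment CPP arena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-cell remapping and population decoding in a two-compartment CPP arena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cppmap)
```

## The analysis problem

Conditioned place preference (CPP) pairs a reward with one of two visually
distinct compartments (two 25 × 25 cm boxes joined by a 6.5 cm door).
Chronic calcium imaging of hippocampal CA1 across the CPP timeline
(pre-baseline, baseline, conditioning, two test sessions) yields, per
animal and session, a behavioural trajectory (~30 Hz) and a neurons ×
frames matrix of deconvolved calcium activity for cells tracked across
days. `cppmap` implements the full analysis stack for such experiments:

1. **Preprocessing** — event binarization, speed filtering, occupancy and
   rate maps, occupancy-matched down-sampling.
2. **Place-cell identification** — spatial information with a circular
   shuffle test, aggregated over occupancy-matched iterations into a place
   cell agreement index (PCI).
3. **Functional cell typing** — disappeared/appeared/retained place cells
   per compartment (disPCp, disPCnp, aPCp, aPCnp, rtPCp), rate- versus
   non-rate remapping, and the inter-compartment correlation difference
   (CorrDiff).
4. **Position decoding** — a multinomial naive Bayes decoder with an
   empirical prior, a two-step continuity constraint, shuffle controls and
   computational knock-out.
5. **Temporal clustering** — consensus k-means on calcium-trace
   correlations with PAC/cophenetic model selection and spatial template
   sorting of clusters.
6. **LN encoding models** — linear-nonlinear Poisson models over
   position, head direction and speed with cross-validated forward model
   selection.

Because every stage is recovery-tested against planted ground truth, the
package also ships a first-class synthetic experiment generator.

## The synthetic experiment generator

`simulate_trajectory()` produces a momentum random walk (velocity
persistence 0.8, target speed mean 8 ± 4 cm/s, 5% pause probability,
30 cm/s cap) with reflective walls. The midline partition can only be
crossed through the door, and only during stochastic "shuttle" episodes —
directed runs at the door initiated at `shuttle_rate` (default 0.04/s).
Compartment preference is controlled by skewing the shuttle initiation
rates: with bias $b$, the rate of leaving the preferred compartment is
scaled by $1-b$ and the rate of entering it by $1+b$, so the expected
occupancy fraction of the preferred side is $(1+b)/2$. The default
experiment uses $b = 0.2$ (a 60/40 split) toward the naturally preferred
compartment at baseline and toward the drug-paired compartment in test
sessions, which yields CPP scores of roughly +150–200 s on 15-minute
sessions — the scale reported for methamphetamine cohorts. Head direction
is the movement heading plus wrapped-Gaussian noise (SD 0.4 rad) — a
minimal model, since head orientation is not fully determined by the
movement direction in real animals.

`neuron_population()` draws per-neuron ground truth: 2D Gaussian place
fields (width 4–6 cm, peak event probability 0.05–0.12 per frame), by
default homotopic across compartments with a cross-compartment peak-rate
ratio of 0.4–1 (rate remapping), a minority with independent field
locations (global remapping). Optional modulations are a von Mises
head-direction gain (normalized to unit mean so tuning does not change the
mean rate) and a power-law speed gain saturating at 15 cm/s
(exponent configurable per neuron, default quadratic). Session
effects are planted per neuron: `disappear` (tuning in a designated
compartment removed in test sessions), `appear` (the reverse), `remap`
(field centres move in test sessions) and `untuned` (spatially flat but
active at 0.12–0.36 Hz, so untuned cells pass the mean-rate gate and
genuinely exercise the specificity of the shuffle test). All neurons share
a spontaneous event probability (default 0.2% per frame) that keeps
shuffle controls non-degenerate. With `n_clusters = 5`, field centres
concentrate in the four compartment sectors (SW/NW/SE/NE, homotopic in
both compartments) plus a junction-centred group, and anatomical centroids
cluster accordingly. Cluster membership is expressed through two
mechanisms jointly: the shared spatial sector, and a slow (0.5 s
correlation time) log-normal excitability gain common to the members of a
cluster (`coactivation`, the gain's log-SD, default 0.6). The cluster
gains are *competitive* — centred on the momentary mean across clusters,
so ensembles alternate rather than co-vary, as CA1 assemblies do. This
matters for model-order selection: spatial overlap alone leaves sparse
event trains almost uncorrelated frame-to-frame (membership becomes
ambiguous), while independent per-cluster gains make every merge level of
the cluster hierarchy equally stable (the same most-similar pair of
clusters merges every time, so stability criteria cannot single out the
true cluster number). With competitive gains any merged pair is
internally anti-correlated, merges below the true K are unstable, and
the ambiguity measure identifies the planted K.

What the generator does *not* emulate: raw imaging movies, motion
artifacts, calcium indicator dynamics and deconvolution errors,
cross-session registration failures, theta-timescale spike timing, or
behavioural idiosyncrasies (thigmotaxis, grooming bouts). Tests passing on
synthetic data therefore validate the *analysis logic* — estimator
correctness, calibration of null distributions, recovery of planted
effects — not robustness to acquisition artifacts.

## Preprocessing choices

* **Binarization** (`binarize_events()`): events are frames whose
  deconvolved amplitude exceeds 3 × the SD of the neuron's full trace.
  The SD is the population SD over all frames, zeros included; the rule is
  scale-invariant per neuron. Constant non-zero traces (SD 0) are flagged
  degenerate and excluded.
* **Speed filter**: frames below 2 cm/s are dropped from all spatial
  analyses.
* **Maps** (`compute_maps()`): 1.8 × 1.8 cm bins, half-open `[lo, hi)`,
  origin at the SW corner. Unsmoothed rates (used by the information
  score) are kept separately from the smoothed map (Gaussian kernel,
  SD = 2 **bins** = 3.6 cm, truncated at 4 SD, renormalized at the arena
  boundary; whether the smoothing SD is expressed in bins or cm is a
  convention that differs between labs, so the units are exposed as
  configuration). Bins occupied < 0.1 s are
  excluded from occupancy-normalized statistics and from map
  correlations (pairwise-complete).
* **Occupancy matching** (`match_occupancy()`): per bin, both conditions
  retain the minimum count, surplus removed uniformly at random; 50
  iterations by default, each seeded from one master seed. For transverse
  (left versus right) comparisons frames are binned in
  within-compartment coordinates so that homotopic bins correspond.

## Place cells and the PCI

Spatial information is computed per compartment on unsmoothed rates:
$\mathrm{bits/event} = \sum_i P_i \frac{\lambda_i}{\lambda}
\log_2 \frac{\lambda_i}{\lambda}$. The null distribution comes from 1000
circular shifts of the event train, drawn uniformly over 5–95% of the
trace length (the same shift range as the decoder's shuffle control, used
for consistency; it is configurable). A neuron passes one
iteration when its score exceeds the 95th percentile of its own shuffles.
The full test is repeated over 20 occupancy-matched iterations; PCI is
the passing fraction, and a place cell requires PCI ≥ 0.3 plus a mean
event rate ≥ 0.1 Hz (applied once on the speed-filtered session, before
shuffling, to save compute). Field size is measured on the smoothed
matched map at 50% of peak with 8-connected components (the field's
standard choice for smoothed maps), taking the largest field.

On default synthetic populations this classifier reaches sensitivity and
specificity around 0.9, and its false-positive rate is unchanged by a
CPP-like occupancy bias — the calibration property that motivates the
occupancy-matching machinery.

## Functional typing and CorrDiff

Typing is a pure function of the per-session, per-compartment place-cell
flags: disPCp lost preferred-compartment tuning in *both* test sessions;
aPCp gained it in both; rtPCp retained it in at least one (disjoint from
disPCp by construction). A neuron can satisfy definitions in both
compartments; all indicator columns are returned and the scalar `label`
uses a documented precedence (disPCp > disPCnp > aPCp > aPCnp > rtPCp).
Rate remapping is an inter-compartment matched-map correlation strictly
above 0.4. CorrDiff is the baseline-minus-test inter-compartment
correlation aggregated over the cells of a type (mean by default,
median available), two values per animal (baseline vs. each test
session); both a rank and a linear correlation against the CPP score are
reported downstream, since either statistic is defensible for small
per-animal samples.

## The decoder

Events are summed in non-overlapping 0.8 s bins (24 frames at 30 Hz;
the dropped remainder is logged), labelled with the spatial bin of the
mean position within the window — robust to within-bin motion. The
decoder vocabulary reuses the 1.8 cm map bins. Training fits, per
location, a multinomial over neurons with Laplace smoothing: neuron
$i$'s parameter at location $y$ is (total events of $i$ at $y$ + 1) /
(total events of all neurons at $y$ + N). Observation weights are
normalized so that the weights within a location sum to that location's
prior, rescaled to unit mean — under the empirical prior used here this
weighting is exactly neutral (the numerator stays the raw spike count,
as the estimator requires); it would reweight counts under a
non-empirical prior, and can be disabled with `use_prior_weighting =
FALSE`. Decoding maximizes the log posterior; ties break to the smallest
location index.

The two-step rule multiplies the posterior by a 2D Gaussian centred on
the previous *decoded* position with SD $\sigma_t = a v_t$, $a = 2.5$,
floored at one bin width (1.8 cm) so a stationary animal never freezes
the estimate; the first bin and bins with missing speed fall back to the
single-step rule. The scaling constant of the Gaussian cancels in the
argmax and is fixed at 1. On 150-neuron synthetic baselines the decoder
achieves ~5 cm mean error versus ~15 cm chance (100 joint circular
shuffles of the test activity, shifts 5–95%; a per-neuron shift variant
is available behind a flag), and the continuity constraint lowers the
error of moderate-size populations by roughly 5–10%.

Knock-out decoding zeroes the chosen neurons in the *prediction* data
only — ablating them from training would let the model compensate — and
reports the decoding error plus the reconstructed CPP time (fraction of
decoded bins per compartment). `ko_contrast()` pairs every knock-out
with size-matched random controls.

## Temporal clustering

Traces are noise-filtered at 2 × the SD of the raw-minus-denoised
residual. The consensus matrix accumulates co-assignment frequencies
over 100 iterations of k-means (10 restarts each) on 90% frame
subsamples; each neuron is represented by its vector of pairwise Pearson
correlations to all neurons on the subsampled frames
(correlation-as-features; a k-medoids alternative on 1 − r distances is
available by configuration). The final partition is a complete-linkage cut of
`1 - consensus`. K is selected over 2–10 by the interior local minimum
of PAC (fraction of pairs with consensus strictly inside (0.1, 0.9)),
with the cophenetic correlation's local maximum reported alongside; PAC
governs on disagreement. Ensemble maps (summed member smoothed maps,
min-max normalized) are sorted onto sectors by first holding out the
centre cluster (peak closest to the midline) and then assigning the
remaining four to two-field Gaussian templates at homotopic sector
positions (variance 12.5 cm² for the near-midline field, 25 cm² for the
far one) using the permutation with maximum summed correlation — which
subsumes the greedy rule whenever that rule is unambiguous.

## LN models

Behaviour is binned at 0.5 s; position uses the 1.8 cm bins, head
direction 20° bins (circular), speed 2 cm/s bins capped at 30 cm/s with
an open-ended last bin (the cap keeps rarely visited high-speed bins from
fragmenting the vocabulary). The rate model is
$r = \exp(\sum_i X_i^\top w_i)/dt$ fitted by penalized Poisson maximum
likelihood (L-BFGS with analytic gradients); the smoothness prior is the
mean squared difference of adjacent parameter bins (4-neighbour grid for
position, circular ring for head direction), weight 5 by default on the
normalized penalty, plus a negligible ridge (1e-6) that fixes the
constant-offset degeneracy between variable blocks. Performance is the
held-out Pearson correlation between predicted and observed rates minus
the 95th percentile of 500 circular shuffles of the observed rate,
over 10 random 10% folds (contiguous blocks available as a guard against
temporal leakage). One fold assignment is shared by all candidate models
of a neuron so the forward search's one-sided sign-rank comparisons
(p < 0.05) are genuinely paired; a neuron whose final model is not
significantly above zero stays unclassified.

A practical note on recovery: with binarized Bernoulli events at
realistic rates, the *raw empirical* rate map of a 20–40 minute session
correlates only ~0.85–0.90 with the generative field, so no estimator
can exceed that ceiling; the recovery tests therefore require the LN
position estimate both to correlate > 0.75 with the planted field and to
reach the empirical map's own ceiling. Model-*class* recovery is
near-perfect on strongly modulated neurons (two concatenated baseline
sessions, which is also how the pipeline assembles enough training data
in practice).

## Problem sizes in the shipped tests

The test-suite and acceptance script run end to end on a single CPU, so
they use deliberately compact study conditions chosen once: sessions of
10–15 minutes (30 minutes concatenated for LN fits), populations of
40–150 neurons, 300–1000 shuffles, 10–20 matching iterations, and 4–20
seeds per Monte-Carlo property. The full-scale defaults (50 matching
iterations, 1000 shuffles, 100 consensus iterations, 500 LN shuffles)
remain the package defaults and are exercised directly where the
property depends on them (e.g. PCI recovery).

## Known limitations

* The pipeline starts from deconvolved activity; deconvolution itself,
  imaging artifacts and registration are out of scope.
* Group-level cohort statistics (t-tests/ANOVAs across animals) are not
  re-implemented; the per-animal tables are the interface to whatever
  inferential layer a study needs.
* The fixture format is a plain-text directory (CSV + JSON) rather than
  a binary container, keeping fixtures inspectable and diff-able.
* The two-step decoder assumes approximately continuous motion between
  0.8 s bins; for teleport-like paradigms it should be disabled.
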