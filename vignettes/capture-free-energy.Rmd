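---
title: "Modelling LASSO probe capture free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LASSO probe capture free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

A LASSO probe (long-adapter single-stranded oligonucleotide) is a molecular
inversion probe whose two target-complementary arms are joined by an adapter
of user-defined length. Experimentally, capture efficiency depends
non-monotonically on adapter length: intermediate adapters outperform both
the short MIP-style (~50 nt) and very long (~800 nt) designs. `lassocapture`
models the physical side of that observation: the free energy of the
probe-target interaction, defined over a two-dimensional order parameter
that records whether each arm is engaged with its target site, estimated by
umbrella-sampled Monte Carlo over a reduced coarse-grained DNA model. The
sequencing side — RPKM, median-ratio enrichment, relative free energies via
`-ln(RPKM_A/RPKM_B)`, and the Pearson correlation between experimental and
simulated free energies — is implemented in the `enrichment` functions so
that simulation and experiment land on a common RT-unit scale.

## The reduced coarse-grained model

The model is deliberately minimal: one bead per nucleotide, energies in kT
at the configured temperature (default 338.15 K, the 65 °C capture
temperature), distances in nm. Terms:

* **Bonds**: harmonic, `0.5 * bond_k * (r - bond_r0)^2`, with
  `bond_r0 = 0.65` nm (the ssDNA backbone rise) and `bond_k = 100` kT/nm²
  (stiff but samplable).
* **Bending**: harmonic in the angle between consecutive bond vectors,
  `0.5 * bend_k * theta^2`. The default `bend_k = 2.12` kT is calibrated by
  quadrature (`bend_k_for_persistence()`) so the discrete worm-like-chain
  persistence length is 1.5 nm, the accepted ssDNA value at high monovalent
  salt. The package verifies the calibration against the closed-form
  freely-rotating-chain `<R^2>` in its test suite.
* **Excluded volume**: Weeks-Chandler-Andersen repulsion with
  `ev_sigma = 0.65` nm, capped at `ev_cap = 100` kT so overlapping beads
  have large-but-finite energy (no infinities anywhere in the energy
  surface; a proposal onto a coincident bead is simply very improbable).
* **Electrostatics**: a truncated-shifted Yukawa repulsion with the Debye
  length `0.304/sqrt(M)` nm. The default 300 mM Na+ follows the experimental
  convention of substituting a higher monovalent concentration for a
  Mg2+/Na+ buffer; magnesium is not modelled. The truncation at
  `2 * debye_length` makes a straight chain at rest geometry exactly zero
  energy, which anchors the unit tests.
* **Hybridization**: a Go-like square well of depth `hyb_epsilon`
  (default 3 kT) and radius `hyb_range = 0.85` nm acting *only* between the
  designed arm/site bead pairs returned by `find_arm_complements()`.
  Sequence specificity therefore enters through the designed pairing, not
  through nearest-neighbour thermodynamics — the adapter-length question is
  a question about polymer statistics of loop closure, and every term is
  individually testable.

The box is a periodic cube; `init_configuration()` sizes it as 1.2 times
the longer chain's contour length — "well contained" for both strands even
in scaled-down systems whose target outmeasures the probe — and places both
chains as self-avoiding walks, reproducibly per seed.

## Order parameters and free energy

For each arm the distance to its site is the *minimum* over the designed
complementary pairs of the minimum-image bead-bead distance. Each distance
is discretized by a `bin_table()` of half-open intervals; `(Q_ex, Q_lig) =
(0, 0)` is the interaction state and `(max, max)` the non-interaction
state. The interaction free energy is

    dG_int / RT = -ln( P(0, 0) / P(max, max) )

on the unbiased distribution, with a block-bootstrap error bar (20 blocks,
200 resamples by default) over the recorded trajectory, and
`diagonal_profile()` reports `-ln P(q, q)` zeroed at the non-interaction
corner; its end-to-end difference equals `dG_int` identically.

The default table keeps every printed edge of the published 11-interval
scheme (0, 1.7, 3.4, 5.1, 8.5, 12.8, 17.0, 34.1, 68.1, 102.2 nm). Those
edges enumerate only ten intervals against a stated count of eleven with
order parameters 0..10, so one additional edge is interpolated at 85.2 nm
(midway between 68.1 and 102.2). The table is fully configurable and every
serialized artifact records the edges it was computed under, so nothing
depends silently on this reconstruction.

Distances at an edge fall in the upper interval (half-open `[lo, hi)`
convention, so "smaller than 1.7 nm" is exactly `Q = 0`); the final
interval is unbounded.

## Samplers

Two engines share one umbrella-bias rule (acceptance multiplied by
`w_new/w_old` evaluated on the order-parameter state):

* `metropolis`: single-bead displacements. Exact and simple; the reference
  oracle for the cluster sampler.
* `vmmc`: Virtual Move Monte Carlo in the symmetrized form — a seed bead
  proposes a rigid translation, or a rotation pivoted on a bonded
  neighbour of the seed; pairwise links recruit neighbours with probability
  `max(0, 1 - exp(-dE_fwd))`, frustrated links (reverse-move probability
  smaller than forward) are resolved stochastically with early rejection.
  Three implementation points deserve record:
  1. with symmetrized link formation, boundary pairs that stay outside the
     cluster need *no* acceptance factor (their no-link probabilities carry
     the Boltzmann weight); pairs whose link test failed but whose outer
     bead was later recruited through another member *do* need the
     `(1 - p_rev)/(1 - p_fwd)` factor;
  2. rotations pivot on a bonded neighbour because a point bead rotated
     about itself moves nothing — this turns rotations into
     crankshaft/pivot moves, which is what decorrelates long chains;
  3. cluster members are unwrapped relative to the pivot along the
     recruitment path before rotating; min-imaging the spans directly is
     not invertible once a cluster exceeds half the box, and that subtle
     irreversibility is a measurable bias on chains of 20+ beads.
  The bending term is 3-body and cannot ride in pairwise link
  probabilities; angles straddling the cluster boundary enter the
  acceptance as an explicit Boltzmann residual.

  Correctness is enforced empirically: bond-length distributions against
  the radial Boltzmann law, a bound pair's internal distance distribution
  against quadrature, and stationary distributions against Metropolis on a
  4-bead toy.

Move sizes default to 0.25 nm / 0.2 rad (30-50% acceptance on the
reference systems); the umbrella studies below use larger steps where the
ideal-chain systems tolerate them. A `cluster_size_cap` auto-rejects (and
counts) oversized cluster moves; the default is no cap.

## The three-stage umbrella pipeline

`run_capture_pipeline()` chains the stages and persists every intermediate
with seed and config hash.

1. **Weight adaptation** (`adapt_weights()`): per block, weights of visited
   states are divided by their counts (`w <- w / max(counts, 1)`, the
   multiplicative Wang-Landau-flavoured rule), after normalizing counts by
   their geometric mean and clamping every per-block factor to
   `exp(±damping)` (default ±2 in log units). Unvisited states are left
   untouched: effectively-unreachable states must not accumulate runaway
   weights, because a runaway weight turns a rare state into a trap the
   first time the sampler enters it; exploration pressure comes from the
   well-visited weights falling relative to the frontier. Convergence
   demands, within one block, histogram flatness `min/mean >=
   flatness_target` over the visited states *and* at least two round trips
   between the two corners (plus any `require_cells`, which the pipeline
   sets to the corners). The round-trip requirement is the direct
   certificate that production will sample both corners. If the budget runs
   out the best table is returned with a warning flag — never an invented
   convergence.
2. **Equilibration**: `n_equilibration` discarded steps under the final
   weights.
3. **Production**: counts accumulate every step; the order-parameter
   trajectory is recorded every `stride` steps for the bootstrap.

`unbias()` refuses a weight table whose hash does not match the one the
histogram was sampled under. States never visited are zeros in the
distribution and reported as gaps by the profile, and `dG_int` refuses to
evaluate when either corner is unvisited — a longer run is the only honest
remedy.

## What the validation systems are, and why

* **Two-bead toy** (one bead per chain, one designed pair): the partition
  function reduces to a radial quadrature, `Z_cell = int 4 pi r^2
  exp(-u(r)) dr`, with the final open cell's exact box volume. This is the
  enumeration oracle for `dG_int` (agreement within 0.2 RT) and for the
  bias-invariance check (two independently adapted weight tables must agree
  within combined bootstrap error).
* **Loop-closure scaling**: probes of N = 16..128 ideal-chain adapter beads
  (bending and excluded volume off) whose terminal beads hybridize to a
  2-bead target. Ring-closure statistics predict the corner-to-corner cost
  to grow like `1.5 ln N`. Design choices that matter: the far-corner edge
  is small (8 nm) inside a 40 nm box so the non-interaction corner's
  probability is nearly N-independent (a large far-corner threshold makes
  P(max,max) fall with chain size through the correlation of the two
  end distances, which contaminates the slope); the probe *is* the adapter
  (terminal beads as arms), so the loop length tracks N itself. An
  independent semi-analytic oracle (direct sampling of the freely-jointed
  end-to-end vector against an analytic two-ball overlap integral) puts the
  exact slope of this system at about 1.41 over this N range — the
  asymptotic 1.5 eroded slightly by the finite loop-length offset at N=16.
* **Adapter sweep** (the scaled-down analogue of the experiment): 8-nt
  arms, 40-nt target, adapters of 10/30/60/120 nt generated by
  `gen_capture_system()` with identical arms, full energy model. All four
  systems share one box (40 nm) and one bin table, otherwise the
  non-interaction corner differs by pure geometry between systems and the
  ordering is a box-size artifact. The sweep uses `hyb_epsilon = 1.5` kT:
  the adapter-length dependence lives in the loop-closure entropy, not the
  well depth, and weak wells keep arm binding/unbinding kinetics fast
  enough to sample. The tested property is the experimental headline at
  desk scale: the longest adapter's interaction free energy exceeds the
  sweep minimum.

Problem sizes (blocks of 1e5-1e6 steps, production runs of 8e5-4e7 steps,
40-50 nm boxes) are the package's chosen desk-scale study conditions: large
enough that every estimate carries a bootstrap error bar that the assertion
tolerances respect, small enough to be routinely re-runnable.

## The synthetic-data generator

`gen_capture_system()` draws a random target and derives both arms as exact
reverse complements of its two ends, one probe per adapter length with
shared arms — the construction mirrors library experiments where probes
differ only in adapter. `gen_read_table()` emulates the sequencing readout:
negative-binomial counts (dispersion 0.3 by default; 0 selects Poisson)
with mean `mean_depth * length/1000`, multiplied by `true_enrichment *
propensity` on target rows, lengths uniform in 400-1500 nt. Because the
same multiplicative noise acts on both strata, the median-ratio enrichment
estimator recovers `true_enrichment` without bias — the parameter-recovery
test demands < 5% at depth 100 over 50 replicates. What the generator does
*not* emulate: PCR amplification bias, sequencing error, duplicate reads,
or any sequence-composition effect on capture, so passing tests certify the
statistics pipeline, not those laboratory artifacts.

One interaction between normalizations is worth knowing: RPKM computed with
*per-probe* library sizes partially absorbs a probe's capture propensity
when target reads dominate the library. Cross-probe comparisons in the
package's tests therefore fix a common `reads_lib`; with real data the
equivalent is comparing libraries sequenced to a common scale.

## Enrichment conventions

`rpkm()` uses the standard per-kilobase per-million constant (1e9); the
printed definitional form omits it, and every downstream quantity is
invariant to it. Medians of even-sized strata are the mean of the central
pair. `relative_dg()` assigns exactly 0 to all probes tied at the maximal
RPKM. Zero counts error by default; `add_rpkm(pseudocount = 0.5)` is the
explicit opt-in before log transforms. `pearson_r()` demands at least three
pairs and non-degenerate variance.

## Known limitations

* The reduced model has no base-pair-resolution thermodynamics, no
  stacking, no Mg2+-specific electrostatics, and no ligation chemistry;
  absolute `dG_int` values are model quantities, useful for *comparisons*
  across adapter lengths.
* One global weight table over the full grid (no WHAM over windows, no
  transition-matrix estimators); histogram unbiasing is exact but the
  adaptation quality only affects statistical efficiency.
* The order parameter does not see the slow internal coordinate of a
  zipped arm; deep wells therefore mix slowly, which is why the sweeps use
  shallow wells and why `adapt_weights()` certifies corner round trips
  rather than flatness alone.
* Secondary structure of long adapters (a competing experimental
  hypothesis, largely ruled out at 65 °C) is outside the model.
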