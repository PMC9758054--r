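---
title: "Mapping and quantifying protein roadblocks by DNA unzipping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying protein roadblocks by DNA unzipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unzipr)
```

`unzipr` analyzes single-molecule DNA unzipping experiments in which an
optical trap separates the two strands of a DNA template to map bound
proteins — in particular CRISPR dCas effector complexes acting as polar
roadblocks to RNA polymerase (RNAP) or the Mfd translocase — and to
quantify how efficiently a motor reads through or removes the roadblock.
This vignette documents the models, the tunable parameters, the synthetic
data the package tests itself against, and the design decisions taken where
the analysis admitted genuine alternatives.

## The equilibrium unzipping model

The naked-DNA baseline is the equilibrium force–extension curve of a
Y-structure: dsDNA arms of total contour $L_{arm}$ (bp) in series with the
two ssDNA strands released by opening $j$ base pairs. At a controlled total
extension $z$ (nm), each fork position $j$ defines a mechanical state whose
force solves

$$z = L_{arm}\,x_{ds}(f) + 2j\,x_{ss}(f),$$

and whose free energy is the opening cost of the first $j$ base pairs plus
the Helmholtz stretching energy of the arms and ssDNA at that extension
(obtained by Legendre transform from the force–extension integrals). The
curve reports Boltzmann-weighted averages of force and fork position over
$j$, truncating weights below $10^{-12}$ of the maximum. Averaging — rather
than taking the minimum-energy state — matters: it produces the thermal
"breathing" by which the fork senses an unpaired bubble a few base pairs
before reaching it, and it rounds the sawtooth rips realistically.

Assumptions: the unzipping is quasi-static (loading at 500 nm/s or 8 pN/s
is slow compared with base-pair opening kinetics), trap compliance is
ignored (extension is the DNA end-to-end distance), and torque plays no
role.

**Base-pairing energetics** (`thermo_params`). Unified nearest-neighbor
dinucleotide enthalpies and entropies at 1 M NaCl, with a uniform
salt correction of 0.114 kcal/mol per step per $\ln[\mathrm{Na^+}]$ and
$\Delta G = \Delta H - T\Delta S - m\ln[\mathrm{Na^+}]$. Defaults:
$T = 298.15$ K — transcription buffer nominally at 23.3 °C warms to an
estimated 25 °C under the trapping laser — and 100 mM monovalent salt, the
KCl concentration of the transcription buffer. Step energies are averaged
onto base-pair positions (terminal base pairs take their single flanking
step). The published record of the assay does not state which parameter set
its theory curves used, so the tables are replaceable through
`thermo_params()`.

**Elasticity** (`elastic_params`). ssDNA is an extensible freely jointed
chain (contour 0.56 nm/nt, Kuhn length 1.5 nm, stretch modulus 800 pN);
dsDNA an extensible worm-like chain in the Marko–Siggia interpolation
(0.338 nm/bp, persistence length 43 nm, stretch modulus 1200 pN). These are
standard optical-tweezers values at ~100 mM salt; they too are configurable
rather than asserted. With the defaults, an AT-rich segment unzips at
~12 pN and a GC homopolymer at ~18 pN, and the plateau satisfies the
two-state work balance $\Delta G_{open} = 2\int_0^{f^*} x_{ss}(f)\,df$ to
well under 2% — a property the tests verify against independent
quadrature.

## Converting, aligning and calling traces

`bp_from_force_extension` inverts the series elasticity per sample:
$j = (z - L_{arm} x_{ds}(f)) / (2 x_{ss}(f))$. Two numerical points
deserve note:

* Samples below a 3 pN force floor are masked — near zero force the ssDNA
  extension vanishes and the inversion is degenerate.
* The force is boxcar-averaged over 5 samples before conversion.
  Conversion amplifies force noise several-fold in bp (at fork position
  400 on the default construct, ~8 bp per pN), and where the baseline is
  steep the amplified noise also acquires a systematic bias; averaging
  first, as instrument pipelines do when decimating 10 kHz data to 1 kHz,
  suppresses both.

`align_to_theory` fits an offset (±20 bp) and stretch scale (0.95–1.05) by
trimmed least squares (10% trim, so protein peaks do not bias the fit),
with a coarse-to-fine grid and a final continuous polish of the offset —
residual misalignment of even a fraction of a base pair leaves
threshold-crossing deviations at steep sawtooth rips. A small ridge penalty
ties the scale to 1: the scale is nearly unidentifiable from noise on an
undistorted trace, yet an error of 0.01 displaces distal positions by
several bp; a genuinely stretched trace overwhelms the penalty. Traces
whose trimmed RMS residual exceeds 1.2 pN are flagged `alignment_failed`.

`call_interactions` thresholds the deviation from the baseline at +2 pN
(rise) and −1.5 pN (dip), with a minimum width of 3 bp; these defaults were
chosen so that the simulated null false-positive rate is below 5% per trace
(the tests measure it at 0/40 naked traces at default noise). Run extent is
measured in *fork progress* — where the naked fork would be at the sample's
extension — because a fork stalled against a protein climbs in force at
nearly constant bp and would never accumulate width on the bp axis. The
call position is the median converted bp over the samples near the run
maximum, where the fork sits hard against the obstruction. Samples whose
fork position lies within 6 bp of the template end are excluded: there both
trace and baseline stiffen sharply as the template is exhausted, and
deviations are edge artifacts, not proteins.

The tether-shortening correction (`correct_transcript_annealing`) detects a
sustained backward jump of the converted bp at near-constant force — the
signature of the nascent transcript annealing to exposed ssDNA — and shifts
downstream calls forward by the measured amount. Its threshold adapts to
the trace's own conversion noise (6 robust standard deviations of the
sample-to-sample increments, at least 2 bp), so noisy traces cannot fire
spurious corrections; the cost is that small events are only detectable on
quiet traces.

## Classification

Pre-chase traces are labelled by the presence of a motor rise within 15 bp
of the A20 stall site and of the dCas signature; post-chase traces by the
decision order: dCas present? then the motor peak's distance upstream of
the dCas target site — strictly more than the cutoff (60 bp for RNAP,
70 bp for Mfd, matching the complexes' footprints) means the motor never
arrived; within it, a collision (`Coll`, dCas present) or a removal with a
stalled motor (`dCas_rem`, dCas absent); downstream of the site without a
dCas, `TEC_dn`. Two conventions were genuinely open and are fixed as
follows (both configurable):

* The "dCas target site" reference point is the PAM-proximal edge of the
  protospacer — a fixed, orientation-independent anchor.
* Distance ≤ cutoff counts as collided (the strict inequality applies to
  the "not yet arrived" side).

dCas presence is direction-dependent. Unzipped PAM-proximal-first, a bound
dCas shows a sharp clamp rise ~6 bp before the PAM; the rise alone
suffices. Unzipped PAM-distal-first, the complex shows the R-loop bubble
dip followed by a clamp rise within the hybrid — but a lone rise inside the
footprint could equally be a motor that invaded and removed the dCas, so
the clamp rise must be corroborated: either by the dip (the fork approached
the intact complex quasi-statically) or by a separate motor rise upstream
(a collision, in which the fork rips through the stalled motor at elevated
force and crosses the bubble region during the relaxation jump, skipping
the dip). A dip alone is never sufficient. Consequence: on
PAM-proximal-first templates a `dCas_rem` trace is indistinguishable from a
bound dCas by position alone; the experiments this matters for (removal is
observed only from the PAM-distal side) are unaffected, and the limitation
is noted here deliberately.

For Mfd runs the 70 bp cutoff applies and `dCas_rem` is tallied like any
other category; no stalled-Mfd-after-removal population is expected, and
the removal efficiency then coincides with the move-through efficiency.

## The estimator

Per chamber, with pre-chase fractions $F_{\cdot,i}$, post-chase fractions
$F_{\cdot,f}$ and nuisance probabilities $P_{md}$ (motor) and $P_{dd}$
(dCas) of non-collision dissociation over the chase:

$$P_{cc} = 1 - \frac{F_{TECup,dCas,f} + F_{TECuponly,f}}
  {(F_{A20,dCas,i} + F_{A20only,i})(1 - P_{md})}$$

$$P_{RT} = \frac{F_{Nak,f} + F_{TECdn,f} - F_{Nak,i}
  - F_{A20,dCas,i}\,r\,P_{dd} - F_{A20only,i}\,r - F_{dCasonly,i}\,P_{dd}}
  {F_{A20,dCas,i}\,P_{cc}(1 - P_{md})(1 - P_{dd})},
  \quad r = P_{cc}(1-P_{md}) + P_{md}$$

and $P_{Removal}$ adds $F_{dCasrem,f}$ to the numerator. The central
correctness property is algebraic: `expected_fractions()` computes the
exact leaf probabilities of the generative outcome tree, and the estimator
applied to them returns the generator's true
$(P_{cc}, P_{RT}, P_{RT} + P_{removal\_stall})$ to machine precision, for
any valid configuration with nonzero denominators. The tests assert this
over 200 randomized configurations at $10^{-12}$ absolute tolerance, with
the tree enumerated independently of the closed form.

Numerical conventions: estimates pushed outside $[0,1]$ by sampling noise
are flagged but enter the cross-chamber aggregate unclipped (clipping would
bias the mean); chambers with zero denominators are excluded and counted;
the s.e.m. uses the $n-1$ sample standard deviation over chambers, with no
propagation of nuisance-parameter uncertainty (the nuisance probabilities
are measured in separate dissociation controls and treated as known).
`F_Coll_f` and `F_dCas_f` enter no equation — they are complements — and
are only validated for the sum-to-one constraint.

## The synthetic generator

`sample_outcomes` draws each chase trace through the outcome tree: initial
state (defaults 0.90/0.04/0.04/0.02, reflecting the >90% co-occupancy of
the assay), non-collision motor loss, spontaneous dCas loss, collision
competence, then the collision outcome (read-through / removal-then-stall /
blocked). Two structural choices close gaps the estimator's algebra
implies: a collision-competent motor on a dCas-free template always ends as
naked DNA or a downstream motor (split by `p_runoff`, to which the
estimator is provably insensitive), and a non-competent motor whose dCas
dissociated spontaneously maps to `TEC_up_only`. Chase duration (135 s for
RNAP, 480 s for Mfd) and the Mfd translocation rate are metadata: the
generator is outcome-level, not kinetic, because the estimator consumes
end-point categories only.

`render_trace` produces full force–extension records: the R-loop bubble is
rendered by replacing the opening energies across the hybrid (widened
upstream by a 3 bp breathing look-ahead) with the residual corresponding to
a force ~3 pN below the plateau, and each protein clamp is a *yielding
constraint* — the fork cannot pass until the stalled-branch force exceeds
the local naked baseline by the rise amplitude (default 6 pN), then the
constraint lifts and the curve relaxes to equilibrium. An additive
energy-barrier rendering was rejected: equilibrium averaging tunnels
through few-bp barriers and produced rises far weaker than observed
signatures. Gaussian force noise (s.d. 0.4 pN per 1 kHz sample) is added
throughout. The optional dCas12a dual-conformation mixture adds a second
rise at the distal end of the hybrid with probability 0.57; it is off by
default and classification does not depend on it.

What the generator does *not* emulate: instrument drift, bead rotation,
refolding curves, force-dependent protein dissociation during the scan,
heterogeneous noise, or kinetic asynchrony of the motor population. Passing
the round-trip tests therefore shows that the processing and classification
recover what this model of the experiment produces — it does not certify
performance on raw instrument data.

## Problem sizes and runtime choices

The packaged analyses use a 450 bp unzipping segment on 2200 bp arms —
enough to separate the A20 site, a 300 bp chase run-up, and the dCas
footprint — with theory curves on a 2500-point extension grid (finer grids
change plateau forces by well under the noise). Parameter-recovery checks
run the outcome-level pipeline at the experimental scale (5–6 chambers of
40 control + 60–80 chase traces) and at 100× that trace count, where the
recovered aggregate converges to within ~1 percentage point of the
generator truth; trace-level round-trip checks use 20 rendered traces per
category, which keeps the whole suite under two minutes on one core.

## Known limitations

* The equilibrium model has no loading-rate dependence; both loading modes
  differ only in their time stamps.
* Position accuracy degrades with fork position (conversion noise grows
  roughly linearly in $j$); beyond ~450 bp segments, thresholds and the
  minimum call width would need revisiting.
* The dCas-presence rule on PAM-distal-first templates relies on the dip or
  a second rise; a removal event whose motor stalls exactly at the clamp
  position of a *still-bound* complex on a proximal-first template is
  ambiguous by construction.
* The annealing correction detects only jumps larger than the local
  conversion noise; on noisy distal regions small shortenings pass
  uncorrected.
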