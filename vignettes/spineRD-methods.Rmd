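---
title: "spineRD: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spineRD: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological model

spineRD simulates dopamine-activated PKA signaling in a dendrite of a
striatal medium spiny projection neuron.  Dopamine binding to D1 receptors
activates Golf; the GTP-bound alpha subunit stimulates adenylate cyclase
type 5, producing cAMP from ATP.  cAMP binds the PKA holoenzyme (R2C2) in
two pairs; the saturated holoenzyme releases its two catalytic subunits
(PKAc) one at a time, through the R2C intermediate.  Free PKAc
phosphorylates Thr34 of DARPP-32 (turning it into a PP1 inhibitor), Ser845
of the AMPA-receptor GluA1 subunit in the PSD, phosphodiesterase 10
(enhancing cAMP degradation, a negative feedback) and the B56-delta
regulatory subunit of PP2A (accelerating dephosphorylation of
phosphoThr75 DARPP-32, a disinhibition loop, since phosphoThr75 inhibits
PKAc by direct binding).  Calcium acts through four routes: direct
inhibition of adenylate cyclase, calmodulin-dependent activation of PDE1B
and of calcineurin (which dephosphorylates phosphoThr34 and phosphoSer845),
calcium binding to the PR72 form of PP2A, and CaMKII activation (which
phosphorylates GluA1 Ser831).  Calcium handling includes calbindin
buffering, PMCA and NCX extrusion, and a constitutive leak.

The network ships as a line-oriented reaction table
(`inst/extdata/reactions.tsv`) of 93 rows that expand to 208 irreversible
elementary mass-action reactions over 109 species.  Three notational
conventions matter:

* `A + 2*X` marks a lumped pair (the two fast or the two slow
  calcium-binding sites of calmodulin; the cAMP pairs binding PKA): the
  propensity is first order in X but two molecules are consumed.  This is
  the convention under which the tabulated basal state is
  flux-consistent (e.g. holoenzyme cAMP binding runs at 3.1 nM/s forward
  vs 3.2 nM/s backward at the tabulated basal concentrations; a
  second-order propensity would be off by more than an order of
  magnitude).
* `A + A` is a true self pair, with stochastic propensity
  `c n (n-1) / 2` (CaMKII subunit pairing into the "Complex" species,
  which therefore carries subunit weight 2 in the CaMKII conserved
  moiety).
* Enzyme rows `E + S <-> ES -> E + P` expand to bind/unbind/catalyze
  elementary steps; the ES complex is a first-class species, so enzyme
  sequestration (e.g. of PKAc by its 36 uM DARPP-32 substrate pool) is
  represented exactly.

Every species declares a subunit composition over 23 conserved moieties
(receptor, G-protein subunits, cyclase, adenine nucleotide, total calcium,
calmodulin, CaMKII subunits, PKA catalytic/regulatory subunits, DARPP-32,
phosphatases, pumps, buffer, GluA1, dopamine).  `conservedMoieties()`
verifies each declared weight vector against the stoichiometric matrix:
all 23 lie exactly in the left null space, which doubles as a
transcription check on the 93 rows.

Two quantities the source tables do not provide were fixed once, from
first principles, before any downstream result was computed:

* PMCA and NCX totals: the constitutive calcium leak at the tabulated
  external and basal calcium concentrations is 3409 nM/s and must be
  balanced by pump efflux at basal calcium (58.7 nM).  With the
  low-affinity exchanger about twice as abundant as the high-affinity
  pump, balance gives pmca = 2500 nM and ncx = 4800 nM
  (whole-morphology equivalents, placed in the submembrane and spine
  subvolumes).
* GluA1 abundance: 100 receptors per PSD, a typical synaptic AMPAR
  complement.  Only the *percent* of phosphorylated GluA1 is reported, so
  this choice scales the readout without changing its dynamics.

## Morphology and diffusion

The short morphology is a 7.75 um dendrite (0.6 x 0.4 um cross-section)
of 310 cuboidal subvolumes (62 axial x 5 lateral, 0.12 x 0.125 x 0.4 um),
with the two lateral edge rows forming the submembrane region — the
rectangular equivalent of a 70 nm shell on a cylindrical dendrite.  Four
spines (0.2 um neck in 0.1 um slices; 0.6 um head as two slices plus a
PSD slice) attach to evenly spaced positions on the top submembrane row;
neck length variants (0, 0.3, 1.0 um) change only the neck chain.
Diffusion is 2-D in the dendrite plane and 1-D along the spine.  The long
morphology is a 22.8 um dendrite of 342 coarser cuboids
(0.2 x 0.2 x 0.4 um) with 12 evenly spaced spines and no submembrane
region (nothing is anchored in that dendrite).

Diffusion between coupled subvolumes uses the finite-volume rate
`k = D A / (V d)` per molecule, which satisfies detailed balance by
construction.  Anchoring is "D = 0 plus region-restricted
initialization": the D1R/G/AC complex occupies the spine-head cytosol or
a focal submembrane block whose volume equals the *total* spine-head
cytosol volume (38 subvolumes, 0.226 um^3 on the short mesh) and whose
molecule totals are copied exactly from the spine-derived counts — so
every anchoring configuration carries identical global amounts *and*
identical local concentrations (the tabulated focal surface densities
decode to exactly this: e.g. the cyclase density times the patch area
reproduces the four-head molecule total to 0.4%).  PKA additionally
occupies the PSD; PDE10 occupies submembrane+spine or is uniform; GluA1
lives only in the PSD.

## Engines

The stochastic engine is a mesoscopic tau-leap: per subvolume, reaction
event counts are Poisson with mean (propensity x dt); diffusion transfers
are conditional-binomial (multinomial across neighbors, which cannot
overdraw a subvolume), with per-species substepping so that a fast
species like calcium (hop rates up to ~17000/s in spine slices) keeps its
hop probability below 0.1 without forcing the whole system to its step.
If a leap would drive any count negative the subvolume redraws at half
the step (up to 5 halvings, then an exact SSA finishes that
subvolume-step).  Moieties are conserved exactly (integer arithmetic);
runs are bit-reproducible under a fixed seed.  In fixed-step mode a hop
probability over 0.1 aborts with the offending species; in adaptive mode
(well-mixed systems) the step is chosen so no species' expected relative
change exceeds 3% per step.

The deterministic engine integrates the same elementary network as
mass-action ODEs (concentration units) with inter-compartment fluxes, via
`deSolve::lsodes` (stiff, sparse Jacobian), piecewise between stimulus
events; clamps reset the state and zero the clamped derivatives, pulse
injections become square-wave sources, and 100 Hz pulse clusters are
merged into a single pulse at the original influx rate lasting the
cluster's total on-time.  This compression preserves both the total
influx and the influx rate — and therefore the calcium concentration
scale seen by the cooperative (two-site) calmodulin steps, which a
duty-cycle average would understate several-fold — at the cost of
shortening the envelope (0.3 s instead of 1.3 s per train).  It is the verification oracle for the
tau-leap engine (well-mixed means agree within 3 SE in the test suite)
and the desk-scale substitute for multi-day stochastic runs.

## Stimulation protocols

* Phasic dopamine: five 1 s, 1 uM transients, 20 s apart, starting at
  t = 50 s.  Under volume transmission (D = 150 um^2/s) the transient is
  a uniform clamp; in gradient mode (D = 50 um^2/s, the 3x slow-down) it
  is a point release into the dendritic subvolumes at the first spine,
  with the rate auto-calibrated against the steady diffusion-removal
  equation so the release-site concentration reaches 1 uM.
* Calcium tetanus: 100 pulses (3 ms on, 10 ms gap, 125 molecules/ms) into
  the PSD of two spines — 37500 molecules per stimulated spine.  When
  paired with dopamine, one tetanus accompanies *each* of the five
  transients (the paired-trial design; the calcium-bound PP2A trace shows
  one discernible pulse per trial).
* Bath clamps hold a species uniformly at a level (validation runs:
  10 uM dopamine, 600 nM calcium).

## Basal state and equilibration

The tabulated initial concentrations are very close to the *spatial*
model's fixed point: with the G-protein/cyclase machinery concentrated in
spine heads, the equilibrated basal cAMP is 36.1 nM against the tabulated
35.6 nM.  Pooling the same totals into one well-mixed compartment dilutes
the nonlinear activation chain and the basal cAMP settles near 2 nM, with
basal phosphoThr34 following.  Consequently:

* well-mixed validation runs equilibrate to the pooled system's own
  steady state (3000 s unstimulated integration) and report fold changes
  against that self-consistent basal;
* long-dendrite gradient runs equilibrate the spatial model for 1500 s
  (basal phosphoThr34 is stationary from ~1000 s) so the fitted baseline
  is meaningful;
* short-dendrite comparative runs (colocalization, Ht31, calcium pairing)
  start from the tabulated basal with a 50 s unstimulated lead-in, since
  both arms of each comparison share any residual relaxation and the
  reported quantities are ratios between arms.

## Readouts

Phospho readouts are group totals (free plus complexed forms carrying the
phosphosite) divided by the volume of the region of interest; GluA1 is
reported as percent of the receptor moiety phosphorylated on Ser845
(irrespective of Ser831).  "PKA activity" is free catalytic subunit
summed (time-integrated) over 50-350 s.  Spatial profiles are
window-averaged per axial bin and fitted with
`C(x) = C0 exp(-x/lambda) + b` by Levenberg-Marquardt least squares.  The
primary decay length fixes `b` at the run's own pre-stimulus stationary
basal: a relaxation profile cannot decay below its own basal, and on a
22.8 um dendrite the free-baseline fit of shallow profiles is ill-posed
(it can return baselines below basal with several-micron standard
errors).  The free-baseline variant is computed and reported alongside.
Flat profiles are flagged non-identifiable rather than fitted.  The
colocalization analysis regresses per-run PKA activity on local cAMP
(averaged at the PKA anchoring site) plus a colocalization indicator by
ordinary least squares.

## Desk-scale presets

Full-fidelity stochastic runs (hundreds of seconds at ~10 us steps on
the full meshes) take days; the desk presets substitute, per scenario:

* well-mixed deterministic runs for the bath validations (seconds);
* spatial deterministic runs on conservatively coarsened meshes for the
  window-averaged comparisons — the short mesh merges axial pairs and
  same-region lateral rows (106 compartments, ~11.5k ODE states), the
  long mesh merges axial triples (74 compartments); coarsening sums
  volumes and crossing areas and recomputes coupling distances between
  volume-weighted centers, so the diffusion operator remains consistent;
* full-mesh stochastic runs where stochasticity is the point: the
  calcium-peak check (334 subvolumes, ~1.6 simulated seconds, ~10 us
  steps) and per-spine variability;
* the coarsest stochastic preset (whole-spine compartments, PSD merged
  into the head, ~15 compartments) for the 4-configuration x 4-trial
  activity regression with a shortened two-pulse protocol.

What the desk presets preserve: the reaction network, anchoring
geometry-by-region, molecule totals, stimulus timing, and the readout
definitions.  What they give up: within-region concentration structure
below the coarsening scale, and trial-to-trial variability wherever the
deterministic substitute stands in — so deterministic comparisons report
ratios of means without error bars, and the test suite checks orderings
and bands rather than seed-level distributions for those scenarios.  The
synthetic-input module emulates reward-like dopamine transients and
LTP-like calcium tetani as idealized square pulses; real dopamine
transients have diffusion-broadened rise and decay, and real NMDA calcium
influx depends on receptor gating, neither of which is modeled (influx is
imposed, not mechanistically gated).

## Known limitations

* Dopamine uptake/transporter kinetics are deliberately absent; the
  extracellular exchange reaction is the only removal path, so gradient
  mode relies on the slowed diffusion constant.
* The deterministic substitute underestimates quantities driven by rare
  fluctuations (e.g. spine-level GluA1 excursions above 20%); those
  claims are checked with the stochastic engine only.
* The 2x2 anchoring comparisons inherit ~percent-level sensitivity to the
  coarsening factor; decay lengths on the long mesh shift by ~7% between
  axial-triple and axial-pair coarsening, well inside the acceptance
  bands used.
* One printed product in the calcineurin row acting on PP1-bound
  phosphoThr34 DARPP-32 is internally inconsistent with its PP2A
  analogues and was corrected to release dephosphorylated DARPP-32 (the
  printed product would make the reaction a no-op).
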