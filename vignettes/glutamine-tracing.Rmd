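---
title: "Methods: steady-state isotope tracing of glutamine/glutamate metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state isotope tracing of glutamine/glutamate metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glntrace)
```

This vignette is the package's account of its models: what is assumed, which
parameters matter, what the synthetic-data generator does and does not
emulate, and where genuinely open design choices were resolved.

## 1. Mass-isotopomer distributions and natural-abundance correction

An isotopologue assay for a metabolite with $n$ tracer-accessible atoms
reports fractional abundances $M_0 \dots M_n$ by mass shift. The measured
vector is contaminated by naturally occurring heavy isotopes in *every* atom
of the molecule. We model measurement as a linear operator $M$: column $j$
is the expected envelope of a species carrying exactly $j$ tracer-derived
heavy atoms — a $\mathrm{Binomial}(j, \text{purity})$ shift from the tracer
positions convolved with the natural envelope of all remaining atoms.
Correction solves

$$\hat{x} = \arg\min_{x \ge 0} \lVert Mx - \text{raw} \rVert_2^2,$$

renormalized to the simplex. Non-negative least squares
(`pracma::lsqnonneg`) was chosen over matrix inversion because inversion of
the nearly triangular $M$ amplifies noise in the high-shift tail into
negative abundances that must then be clipped, biasing the renormalization;
NNLS handles the constraint inside the optimization.

Parameters: the default isotope table uses standard terrestrial abundances
(¹³C 0.0107, ¹⁵N 0.00364, ²H 1.15·10⁻⁴, ¹⁷O/¹⁸O at +1/+2, sulfur up to +4);
any element can be overridden, e.g. to a locally measured ¹³C baseline.
Tracer purity defaults to 1 and is exposed because vendor enrichment
certificates vary; purity enters below the matrix diagonal only.
All elements of the formula are corrected by default; restricting the
formula to carbon reproduces a carbon-only correction when desired.

For the dual-isotope glutamine tracer, glutamate carries five ¹³C and one
¹⁵N tracer shift. The correction matrix takes a named tracer-atom vector
(`c(C = 5, N = 1)`); the residual natural envelope of column $j$ assigns
heavy atoms to elements in the order given. The assignment only changes
which single atom is removed from the natural pool, a sub-10⁻⁴ perturbation
of the envelope.

## 2. The atom-mapped network and its steady state

The simulator's network covers glutamine uptake, glutaminase (amide
nitrogen released), glutamine synthetase, glutamate–αKG transamination
against a well-mixed amino-nitrogen pool, oxidative TCA flux (αKG C1 lost
as CO₂; succinate and fumarate symmetric), reductive IDH
(αKG + CO₂ → citrate), citrate synthase and ATP-citrate lyase (exact
inverses, so the lipogenic acetyl-CoA lineage is αKG C4/C5), malic enzyme,
PDH, pyruvate carboxylase, glycolysis, lactate release, the
glutamate–P5C–proline/ornithine axis with media uptake and catabolism,
unlabeled anaplerotic influxes (pyruvate, acetyl-CoA, OAA — serum- and
amino-acid-derived carbon that dilutes the glycolytic pools), and
protein/biomass sinks. Every reaction is atom-complete: each substrate atom
appears in some product (CO₂ and sinks are explicit external outlets), so
label is conserved reaction by reaction and, at the fixed point, tracer-atom
inflow equals outflow — a property the test suite checks on the packaged
presets.

Labeling states are full positional isotopomer vectors (up to $2^7$ states
for glutamine: 5 carbons + 2 nitrogens). The steady state solves the
balance: each internal metabolite's distribution is the flux-weighted
mixture of its producers' mapped outputs, with joint substrate
distributions formed under independence. This fixed point is found by
Gauss–Seidel sweeps; symmetric skeletons are scrambled by averaging with
their carbon-reversed image after every update.

Assumptions worth stating plainly:

* **Steady state, single endpoint.** The study design samples one 24-h
  endpoint of near-confluent, quiescent cultures; fractional readouts are
  therefore modeled at the isotopic steady state rather than by kinetic
  ODEs. No turnover times are predicted.
* **One compartment.** Cytosolic and mitochondrial pools are merged; a
  single acetyl-CoA and a single αKG pool exist. Pathway-route readouts
  (M5 citrate etc.) survive this merge, but compartment-specific dilution
  does not.
* **Pool independence.** Joint substrate labeling is the product of the
  marginals — exact for well-mixed pools, approximate if substrate pairs
  are channeled.
* **Linear media balance.** Media concentrations change linearly with time
  (no depletion feedback); a harvest concentration driven negative raises
  an error instead of being clamped.

Numerical choices: convergence tolerance $10^{-10}$ on the per-sweep
maximum L1 change, sweep limit 2000 (presets converge in well under 100);
each update is renormalized to the probability simplex because round-off in
the joint outer products otherwise compounds multiplicatively across sweeps
at high exchange fluxes. Uniform scaling of all fluxes leaves the fixed
point unchanged (only ratios matter), which the tests assert.

## 3. Condition presets as calibration products

The network needs absolute fluxes only to generate measurements; the
literature for this system prints fractional readouts, not fluxes. The
packaged presets (`hepl_fluxes()`, `hdf_fluxes()`, `phh_fluxes()`) were
therefore *calibrated once*: free fluxes were fitted so that the steady
state of the hepatocyte-like condition reproduces the published composition
of secreted glutamate (71% glutamine-, 15% glucose-derived carbon) and the
glutamine re-secretion split (58% returned as glutamate of a
3.26 µmol·mg⁻¹·day⁻¹ uptake), and the fibroblast condition reproduces the
published contrasts against it (half the glutamine uptake, 14-fold higher
labeled proline, 1.7-fold higher biomass ¹³C incorporation, 1/1.53 of the
lipogenic acetyl-CoA enrichment under 5-¹³C-glutamine). After calibration
the fluxes were frozen; every analysis stage sees only simulated noisy
measurements, never the calibration targets.

Two magnitudes are free parameters that the printed values do not pin down,
and were set by design reasoning:

* **Lipogenic acetyl-CoA enrichment `D`.** The published ISA comparison
  resolved a 53% between-condition difference at n = 7 with small
  replicate scatter, which bounds the labeling signal from below: at
  `D ≈ 0.01` the myristate M1 signal would drown in 1% measurement noise.
  The hepatocyte-like preset is calibrated to `D = 0.10` under
  5-¹³C-glutamine — a plausible glutamine-via-reductive-carboxylation share
  of lipogenic acetyl-CoA for cells in which that route dominates glutamine
  lipogenesis.
* **Well geometry.** 1 mL media per well; 0.4 mg protein for the
  hepatocyte-like and primary-hepatocyte conditions, 0.6 mg for the denser
  fibroblast cultures. Error propagation fixes these: a rate assay that
  subtracts two concentrations, each with 5% noise on a 2 mM pool, resolves
  a rate only if the 24-h depletion is a substantial fraction of the pool
  (~49% and ~65% of media glutamine here). Smaller wells would leave the
  fibroblast depletion at the noise floor, inconsistent with the clean
  published rate data.

Other fixed measurement scales: biomass enrichment is
`baseline + 0.05 × Σ (protein-sink flux × mean labeled carbons)` atom-%
points with the published unlabeled baseline 1.0799 atom-%; labeled-pool
ion currents are `10⁶ × labeled fraction` EIC per mg, with equal pool sizes
across conditions assumed (so pool contrasts reflect flux contrasts);
`g = 0.5` of the fatty-acid pool is newly synthesized over the 2-day
labeling.

## 4. What the generator emulates — and what it does not

Emulated: the four tracer designs; blank/harvest media concentrations with
multiplicative noise (default CV 0.05); uncorrected MIDs = steady-state
MIDs pushed through the natural-abundance measurement operator, perturbed
by multiplicative channel noise (default CV 0.05) and renormalized; media
glutamate as a mixture of the pre-existing unlabeled 54 µM pool and secreted
intracellular glutamate; labeled proline/ornithine pools as EIC per mg;
biomass ¹³C atom-percent; myristate MIDs from the ISA forward model with
`D` taken from the steady-state acetyl-CoA pool. All randomness flows from
one integer seed.

Not emulated: peak integration and identification artifacts (coelution,
detector saturation, missingness mechanisms other than the uniform rate in
the feature-table generator), inter-batch drift, compartmentation,
depletion-driven nonstationarity, and biological replicate-to-replicate
flux variability (noise is purely of measurement type). Passing
parameter-recovery tests therefore demonstrates that the analysis stages
are correct and unbiased under the stated error model — not that they are
robust to every pathology of real LC-MS data.

## 5. ISA model and fitting

The forward model treats myristate as 7 acetyl units:

$$\text{MID} = (1-g)\,\text{nat}(\text{C}_{14}\text{H}_{28}\text{O}_2)
  + g\,\left[\left(D\,\delta_s + (1-D)\,\text{nat}(\text{C}_s)\right)^{*7}
  \ast \text{nat}(\text{residual atoms})\right]$$

with $s = 2$ for uniformly labeled glutamine-derived acetyl and $s = 1$ for
5-¹³C-glutamine-derived acetyl. MIDs are fitted *uncorrected*; natural
abundance lives inside the model (pre-existing pool, unlabeled portion of
each unit, non-tracer atoms), so odd shifts under $s = 2$ still carry
information and are kept in the residual. Fitting is bounded least squares
on $(D, g) \in [0,1]^2$, multistarted from a 5 × 5 interior grid; replicates
are stacked into a joint residual by default. The multistart spread is
reported as an identifiability diagnostic: at $g \to 0$ the likelihood is
flat in $D$, which surfaces as a large `D_spread` rather than a spuriously
confident estimate. The published "rate" comparison between conditions is
interpreted as the labeled-synthesis product $D \times g$ — the fraction of
acetyl units that are both newly incorporated and tracer-derived — because
$D$ and $g$ separately trade off at low signal while their product is well
identified; all three metrics are available in `compare_conditions()`.

## 6. Rates, apportionment and the M1 trap

Exchange rates use the blank-minus-harvest convention (positive = uptake,
negative = secretion) normalized per mg protein and per 24-h day regardless
of actual incubation length. Replicate-level rates are aggregated as means
before ratios are formed. The de novo secreted MID removes the pre-existing
unlabeled media pool by concentration-weighted subtraction, valid for net
producers under the linear media model.

The dual-tracer apportionment computes each labeled share within its own
experiment (M5+M6 under the glutamine tracer, M2+M3 under the glucose
tracer) and attributes the remainder to other sources. Two deliberate
guards: glutamate M1 under the glutamine tracer is ¹⁵N on an unlabeled
carbon skeleton and counts toward *non*-glutamine carbon — summing it into
the glutamine share is the single easiest implementation mistake in this
assay; and combining experiments assumes equal net secretion, so a >20%
disagreement between the experiments' secretion rates warns.

## 7. Screen and power analysis

The untargeted screen mirrors the published procedure: features present in
all samples of at least one group are kept (no imputation), Welch's
two-sided t-test on log2 intensities per feature, Benjamini–Hochberg
adjustment (the multiple-testing method of the original analysis software
is unstated; BH is the defensible default), and joint thresholds FC > 2,
FDR < 0.005. Fold change uses raw group means, two-sided. Sample-size
estimation is by Monte-Carlo simulation of the Welch test over increasing
n, returning the smallest n reaching the target power; the closed-form
pooled-t power calculation serves as its cross-check in the tests (the two
diverge at n = 2–3 where the Welch degrees of freedom collapse).

## 8. Known limitations

* Fate assignments are derived for the packaged network topology; exotic
  user networks may create additional routes to the same mass shifts, which
  the mechanical derivation will report but the packaged pathway names may
  not describe well.
* The simulator's αKG/citrate concentration ratio readout is input-side:
  pool concentrations are not state variables of a flux model, so
  `reductive_index()` operates on user-supplied concentrations only.
* NNLS correction is biased at the simplex boundary for very noisy tails
  (abundances cannot go negative, so pure noise accumulates slightly
  positive mass); at the default 5% channel noise this bias is far below
  the replicate scatter.
* Problem sizes were chosen for exactness, not scale: full isotopomer
  vectors are enumerated (≤ 2⁷ states per metabolite), which is exact and
  fast for this network but would need an EMU-style decomposition for
  skeletons beyond ~15 tracked atoms.
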