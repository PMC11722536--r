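---
title: "Quantifying persistence vs tolerance with an alarmone-GTP switch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying persistence vs tolerance with an alarmone-GTP switch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bactericidal antibiotic applied to a clonal bacterial culture usually does
not kill it cleanly: survival over time is biphasic, with a fast exponential
phase (the drug-sensitive, growing majority) and a slow plateau phase - a
rare subpopulation of *persisters*, phenotypically dormant cells that are
genetically identical to their neighbours and regrow drug-sensitive once the
drug is removed. Persistence (how many cells are on the plateau) and
tolerance (how slowly the bulk dies) are distinct population traits that
call for distinct statistics; `persistkit` computes both, detects the
single-cell switch that produces persisters, quantifies the rare low-GTP
subpopulation in cytometry data, and ships a stochastic simulator of the
underlying control circuit that generates all three kinds of data.

The biological circuit being modelled: the alarmone (p)ppGpp is synthesized
by several synthetases (a starvation-responsive bifunctional enzyme, a
cooperatively self-amplifying one, and a cell-envelope-stress-induced one).
Alarmone synthesis consumes GTP and, more importantly, alarmone binding
inhibits GTP-biosynthesis enzymes, so rising alarmone depresses GTP. Growth
requires GTP; below roughly 0.1-0.2 mM the cell stops elongating and enters
dormancy. A fluorescent reporter under a CodY-type operator (GTP is the
co-repressor) derepresses as GTP falls, so bright cells are low-GTP cells.
Cooperative self-amplification of alarmone synthesis makes this a positive
feedback loop: a noise excursion in basal synthesis can ignite the loop and
tip a single growing cell into the dormant state.

## The kill-curve model and tolerance statistics

Relative survival is modelled as a two-subpopulation exponential death
process

$$S(t) = (1 - f)\,e^{-k_\mathrm{fast}t} + f\,e^{-k_\mathrm{slow}t},
\qquad k_\mathrm{fast} > k_\mathrm{slow} \ge 0,$$

with persister fraction $f \in [0, 1]$ and rates in h$^{-1}$.

* **Fitting is on log10 survival**, because the plateau spans three or more
  decades: a linear-scale objective would be dominated entirely by the first
  time point. Replicates enter as the per-time mean of log10 survival.
* **Multi-start**: the objective is multimodal in $f$, so optimization is
  started from a coarse grid ($f$ over 7 log-spaced values in
  $10^{-5}..10^{-0.3}$, $k_\mathrm{fast}$ over 6 log-spaced values in
  0.5-20 h$^{-1}$, $k_\mathrm{slow} \in \{0, 0.01, 0.1\}$ h$^{-1}$), the
  best 8 starts are polished by bounded L-BFGS-B on the transformed scale
  $(\log_{10} f,\ \log_{10} k_\mathrm{fast},\ k_\mathrm{slow}/k_\mathrm{fast})$,
  which enforces the ordering constraint by construction.
* **A degenerate ridge** exists at $k_\mathrm{slow} \to k_\mathrm{fast}$,
  where any $f$ reproduces a single exponential. The fitter therefore also
  evaluates the explicit single-exponential boundary candidate (a linear
  regression on log survival, $f$ at its lower bound $10^{-8}$) and prefers
  it whenever it fits within $10^{-6}$ squared-log10 units of the best
  interior point. This matters only for curves with no detectable plateau.
* **Censoring**: CFU counts below the detection limit are replaced by
  LOD/2 and flagged; they can be excluded from fitting via
  `opts$include_censored = FALSE`. Plates with zero colonies are an
  unavoidable reality of plateau-depth counting; the LOD/2 convention keeps
  them in the fit without pretending to precision. Note that a noiseless
  curve sampled after its counts fall below the LOD is *not* noiseless any
  more - the detection floor flattens the tail.

Tolerance is summarized by the **persister-subtracted MDK99**: the minimum
duration of killing for 99% of the *sensitive* subpopulation,
$\ln(100)/k_\mathrm{fast}$. Subtracting the persister plateau first is the
point: without it, a high plateau masquerades as extreme tolerance. The
bulk MDK99 (first crossing of 1% by the interpolated mean survival,
log-linear between sampled points - exact for exponentials) is reported
alongside, and flagged "not reached" when $f \ge 0.01$. Persistence is
reported both as the model plateau $f$ and as the raw mean survival at a
reference time, default 5 h, because the literature uses both conventions.
Condition contrasts use Welch's $t$ on per-replicate log10 survival (the
source protocols say only "Student's t" without a variance assumption;
Welch is the safer default).

## Single-cell dormancy entry

The per-interval specific growth rate uses the interval-start length,
$\mu_i = (l_{i+1} - l_i)/(l_i\,\Delta t_i)$ - the discrete form of
$\mu = (1/l)\,\mathrm{d}l/\mathrm{d}t$ - with intervals that end in a
division omitted (a size reset is not growth). Detection choices, none of
which are dictated by the source protocols, and their defaults:

* smoothing: rolling median, window 3 frames, robust to single-frame
  segmentation glitches without erasing a genuine step;
* arrest: first run of $\ge 3$ consecutive intervals (45 min at 15-min
  framing) with smoothed $\mu < 0.2 \times$ the population median - long
  enough to exclude transient slowdowns, short enough to time the entry to
  one frame;
* reporter threshold: sustained ($\ge 2$ frames) crossing of the
  cytometry-module gate value for the same dataset, keeping the microscopy
  and cytometry analyses consistent;
* switch-like vs graded: an entry is switch-like when the smoothed rate
  falls $\ge 5$-fold across $\le 2$ intervals anywhere in a window around
  the arrest; a monotone decline slower than that is graded. The window
  matters: comparing only the pre-arrest maximum with the first
  below-threshold interval misclassifies genuinely abrupt entries whose
  first sub-threshold frame is mid-collapse.

The *precedence test* asks whether the reporter rose before growth stopped:
the fraction of events with positive lag ($t_\mathrm{arrest} -
t_\mathrm{threshold}$) and a one-sided sign test, ties dropped.

The pooled growth-reporter relationship is summarized by one point per
trace (medians of the last 7 frames) and fitted with (i) a four-parameter
variable-slope logistic in $\log_{10}$ fluorescence and (ii) a straight
line, selected by small-sample-corrected AIC. Per-trace summary points -
not per-frame pooling - are used deliberately: with thousands of per-frame
points AICc detects arbitrarily mild curvature, and the comparison stops
being about the shape of the relationship.

## Cytometry tail gating

Autofluorescence (measured on a reporterless control acquired with the same
settings) is subtracted as a mean shift with clipping at zero, and the
bright-cell gate is $k$-fold above the arithmetic mean of the corrected
values, default $k = 5$. The mean - not the median - defines the gate,
exactly per the standard rule; since corrected values are clipped at zero,
the mean is computed on the clipped values. The gate is scale invariant and
its fraction is non-increasing in $k$; both are tested. Induced persistence
is the plain difference of tail fractions after minus before induction;
negative deltas are returned with a warning flag rather than clamped, so no
information is destroyed. Tail heaviness is summarized by the
99.9th-percentile-to-median ratio and excess kurtosis.

## The simulator

Per-cell state: GTP $G$ (mM), alarmone $P$ (mM), reporter $F$ (a.u.),
length $l$ (um). The committed closure:

$$v_\mathrm{syn}(P, G) = \left[\beta_0(t) + \beta_1\frac{P^h}{K_P^h + P^h}
 + \beta_2\,\mathbf{1}_\mathrm{induction}\right]\frac{G}{K_\mathrm{sub}+G}$$

$$\dot P = v_\mathrm{syn} - \delta_P P, \qquad
\dot G = \frac{\alpha_G}{1 + P/K_i} - \gamma\,v_\mathrm{syn} - \mu(G)\,G$$

$$\mu(G) = \mu_\mathrm{max}\frac{G^m}{G_\mathrm{th}^m + G^m}, \qquad
\dot F = a_F\frac{K_F^q}{K_F^q + G^q} - (\mu + d_F)F, \qquad
\dot l = \mu l$$

with division at twice birth length (one daughter kept) and death hazard
under antibiotic $k(\mu) = k_\mathrm{min} + (k_\mathrm{max} -
k_\mathrm{min})\,\mu/\mu_\mathrm{max}$ - growing cells are killed fast,
dormant cells barely at all. The hazard's linear form is a modelling choice;
the data behind it show only the two ends (growing cells rapidly killed,
non-growing bright cells surviving).

Only two quantities are anchored to published estimates: the cooperativity
of self-amplified synthesis, $h = 3$, and the growth-threshold GTP range,
$G_\mathrm{th} = 0.15$ mM within the estimated 0.1-0.2 mM. Every other
constant is a calibration choice committed to
`inst/extdata/sim_params.yaml` and versioned; the acceptance tests
reference the configuration, not hard-coded literals.

Design decisions that shape the model's behaviour:

* **Shallow growth law, $m = 1$.** The growth-vs-GTP relationship observed
  in alarmone-free (gmk-compensated) cells is linear, so the intrinsic
  growth law is kept Michaelis-like. Wildtype switch-like entries emerge
  from the *bistable collapse of GTP*, not from an ultrasensitive growth
  law - which is the circuit-level claim the simulator exists to embody.
* **Bistability by cooperativity.** With the shipped wildtype constants the
  deterministic skeleton (GTP at quasi-steady state given alarmone) has
  three fixed points - growing ($G^* \approx 0.61$ mM,
  $\mu \approx 0.8\,\mu_\mathrm{max}$), threshold (unstable), and dormant
  ($G^* \approx 0.008$ mM, $\mu \approx 5\%\,\mu_\mathrm{max}$). Setting
  $h = 1$ with all else equal collapses the count to one: no cooperativity,
  no bistable switch. The alarmone turnover rates were chosen so that the
  barrier region is genuinely unstable once crossed (commitment in tens of
  minutes); flatter parameterizations have a quasi-neutral barrier whose
  crossing takes longer than any experiment.
* **Noise.** Basal synthesis $\beta_0$ carries mean-reverting
  (Ornstein-Uhlenbeck) noise, amplitude $\sigma$ (stationary sd) and
  correlation time 30 min, clipped at zero; rare sustained excursions above
  the saddle-node value ignite the feedback - spontaneous persistence is
  noise-driven escape over the threshold. A second, independent OU noise on
  the GTP supply $\alpha_G$ provides the cell-to-cell growth-rate and
  reporter heterogeneity that real populations show; it is also what gives
  feedback-less genotypes their graded GTP excursions. $\sigma$ is
  calibrated so the simulated wildtype kill plateau sits near 0.1% of the
  initial population.
* **Integration.** Explicit Euler-Maruyama, default $\Delta t = 0.1$ min
  (all rates $\le 0.05$/min, so per-step relative changes stay well below
  1%). The compiled kernel and the R reference `sim_step()` perform the
  identical update in the identical random-number order; the suite checks
  exact agreement, and checks the noise-free trajectory against an adaptive
  reference integrator (0.1% over 500 min at $\Delta t = 0.02$). A step
  that moves a state variable by more than half its characteristic scale
  aborts with advice to reduce $\Delta t$.
* **Genotype presets.** `ppGpp0` zeroes all synthesis *and its noise*
  (there is no enzyme to be noisy), so $P \equiv 0$ exactly. `ppGpp0_gmk`
  additionally lowers the GTP supply so its time-averaged GTP matches the
  wildtype preset (within 10%), with a somewhat larger supply noise
  representing the mutant's uncompensated GTP excursions - this preset
  yields the graded, linear growth-reporter relationship. `sasB_null_or_F42A`
  removes self-amplification ($\beta_1 = 0$); `rel_syn` halves basal
  synthesis; `guaB_down` reduces supply in a wildtype background;
  `sasA_induction` arms the antibiotic-induced synthesis channel
  ($\beta_2$, active only during induction windows), calibrated so a 60-min
  sublethal pretreatment gives roughly five-fold more persisters at the
  5-h lethal readout. The pretreated and untreated arms run the identical
  time-matched schedule - only the sublethal induction differs - because
  spontaneous switching accumulates with culture age and an age-mismatched
  control would confound the contrast.
* **Reporter timing.** The reporter derepresses below
  $K_F = 0.2$ mM with steepness $q = 4$: deep enough that the 5x-mean gate
  captures committed low-GTP cells rather than transient excursions, yet
  the collapse trajectory spends enough time between $K_F$ and
  $G_\mathrm{th}$ that fluorescence crosses the gate threshold one to
  several frames *before* growth arrest - the precedence property.
* **Carbon-source panel.** Five conditions vary the supply rate (growth
  rate) and the basal-synthesis noise independently and incoherently, the
  way media quality and stress vary across carbon sources; on this panel
  the bright-tail fraction correlates with 5-h survival but not with growth
  rate. This panel is the simulator's embodiment of the
  persistence-tolerance decoupling; the assertion is about simulator data
  only.
* **Serial passage** initializes a stationary-like population (alarmone
  spread around the unstable threshold), then repeatedly regrows and
  dilutes. Dilution is weighted resampling with probability proportional to
  each cell's expected offspring number, which reproduces bulk frequency
  dynamics at single-cell resolution. Triggered dormant cells are overgrown
  and wash out; the plateau that remains is the spontaneous rate.
  Resuscitation (slow alarmone decay restoring GTP in dormant cells) is
  disabled by default - the dormant state is a true fixed point.

Problem sizes used by the tests and the acceptance script: $10^5$ cells for
the genotype kill-curve contrast, $2\times 10^4$ for panel/passage/induction
runs, 5000-8000 cells with ~100 recorded tracks for single-cell runs, 20
seeded replicates for the model-selection rates. These sizes put the
Monte-Carlo error of a $10^{-3}$ plateau near 10% while keeping a full run
in minutes on one core.

## What the generator does and does not emulate

Emulated: biphasic survival with a plateau subpopulation and Poisson count
noise plus a lognormal replicate effect; heavy-tailed reporter
distributions with a rare bright tail over a lognormal autofluorescence
background; trajectories in which reporter rise precedes abrupt arrest
(wildtype) or accompanies a graded slowdown (feedback-less); induction and
passage protocols.

Not emulated: lineage structure (one daughter is kept at division, so
tracks are mother lines and the population has no genealogy);
cell-cycle-dependent growth-rate structure; image-analysis artifacts beyond
multiplicative length/fluorescence noise (no segmentation failures, no
focus drift); cytometry doublets, debris or scatter-gate spillover;
drug pharmacokinetics (the hazard switches on instantaneously);
resuscitation kinetics after drug removal. Passing tests therefore show
that the *analysis* correctly recovers what the *model* generates - they do
not certify performance on artifacts real instruments add.

## Known limitations

* The two-exponential fit reports no confidence intervals (the `ci` slot is
  reserved); replicate scatter is summarized separately.
* $f$ and $k_\mathrm{fast}$ are identifiable only when the sampling design
  brackets both phases; fits on plateau-dominated or censored-tail designs
  return boundary or floor values, which is visible in `sse_log` and the
  censoring flags rather than silently wrong.
* The arrest detector's 45-min run requirement delays the nominal arrest
  time by construction; lags should be interpreted relative to it.
* The simulator's absolute concentration and rate scales are calibration
  choices; only the cooperativity and the GTP threshold range carry
  external meaning. Conclusions should rest on contrasts between presets,
  not on absolute simulated numbers.
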