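# Default parameterization of the alarmone-GTP switch simulator.
# Units: concentrations mM, time min, rates mM/min or /min; kill rates /h;
# reporter a.u.; lengths um. Only two quantities are anchored to published
# estimates: the feedback Hill coefficient h (~3) and the growth-threshold
# GTP concentration G_th (~0.1-0.2 mM). Everything else is a calibration
# choice committed here and versioned with the package.
default:
  h: 3.0            # Hill coefficient of cooperative feedback activation
  K_P: 0.2          # feedback half-activation alarmone level (mM)
  beta0: 1.0e-3     # mean basal alarmone synthesis rate (mM/min)
  sigma: 3.5e-4     # OU amplitude (stationary sd) of basal synthesis noise
  tau: 30.0         # OU correlation time of basal synthesis noise (min)
  beta1: 8.0e-3     # maximal feedback (self-amplified) synthesis rate (mM/min)
  beta2: 0.0        # antibiotic-induced (SasA-like) synthesis rate (mM/min)
  delta_P: 0.02     # alarmone hydrolysis rate (/min)
  alpha_G: 0.03     # mean GTP supply rate (mM/min)
  sigma_alpha: 3.0e-3  # OU amplitude of supply noise (mM/min)
  tau_alpha: 60.0   # OU correlation time of supply noise (min)
  K_i: 0.05         # supply-inhibition constant by alarmone (mM)
  gamma: 1.0        # GTP consumed per alarmone synthesized
  K_sub: 2.0e-3     # substrate (GTP) limitation constant of synthesis (mM)
  G_th: 0.15        # growth half-threshold GTP (mM), within 0.1-0.2
  m: 1.0            # growth-law steepness (shallow; switch-like behaviour emerges from the bistable GTP collapse, not from an ultrasensitive growth law)
  mu_max: 0.025     # maximal specific growth rate (/min), ~28 min doubling
  a_F: 10.0         # maximal reporter synthesis rate (a.u./min)
  K_F: 0.2          # reporter half-derepression GTP (mM); below the growth threshold so the gate captures committed low-GTP cells
  q: 4.0            # reporter repression steepness
  d_F: 5.0e-3       # reporter degradation/bleaching rate (/min)
  k_max: 5.0        # death rate of fully growing cells under antibiotic (/h)
  k_min: 0.02       # death rate of fully dormant cells (/h)
  dt: 0.1           # integration step (min)
  l_birth: 2.0      # birth length (um); division at 2x birth length
  dormant_mu_frac: 0.1   # dormancy flag: mu below this fraction of mu_max
  meas_sd_length: 0.015  # multiplicative measurement noise sd on length
  meas_sd_fluor: 0.25    # multiplicative measurement noise sd on fluorescence
  af_mean: 5.0           # autofluorescence mean (a.u.)
  af_sd: 1.5             # autofluorescence sd (a.u.)
presets:
  wildtype: {}
  ppGpp0:            # no alarmone synthetases: no synthesis, no synthesis noise
    beta0: 0.0
    beta1: 0.0
    beta2: 0.0
    sigma: 0.0
  ppGpp0_gmk:        # additionally gmk down-mutation: supply reduced so that
    beta0: 0.0       # mean GTP matches the wildtype preset mean; larger supply
    beta1: 0.0       # noise reflects the mutant's graded, uncompensated GTP
    beta2: 0.0       # excursions
    sigma: 0.0
    alpha_G: 0.0124
    sigma_alpha: 3.8e-3
  sasB_null_or_F42A: # no cooperative self-amplification
    beta1: 0.0
  rel_syn:           # reduced basal synthesis
    beta0: 5.0e-4
  guaB_down:         # reduced GTP supply in an otherwise wildtype background
    alpha_G: 0.021
  sasA_induction:    # antibiotic-inducible synthetase armed
    beta2: 9.0e-4
# Carbon-source-like growth conditions: media of different quality vary both
# the GTP supply (growth rate) and the basal-synthesis noise (persistence),
# and do so incoherently, mirroring the observed decoupling of persistence
# from growth rate across media.
carbon_panel:
  glucose_caa:   {alpha_G: 0.036, sigma: 2.8e-4}
  glucose:       {alpha_G: 0.030, sigma: 3.9e-4}
  glycerol:      {alpha_G: 0.024, sigma: 2.8e-4}
  succinate:     {alpha_G: 0.020, sigma: 3.7e-4}
  malate_poor:   {alpha_G: 0.016, sigma: 3.1e-4}
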