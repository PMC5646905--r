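# Benchmark scenario parameters.
#
# Calibration targets (realised OCV, mean firing rate, ground-truth spike
# phase locking) are stated per preset; the perturbation scales, depths and
# drive offsets below were calibrated once, by simulation at large trial
# counts, to realise those targets and are then fixed. The amplitude
# irregularity C_A is taken as large as the OCV target permits (the envelope
# carries most of the irregularity, including occasional sign reversals),
# with the phase-rate perturbation C_xi covering the remainder. AR(1)
# timescales for the phase/amplitude perturbations are one nominal
# oscillation period.

fig2:
  # targets: ~40 Hz firing, 15 Hz modulation, OCV ~0.13, spike-phase R ~0.22
  generator: lif
  nu: 15.0
  dt: 0.001
  duration: 1.0
  M: 60
  C_xi: 0.02
  C_A: 0.35
  depth: 18.0
  ar1_timescale: 0.0667
  mu: 41.5
  tau: 0.2
  sigma_b2: 0.2
  f_amp: 3.0
  f_center: 0.5
  f_sd: 0.15

fig3a:
  # targets: ~40 Hz firing, 10 Hz modulation, OCV ~0.18
  generator: renewal
  nu: 10.0
  dt: 0.001
  duration: 1.0
  M: 60
  C_xi: 0.03
  C_A: 0.35
  depth: 0.5
  ar1_timescale: 0.1
  mu: 3.0
  refractory:
    hard: 0.003
    inhibition: 3.0
    inhibition_tau: 0.008
    rebound: 0.4
    rebound_tau: 0.04
    support: 0.1

fig6:
  # targets: ~60 Hz firing, 20 Hz modulation, OCV ~0.14
  generator: renewal
  nu: 20.0
  dt: 0.001
  duration: 1.0
  M: 60
  C_xi: 0.02
  C_A: 0.36
  depth: 0.5
  ar1_timescale: 0.05
  mu: 3.55
  refractory:
    hard: 0.002
    inhibition: 2.0
    inhibition_tau: 0.005
    rebound: 0.0
    rebound_tau: 0.02
    support: 0.05

fig8:
  # targets: ~22 Hz firing, 20 Hz modulation, OCV ~0.27, flat PSTH,
  # 50% duty square-wave slow offsets (exponential durations, 100 ms min)
  generator: renewal
  nu: 20.0
  dt: 0.001
  duration: 1.0
  M: 200
  C_xi: 0.03
  C_A: 0.42
  depth: 0.6
  ar1_timescale: 0.05
  mu: 2.0
  square_wave: true
  duty: 0.5
  mean_state_duration: 0.25
  levels: [-0.75, 0.75]
  refractory:
    hard: 0.002
    inhibition: 2.0
    inhibition_tau: 0.005
    rebound: 0.0
    rebound_tau: 0.02
    support: 0.05

fig9:
  # targets: ~36 Hz firing, 20 Hz modulation, OCV ~0.32, 80 trials of 1.2 s,
  # a fraction of trials weakly modulated (strength s0)
  generator: renewal
  nu: 20.0
  dt: 0.001
  duration: 1.2
  M: 80
  C_xi: 0.03
  C_A: 0.46
  depth: 0.6
  ar1_timescale: 0.05
  mu: 2.82
  weak_fraction: 0.25
  s0: 0.1
  refractory:
    hard: 0.002
    inhibition: 2.0
    inhibition_tau: 0.005
    rebound: 0.0
    rebound_tau: 0.02
    support: 0.05
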