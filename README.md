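# swayagree

Can cheap consumer balance boards stand in for a laboratory force plate in
quiet-stance posturography — and can several such boards be used
**interchangeably**? `swayagree` implements the full measurement-agreement
pipeline for that question: from raw load-cell / force-plate recordings to
center-of-pressure (CoP) trajectories, nine stabilometric parameters, and
the device-agreement statistics, plus a synthetic paired-device study
generator so the entire chain is testable without hardware.

It is aimed at movement scientists and rehabilitation researchers running
method-comparison studies, and at anyone who needs tested reference
implementations of the standard posturographic quantities.

## The method

**Conditioning.** A board trial is four corner loads `TL, TR, BL, BR` (N);
the CoP follows from the quad-cell moment balance

    ml = (s_ml/2) * ((TR+BR) - (TL+BL)) / ΣF
    ap = (s_ap/2) * ((TL+TR) - (BL+BR)) / ΣF

with sensor spans `s_ml = 433`, `s_ap = 238` mm. A force-plate trial is a
wrench `(Fx, Fy, Fz, Mx, My, Mz)`; the CoP at the contact surface a height
`dz` above the moment origin is `ml = (−My − Fx·dz)/Fz`,
`ap = (Mx − Fy·dz)/Fz`. Both signals are resampled to a uniform 1000 Hz
grid by linear interpolation and low-pass filtered with a zero-phase
(forward–backward) 2nd-order Butterworth at 12 Hz.

**Nine parameters** per trial: total sway path DOT (mm); 95% prediction
ellipse area `π·χ²₀.₉₅(2)·√det S` (mm²); per-axis dispersion RMS_AP/RMS_ML
(mm); per-axis amplitude AdCP = max−min (mm); per-axis mean velocity MV
(mm/s); total mean velocity TMV = DOT/duration (mm/s).

**Agreement battery** on per-trial force-plate − board differences:
two-way random-effects ICC(2,1) and ICC(2,k) across devices with F-based
confidence bounds (trial-level 18×4 and subject-mean 6×4 granularities);
Friedman repeated-measures tests across devices; pooled 95% limits of
agreement (mean ± 1.96·SD) with an out-of-limit contingency table
(parameter × device) and Pearson chi-square; per-device Spearman
correlations between plate and board values.

**Synthetic studies.** Quiet stance is modeled as a 2-D Ornstein–Uhlenbeck
process (per-axis relaxation time τ, stationary SD `√(Dτ/2)`); each trial's
truth is observed simultaneously by an exact inverse-load-split board model
(with gain/offset miscalibration, noise, quantization, jittered low-rate
sampling) and a force-plate wrench model, for a full subject × device ×
trial crossover.

## Worked example

```r
library(swayagree)

scenario <- default_scenario(seed = 20260924, trial_duration = 30)
study <- generate_synthetic_study(
  design = scenario$design, sway = scenario$sway,
  population = scenario$population, boards = scenario$boards,
  plate = scenario$plate, seed = scenario$seed)
met <- study_metrics(study)
report <- run_interchangeability_study(met$fp, met$board,
                                       design = scenario$design)
print(report)
```

prints (with `seed = 20260924`, the seed used by the `analysis/` scripts;
abridged):

```
<agreement_report> 6 subjects x 4 devices x 3 trials

ICC(2,1) on FP-board differences across devices:
  dot       0.977 [ 0.953,  0.990]
  area      0.889 [ 0.791,  0.951]
  rms_ap    0.897 [ 0.805,  0.955]
  rms_ml    0.894 [ 0.800,  0.954]
  adcp_ap   0.821 [ 0.680,  0.919]
  adcp_ml   0.813 [ 0.665,  0.915]
  mv_ap     0.939 [ 0.881,  0.974]
  mv_ml     0.941 [ 0.884,  0.975]
  tmv       0.977 [ 0.953,  0.990]

Friedman across devices (p-values):
  dot      p = 0.753
  ...
  tmv      p = 0.753

Out-of-limit observations: 29 of 648 (4.5%); chi-square p = 0.928
Mean FP-board Spearman rho: 0.993
```

Reading: ICC near 1 means the plate−board difference is consistent across
the four boards (interchangeable up to a shared bias); Friedman p > 0.05
means no board ranks systematically apart; ~5% of differences outside the
95% limits is what the limits-of-agreement convention predicts; the
chi-square checks whether those exceedances concentrate on one board.

The same workflow as numbered file-based stages:

```sh
Rscript analysis/01_simulate.R     # corpus -> results/corpus/
Rscript analysis/02_metrics.R      # conditioning + parameters -> results/metrics.csv
Rscript analysis/03_agreement.R    # agreement tables -> results/report/
Rscript analysis/04_sensitivity.R  # one-board 5% corner-gain injection
```

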