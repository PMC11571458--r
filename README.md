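# foamimpact

Strike forces in combat-sports research are measured through protective foam
mats, so the load cell only ever sees a damped force. `foamimpact` implements
the falling-weight impact-test analysis used to characterize that damping for
stacked layers of cross-linked closed-cell polyethylene mat: it estimates the
**undamped force** — the force the instrument would register with no mat at
all — from the measured peaks, builds per-layer **transfer functions**
between measured and undamped force, decomposes each impact cycle into
elastic and plastic energy, and quantifies how repeated loading degrades the
mat's protection. Because no raw traces are publicly deposited for this kind
of rig, the package ships a physics-based simulator of the experiment (an
8-kg impactor dropped from 0.15/0.25/0.50 m onto 1–3 foam layers of 18 mm)
that is calibrated to published summary tables and used as the data source
for all tests.

## The model in brief

For each drop height and repetition, the peak force `F` and peak compression
`x` of every layer stack are fitted with

&nbsp;&nbsp;&nbsp;&nbsp;`F(x) = a · exp(b·x)`,

and the extrapolation to zero compression, `F(0) = a`, is the undamped
force. Pairing each measured peak with its group's undamped force and
fitting a zero-intercept line `undamped = k · measured` per layer count
gives the transfer slope `k` (with through-origin R² and 95 % CI). Energy
accounting uses the areas under the loading and unloading portions of the
displacement–force curve: total absorbed `E`, elastic `E_E`, plastic
`E_P = E − E_E`. The repeated-loading analysis reads the force at a
reference absorbed energy `E_ref` (the energy at the 10 kN crossing of the
reference condition; 30 J here) off every 50-cm test and compares the five
repetitions with a repeated-measures ANOVA and one-sided consecutive paired
t tests.

The synthetic specimen follows an elastoplastic strain law
`F = M·a_f·(exp(b_f·ε) − 1)·D(ε)` with a densification term `D` switching on
above ~75 % compression, a power-law unloading branch, and degradation
driven by accumulated plastic energy (stiffness multiplier and advance of
the densification onset, both saturating). `calibrate_defaults()` fits the
material constants to the published forces-at-30-J table; the fitted values
are the package defaults.

## Worked example

```r
library(foamimpact)

study <- run_full_study(study_config(seed = 1), foam_params())
print(study)
```

```
Falling-weight impact study
  seed 1, 126 traces, E_ref = 30 J
Transfer functions (undamped = k * measured):
  1 layer(s): k = 3.2  (R^2 = 0.982, 95% CI [3.06, 3.33], n = 42)
  2 layer(s): k = 8.5  (R^2 = 0.942, 95% CI [7.80, 9.12], n = 42)
  3 layer(s): k = 13.5  (R^2 = 0.939, 95% CI [12.39, 14.56], n = 42)
  2 layers attenuate 2.6 times more than a single layer
  3 layers attenuate 4.2 times more than a single layer
Repeated loading at E_ref = 30 J:
  1 layer(s): F(4,8) = 151.58, p = 1.42e-07, eta^2 = 0.987
    rep 1:  9994 +/-  251 N   +0%
    rep 2: 12499 +/-  459 N  +25%  p = 0.00125
    rep 3: 12910 +/-  378 N  +29%  p = 0.00718
    ...
  3 layer(s): F(4,8) = 103.22, p = 6.43e-07, eta^2 = 0.981
    rep 1:  2776 +/-   13 N   +0%
    rep 2:  2997 +/-   44 N   +8%  p = 0.00724
    ...
```

One seeded run simulates the full factorial design (126 drops), segments
every trace into loading/unloading portions, finds `E_ref` = 30 J (the
energy absorbed when the single layer first carries 10 kN at 0.50 m),
estimates one undamped force per (height, repetition) group and fits the
three transfer functions. A transfer slope of 3.2 means a punch measured at
2.9 kN through one mat layer corresponds to an undamped force of
`predict_undamped(2.9, 3.2)` ≈ 9.3 kN; with the published slope of 2.8 the
same call gives 8.1 kN. The repeated-loading table shows the mat stiffening
under successive impacts: the force carried at 30 J rises significantly at
the second repetition for every layer count (one-sided paired t), i.e. the
mat's energy-absorbing capacity degrades most in the first hit.

Individual stages are ordinary functions on tibbles and compose with the
pipe:

```r
params <- foam_params(specimen_cv = 0, noise_force_sd = 0, noise_disp_sd = 0)
sim <- simulate_drop(test_condition(drop_height = 0.5, n_layers = 1), params)
seg <- process_trace(sim$trace)
energy_at_force_threshold(seg$loading, 10000)  # 30.1 J
autoplot(seg)                                  # loading/unloading figure
```

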