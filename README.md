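# hepatoflux

Kinetic modelling and regulatory analysis of hepatic glucose metabolism in
the rat hepatocyte.

The liver stabilizes plasma glucose by switching between net glucose
production (gluconeogenesis, glycogenolysis) and net glucose uptake
(glycolysis, glycogen synthesis). `hepatoflux` implements a kinetic ODE
model of this switch — glycolysis, gluconeogenesis and glycogen turnover
across cytosol, mitochondrion and endoplasmic reticulum, 32 reactions in
total — coupled to plasma glucose through empirical glucose–hormone transfer
(GHT) functions for insulin and glucagon and a hormone→phosphorylation
signal function γ. On top of the simulator it provides the two analyses
this model exists for:

* **Regulation-mode dissection.** Freeze one regulatory layer — enzyme
  abundance (α·V<sub>max</sub> scaling), reversible phosphorylation
  (γ·v<sub>P</sub> + (1−γ)·v<sub>D</sub> interconversion), or allosteric
  effector saturation — at the normal liver's glucose set point, and
  quantify the degraded diurnal response by the normalized curve distance

  Δ = ∫₀²⁴ʰ |v<sub>ex</sub><sup>full</sup> − v<sub>ex</sub><sup>(−)</sup>| dt
      / ∫₀²⁴ʰ |v<sub>ex</sub><sup>full</sup>| dt

  where v<sub>ex</sub> is the glucose exchange flux (µmol/g/h, positive =
  net uptake).

* **Metabolic control analysis.** Flux control coefficients
  C<sub>i</sub> = (v<sub>i</sub>/v<sub>ex</sub>) ∂v<sub>ex</sub>/∂v<sub>i</sub>
  of the exchange flux by 5 % enzyme-amount variation and steady-state
  re-solution (summation theorem Σ C<sub>i</sub> = 1), π-elasticities
  π<sub>ik</sub> = (p<sub>k</sub>/v<sub>i</sub>) ∂v<sub>i</sub>/∂p<sub>k</sub>
  of the isolated rate laws (π = 1 for the enzyme abundance; ε = −π for
  binding constants entering through X = E/p), and response coefficients
  R<sub>ik</sub> = C<sub>i</sub>·π<sub>ik</sub>.

Every external input has a seeded synthetic generator (diurnal glucose
profiles for fed/fasted/diabetic conditions, glucose–hormone scatter,
enzyme-abundance samples within the reported ranges), so the full pipeline
runs without any downloads. Models can be exchanged as SBML L3V2.

## Worked example

```r
library(hepatoflux)
net <- build_network()

# Stationary physiology: the fasted liver at hypoglycemic 4 mM plasma
# glucose produces glucose; the fed liver at 10 mM takes it up.
steady_state(net, "fasted", clamp_set(glucose = 4,  glycogen = 0.1))$v_ex
#> [1] -60.64408
steady_state(net, "fed",    clamp_set(glucose = 10, glycogen = 0.85))$v_ex
#> [1] 85.11602

# Glucose set points (v_ex = 0) at a half-filled glycogen store:
sapply(c("fed", "normal", "fasted"),
       function(s) set_point(net, s, glycogen_fill = 0.5)$glucose)
#>      fed   normal   fasted
#> 6.224396 7.134123 8.985978

# Control analysis in the fasted reference state: gluconeogenesis is
# controlled by pyruvate carboxylase and lactate import.
ct <- control_coefficients(net, "fasted", clamp_set(glucose = 4, glycogen = 0.1))
attr(ct, "sum")                     # summation theorem
#> [1] 1.001176
head(ct[order(-abs(ct$C)), ], 4)
#>    reaction           C
#> 21       PC  0.51260950
#> 2      LacT  0.19278085
#> 28       GP  0.12224098
#> 18       PK -0.08529349

# Regulation-mode dissection on synthetic diurnal profiles:
regulation_report(net, dt = 0.25)
#> Average curve difference Delta (rows: frozen mode)
#>                 fasted   fed
#> abundance        0.203 0.987
#> phosphorylation  0.322 0.709
#> allosteric       0.211 0.696
```

The first two numbers say the fasted liver releases ~61 µmol glucose per g
per hour at 4 mM plasma glucose while the fed liver absorbs ~85 µmol/g/h at
10 mM. The set points order fed < normal < fasted, and the diabetic liver
(impaired hormone axis plus its enzyme complement) is shifted so far right
that it remains a net producer over the whole physiological glucose range.
The Δ table quantifies how much of the day's exchange-flux response is lost
when one regulatory mode is frozen: in the fed state the abundance
adaptation matters most, while the fast modes (phosphorylation, allosteric
effectors) carry the fasted-state response.

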