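# artstiff

Beat-by-beat estimation of peripheral arterial stiffness from simultaneously
recorded continuous blood pressure and photoplethysmogram (PPG) waveforms,
with sigmoid mapping of the normalized stiffness index to an estimated
numeric pain rating (eNRS).

## Who this is for

Researchers working on objective, autonomic correlates of pain (or of
sympathetic vascular tone generally) who have synchronized ECG / blood
pressure / PPG recordings and want a per-heartbeat arterial stiffness index
that is not confounded by blood-pressure variation — plus a forward
simulator so every step of the analysis can be validated by parameter
recovery before touching real data.

## The model

The arterial wall is treated as a second-order viscoelastic system with an
exponential elastic component, the PPG $P_l(t)$ standing in for
arterial-diameter strain:

$$P_b(t) = \mu \ddot P_l(t) + \eta \dot P_l(t) +
  \exp\{\beta P_l(t) + P_{b\beta_0} + P_{b\beta nl}\}$$

with blood pressure $P_b$ in mmHg, inertia $\mu$, viscosity $\eta$, and the
stiffness index $\beta$, which rises with sympathetic vasoconstriction.
Each R-to-R cardiac cycle is fitted by a two-step least-squares procedure:

1. **Step 1** — difference all signals against the beat's R-wave sample
   $t_0$ (which cancels the constant exponent terms), linearize the elastic
   term, and solve $dP_b = \mu\, d\ddot P_l + \eta\, d\dot P_l + \beta_A\,
   dP_l$ by OLS;
2. **Step 2** — fix $\mu, \eta$, form the residual elastic pressure
   $q(t) = P_b - \mu \ddot P_l - \eta \dot P_l$, and regress
   $\ln(q(t)/q(t_0))$ on $dP_l(t)$ through the origin, using only samples
   with $P_b$ above mean blood pressure, giving $\beta$.

By default the two steps are iterated to convergence, which removes the
linearization bias of the single pass (see the methods vignette); each beat
gets a reconstruction $R^2$ and is accepted only when $R^2 \ge 0.9$.
Downstream, $\beta$ is normalized by its maximum over a no-stimulation
baseline window ($\beta_n$) and mapped to a 0–10 pain estimate through the
bounded sigmoid $\mathrm{eNRS} = 20/(1+\exp(a(\beta_n-1)^{-b}))$ for
$\beta_n>1$, 0 otherwise.

## Worked example

Simulate a full 448 s stimulation block (7 trials of 20 s rest, 24 s
electrocutaneous stimulation, 20 s evaluation; levels 1.5, 1.0, 0.5, 0,
0.5, 1.0, 1.5 × standard amplitude), estimate every beat, normalize against
the zero-level trial, and recover the stimulus–stiffness coupling:

```r
library(artstiff)

synth  <- synthesize_record(fs = 500, sigma_bp = 0.5, seed = 7)
est    <- estimate_record(synth$record)
#> estimated 520 beats: 520 accepted, 0 rejected (R^2 gate 0.9).
series <- normalize_beta(est, protocol_baseline_window(synth$protocol))
trials <- summarize_trials(series, synth$protocol)
trials
#>   trial level n_beats mean_beta_n
#> 1     1   1.5      28      2.0770
#> 2     2   1.0      28      1.3951
#> 3     3   0.5      28      0.9674
#> 4     4   0.0      28      0.9458
#> 5     5   0.5      28      0.9655
#> 6     6   1.0      28      1.3984
#> 7     7   1.5      28      2.0727

fit <- fit_sigmoid(trials$level, trials$mean_beta_n, "stimulus")
fit
#> <sigmoid_map [stimulus]: a=3.2127, b=1.0335, R^2=0.9949, n=7>
```

Per-beat output (first rows; simulator truth is $\mu = 0.05$, $\eta = 0.8$,
resting $\beta = 1.5$):

```r
head(est[, c("beat", "t0", "mu", "eta", "beta", "r2", "accepted")], 3)
#>   beat    t0         mu       eta     beta        r2 accepted
#> 1    1 0.858 0.04821687 0.7866094 1.461987 0.9970857     TRUE
#> 2    2 1.714 0.05144952 0.7953564 1.501975 0.9982635     TRUE
#> 3    3 2.572 0.04902047 0.8079049 1.471989 0.9974269     TRUE
```

The symmetric stimulus schedule is reflected in the per-trial $\beta_n$
means, and the fitted sigmoid recovers the simulator's coupling
$(a, b) = (3, 1)$ to within a few percent at this noise level. `autoplot()`
methods exist for records, beat estimates, stiffness series and sigmoid
fits; `tidy()`/`glance()` for the fitted maps. `run_pipeline()` wires the
whole chain (including CSV/JSON outputs and a settings log) behind one
config, and `exec/artstiff` exposes `synth` / `estimate` / `map-pain` /
`run` subcommands for shell use.

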