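# ijpseudo

Regression models for survival probabilities and cumulative incidences from
censored — and possibly left-truncated — time-to-event data, using
**infinitesimal jack-knife (IJ) pseudo-observations**.

## The problem and the method

For competing-risks data $(T, \Delta)$, $\Delta \in \{1,\dots,d\}$, and a
fixed time $t$, one often wants a direct regression model for the cumulative
incidence $P(T \le t, \Delta = 1 \mid Z) = \mu(\beta^\top Z)$ (or the
survival probability $P(T > t \mid Z)$), rather than a hazard model.  The
pseudo-observation approach replaces the partially unobserved outcome
$V = 1(T \le t, \Delta = 1)$ by a per-subject transformation
$\hat\theta_{n,i}$ of the censored data with the right conditional mean, and
solves the generalized estimating equation

$$\sum_{i=1}^n A(\beta; Z_i)\, w_i \,\{\hat\theta_{n,i} - \mu(\beta^\top Z_i)\} = 0 .$$

The classical jack-knife pseudo-observation
$n\hat\theta_n - (n-1)\hat\theta_n^{(i)}$ requires a leave-one-out
recomputation of the Aalen–Johansen estimate for every subject.  This
package's central object is the *infinitesimal* jack-knife pseudo-observation
— the functional value plus its first-order influence function at the
empirical distribution,

$$\hat\theta^{IJ}_{n,i} = \int_0^t \frac{dN_{1i}(s)}{\hat G_n(s-)}
  + \int_0^t \frac{\hat F_{n,1}(t)-\hat F_{n,1}(s)}{\hat S_n(s)\,\hat G_n(s)}
  \, d\hat M_{0i}(s),$$

which costs a single pass over the data, averages *exactly* to the
Aalen–Johansen estimate, and is asymptotically equivalent to the jack-knife.
For **left-truncated (delayed-entry) cohorts** the plain pseudo-observation
methods are biased whenever the covariate is prognostic; the package
implements the corrected method: IJ pseudo-observations built from
truncation-adjusted curves mapped back to the untruncated scale, combined
with inverse probability of sampling weights
$\hat w_i = 1/\hat F_L(\min(T_i,\tau))$ estimated by the reversed-time
product-limit estimator of the entry-time distribution.

Variance estimation: Huber–White sandwich (default, conservative), a plug-in
asymptotic variance including the second-order influence-function correction,
and a subject bootstrap (practical because IJ pseudo-observations are fast).

## Worked example

A left-truncated competing-risks cohort from the built-in generator
(baseline cause-1 risk 0.2, risk difference 0.3, 30% observed censoring,
entry times with mass 0.2 at zero, else uniform):

```r
library(ijpseudo)
cfg <- scenario_config(n = 600, p_oc = 0.3, beta1 = 0.3,
                       truncation = "mass-uniform")
dat <- as.data.frame(simulate_truncated_cohort(cfg, seed = 1))
fit <- pseudoglm(Event(time, status, entry) ~ z1, dat, time = 1,
                 cause = 1, method = "ij-truncated")
summary(fit)
```

```
Pseudo-observation regression (ij-truncated pseudo-observations)
  target: P(T <= t, cause = 1) at t = 1;  link = identity;  n = 600

Coefficients:
(Intercept)          z1 
     0.2203      0.3571 

Inference (hw variance, 95% CI):
            Estimate Std. Error   Lower   Upper z value Pr(>|z|)    
(Intercept)  0.22034    0.03003 0.16148 0.27920   7.337 2.18e-13 ***
z1           0.35712    0.04643 0.26612 0.44811   7.692 1.45e-14 ***
```

The intercept estimates the baseline cumulative incidence at `t = 1`
(truth 0.20) and `z1` the risk difference (truth 0.30); the identity link
makes both directly interpretable as probabilities, and the Wald intervals
use the Huber–White variance.  With `method = "jackknife"` on the same data
the risk difference would be systematically distorted by the length-biased
sampling — the comparison the simulation engine quantifies.

Other entry points: `pseudo_obs()` (the pseudo-observations themselves, all
methods), `ij_weight_derivative()` (the weight-derivative formulation, a
cross-implementation check agreeing to 1e-14), `fit_curves()` /
`truncation_cdf()` / `rho_map()` (the underlying curve estimators),
`bootstrap_vcov()` / `asymptotic_vcov()` (variances), and
`simulate_cohort()` / `simulate_truncated_cohort()` / `run_scenario()`
(the simulation engine).  A thin command-line wrapper with subcommands
`compute-pseudo`, `fit`, `simulate` and `curves` is installed under
`inst/cli/ijpseudo`.

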