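---
title: "Model-space MCMC for variable selection in GLMs and survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-space MCMC for variable selection in GLMs and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parni)
```

## The model

For covariates $X \in \mathbb{R}^{n\times p}$, fixed covariates
$Z \in \mathbb{R}^{n\times q}$ and a binary model indicator
$\gamma \in \{0,1\}^p$, the linear predictor under model $M_\gamma$ is
$\eta_\gamma = Z\alpha + X_\gamma \beta_\gamma$. Three likelihood families
are supported:

* **logistic** — $y_i \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\eta_i))$;
* **Cox partial likelihood** — the baseline-free product of risk-set
  ratios at event times, with the Breslow convention for tied times (the
  package allows ties; Breslow is our choice of continuity, and the
  location-invariance of the partial likelihood means Cox fits carry no
  intercept);
* **Weibull** — hazard scale $\lambda_i = e^{\eta_i}$ and shape $k$, so
  $S_i(t) = \exp\{-(t\lambda_i)^k\}$; $k = 1$ recovers the exponential
  model. Internally the shape is parameterised as $\log k$ with a
  $N(0, \sigma_k^2)$ prior and updated by an adaptive random walk.

The spike-and-slab prior puts $\alpha \sim N_q(0, \sigma_\alpha^2 I)$,
$\beta_\gamma \mid \gamma \sim N_{p_\gamma}(0, g I)$, and either a fixed
inclusion probability $h$ or the Beta-binomial model prior
$p(\gamma) = B(a + p_\gamma,\, b + p - p_\gamma)/B(a, b)$. A half-Cauchy
hyper-prior on the slab scale $\sqrt{g}$ is available
(`bvs_prior(g = "half_cauchy")`): it is represented as the exact
inverse-gamma mixture $g \mid a_{\mathrm{aux}} \sim IG(1/2, 1/a_{\mathrm{aux}})$,
$a_{\mathrm{aux}} \sim IG(1/2, 1)$, which is conditionally conjugate to the
Gaussian slab, so the Gibbs update is two exact inverse-gamma draws
($a_{\mathrm{aux}} \mid g \sim IG(1, 1 + 1/g)$ — note the shape of 1, which
is what the mixture algebra gives and what the prior-invariance test
confirms). Placing the half-Cauchy on the scale rather than the variance is
the standard global-scale construction; it keeps the update exact.

The object of inference is the posterior over the $2^p$ lattice,
$\pi(\gamma) \propto p(y\mid\gamma)\,p(\gamma)$, summarised by posterior
inclusion probabilities (PIPs) $\pi_j = P(\gamma_j = 1 \mid y)$.

## Marginal-likelihood engines

$p(y\mid\gamma) = \int p(y\mid\theta_\gamma)p(\theta_\gamma\mid\gamma)\,
d\theta_\gamma$ has no closed form in these families. Four estimators sit
behind one interface (`marglik_engine()`):

* **`la`** — Laplace approximation at the posterior mode $\hat\theta_\gamma$
  (Newton with step halving, gradient max-norm tolerance $10^{-8}$,
  at most 100 iterations; these optimiser settings are our choice).
  Deterministic, so an engine memoises each model's value for the whole run.
* **`ala`** — approximate Laplace approximation: one Taylor expansion at a
  fixed initial value (the origin), i.e.
  $\log p_{\mathrm{ALA}} = \log p(y\mid\theta^0) + \log p(\theta^0\mid\gamma)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log|H^0| + \tfrac12 (g^0)^\top
  (H^0)^{-1} g^0$. No optimisation at all; coincides with `la` when
  $\theta^0$ is the mode (a property the tests assert to $10^{-6}$ over
  random models in all three families).
* **`adaptive_ala`** — ALA with an adaptively chosen expansion point: a
  running average $\hat\eta$ of MAP linear predictors of visited models is
  projected onto the model's column space by least squares (QR, with a
  ridge fallback at $\lambda = 10^{-8}$ for rank-deficient designs), one
  Newton step is taken, and the ALA is evaluated there.
* **`cpm`** — correlated pseudo-marginal: an unbiased importance-sampling
  estimate with the LA Gaussian as proposal, $N = 32$ samples by default.
  The auxiliary standard normals are a shared block sliced per model, so
  the two estimates in an MH ratio are positively correlated; the block
  evolves by a Crank–Nicolson autoregression with $\rho = 0.99$ that is
  itself accepted or rejected against the current model's estimate — a
  $\varphi$-invariant sub-step, so the extended chain remains an exact
  pseudo-marginal scheme targeting the true posterior. ($N$, $\rho$ and the
  refresh construction are our realisation; the defaults are exposed.)
* **`da`** — Pólya-gamma data augmentation (logistic only): conditional on
  $\omega_i \sim PG(1, \eta_i)$ the coefficient posterior is exactly
  Gaussian and $\log p(y\mid\gamma,\omega)$ has a closed form whose
  additive constant ($-n\log 2$) we keep exact, so the same value serves
  MH ratios and diagnostics. The PG(1, c) sampler is an exact Devroye-type
  alternating-series sampler implemented in C++ on R's RNG stream.

Indefinite Hessians are jittered once by $10^{-8}\,\mathrm{tr}(H)/d$ on the
diagonal; if still indefinite the estimator reports $-\infty$ and the
proposal treats the model as unreachable.

## The PARNI proposal

Each iteration draws a flip-set $k$ with
$P(k_j = 1) = A_j$ if $\gamma_j = 0$ and $D_j$ if $\gamma_j = 1$, then
visits the active positions in a fresh uniform random order. At each
position the two-model neighbourhood {keep, flip} is scored by the locally
informed kernel $q_N(\gamma,\gamma') \propto
g_H\!\big(\tfrac{\tilde\pi(\gamma')p(k|\gamma')}{\tilde\pi(\gamma)p(k|\gamma)}\big)
\big(\tfrac{\zeta}{1-\zeta}\big)^{d_H(\gamma,\gamma')}$ with Hastings'
balancing function $g_H(x) = \min(1, x)$, where $\tilde\pi$ uses the
proposal-side engine (adaptive ALA by default). The walk needs exactly
$2p_k$ proposal-side model evaluations instead of the $2^{p_k}$ a full
neighbourhood enumeration would cost — the per-iteration instrumentation in
the fitted object (`proposal_evals`) asserts this identity. The reverse
path visits the same two-model pairs in reverse order, so its probability
is assembled from the cached forward scores at no extra engine calls. The
MH correction uses the acceptance-side engine (CPM, LA or DA), which may
differ from the proposal side: only the acceptance side determines the
invariant distribution.

**Adaptation.** $A_j = \min(1, \hat\pi_j/(1-\hat\pi_j))$ and
$D_j = \min(1, (1-\hat\pi_j)/\hat\pi_j)$, clipped to
$[\epsilon, 1-\epsilon]$ with $\epsilon = 0.001$ (the clip bound is our
default; any small value in $(0, 1/2)$ qualifies). The PIP estimate
$\hat\pi_j$ blends a warm start with the ergodic average,
$\hat\pi_j^{(L)} = \phi_L \tilde\pi_j^{(0)} + (1-\phi_L)\tilde\pi_j^{(L)}$,
where $\phi_l = 1 - \tfrac12 (N_b - l + 1)^{-1/2}$ during burn-in and
$\tfrac12 (l - N_b)^{-1/2}$ after, so the chain leans on the warm start
early and on its own ergodic average late; the increments of $A$ and $D$
vanish, giving diminishing adaptation. The warm start
$\tilde\pi^{(0)}$ is the vector of Rao-Blackwellised inclusion
probabilities at the initial model under ALA-at-origin, computed for all
$p$ covariates from one factorisation of
$\Lambda = J^\top W J + V^{-1}$ via Schur complements (adding $j$ costs
$d_{j\uparrow} = X_j^\top W X_j + 1/g - X_j^\top W J \Lambda^{-1} J^\top W
X_j$; removing $j$ costs $d_{j\downarrow} = 1/(\Lambda^{-1})_{jj}$) — the
tests require these to match direct ALA ratios to $10^{-8}$ relative
error. The fixed covariates $Z$ are kept inside $J$ throughout. The
non-informative jumping parameter $\zeta$ adapts by Robbins–Monro on the
logit scale toward acceptance rate 0.234 with step $l^{-0.7}$ (one of
several reasonable schemes; a fixed-$\zeta$ mode is exposed). The adaptive
ALA guess $\hat\eta$ is the running mean of MAP linear predictors stored
by the acceptance engine; the DA engine carries no mode, in which case
$\hat\eta$ stays at the origin.

The add–delete–swap baseline (`sampler = "ads"`) chooses uniformly among
feasible move types, corrects for the unequal neighbourhood counts, and
shares the same acceptance-side engines and hyper-parameter moves.

## Synthetic data

`simulate_bvs()` emulates a high-dimensional selection study: rows of $X$
iid Gaussian with independent, AR(1) ($\rho = 0.6$ default) or equicorrelated
block structure, columns standardised; defaults of $n = 500$, $p = 500$,
ten true effects of alternating sign $\pm 1$ on evenly spaced positions,
30% censoring and Weibull shape 1.5 for the survival families, chosen once
as representative of sparse genetic-association signal strength (marginal
$z$-scores around 5 at $n = 300$). Censoring is exponential with the rate
calibrated by bisection to the target fraction. What the generator does
**not** emulate: discrete genotype coding, linkage-disequilibrium block
structure of real SNP panels, case-control ascertainment, or covariate
measurement error — so passing recovery tests demonstrate correctness of
the sampler on well-specified Gaussian designs, not robustness to those
features of real data.

## Numerical choices and test scales

Logistic log-likelihoods use softplus forms; Cox risk-set denominators use
max-shifted exponentials and the dense curvature is assembled from
cumulative risk-set sums in $O(n^2)$; the Weibull exponent
$k(\eta_i + \log t_i)$ is capped at 690 so overflow degrades to a finite
penalty rather than `Inf`. All randomness flows through R's RNG (including
the C++ PG sampler), so a seed makes a whole run bit-reproducible.

The validation suite works at deliberately small scales chosen so the
oracles are exact or near-exact: full enumeration up to $p = 8$
(sampler-vs-lattice agreement), 1-D quadrature for single-coefficient
marginal likelihoods, closed-form identities for the PG augmentation, and
reduced $n = 300$, $p = 300$ recovery and efficiency runs with 10,000
iterations and 2,000 burn-in, mirroring the simulation protocol at the
scale the package's own enumeration-free gold runs can verify. The
matched-budget sampler comparison is iteration-matched rather than
wall-time-matched, since wall-time is hardware-dependent.

## Known limitations

LA and (adaptive) ALA acceptance targets are the corresponding approximate
posteriors, not the exact one; CPM and DA are the exact-target options and
the package's dual-chain test checks they agree. The Cox curvature is
dense, so proposal-side engines that need Hessians scale as $O(n^2)$ per
evaluation — for large-$n$ Cox problems the adaptive-ALA proposal with CPM
acceptance is the practical configuration. No dispersion-parameter
families (e.g. Gamma GLMs) and no full-likelihood Cox with a baseline
prior are implemented. Multiple chains are run by seed replication rather
than internally.
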