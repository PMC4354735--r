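---
title: "Wrapped Sparse Group Lasso selection of fused EEG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapped Sparse Group Lasso selection of fused EEG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor-imagery brain-computer interfaces classify short multichannel EEG
trials into imagined-movement classes. Each electrode (channel) yields a
time series from which heterogeneous feature families are extracted, so the
design matrix is wide (thousands of columns) while trials are scarce
(hundreds). Two kinds of redundancy coexist: entire channels may be
irrelevant to the task, and individual features within a relevant channel
may carry no class information. `sgleeg` implements a *wrapped* selection
scheme that addresses both at once: the classifier itself is fitted under a
Sparse Group Lasso penalty whose groups are the per-channel feature blocks,
and cross-validation over the penalty strength performs the selection.

## Feature fusion

Every channel contributes a fixed-order block of fused features
(`extract_fused()`):

* **Band powers** (5): a PSD estimate integrated over 2–4, 4–8, 8–12,
  12–18 and 18–30 Hz. These capture the event-related
  desynchronization/synchronization (ERD/ERS) of sensorimotor rhythms.
* **Time-domain statistics** (4): mean, standard deviation, mean absolute
  first and second difference.
* **AR coefficients** (6): a sixth-order autoregressive model of the
  channel signal.
* **Wavelet features** (55): a 6-level Db4 decomposition summarized by the
  energies of the 7 terminal coefficient sets (cA6, cD6, …, cD1) and, for
  each of the 12 per-level approximation/detail vectors, the Shannon
  entropy, log-energy entropy, and the mean and variance of the
  Teager–Kaiser energy operator
  $\psi(c_n) = c_n^2 - c_{n-1} c_{n+1}$.

The per-channel dimension is therefore $d = 5 + 4 + 6 + 55 = 70$, and a
59-channel montage yields $59 \times 70 = 4130$ columns.

Two conventions for the wavelet block are in circulation: the 55-dimension
layout above, and a literal "7 sets × (1 energy + 4 statistics) = 35"
reading. Both are implemented
(`feature_config(wavelet_convention = "per_level")`, the default, versus
`"terminal"`); the default is the unique layout consistent with both a
seven-dimensional energy vector and a 55-dimensional total.

Choices the data do not pin down, fixed as defaults and exposed in
`feature_config()`:

* **PSD estimator**: Welch averaging of 1-s Hann windows with 50% overlap
  (standard for 4-s EEG trials); a plain periodogram is selectable. The
  estimator is implemented over `stats::fft`.
* **AR fitting**: Burg's method (well-behaved on short EEG segments);
  Yule–Walker selectable. Both call the corresponding `stats::ar.*`
  routines.
* **DWT boundary handling**: half-point symmetric extension, fixed across
  train and test. The Db4 analysis filter bank is implemented in
  `dwt_db4()` and follows PyWavelets' `db4`/`symmetric` convention exactly;
  the frozen reference values in the test suite were computed with that
  independent implementation.
* **Log-energy entropy guard**: $\sum_i \log(c_i^2 + \varepsilon)$ with
  $\varepsilon = 10^{-12}$, so zero coefficients stay finite.
* **Resampling**: Fourier-method downsampling (spectrum truncation), which
  preserves DC and band-limited content exactly; polyphase FIR resampling
  was rejected because its edge transients violate the
  constant-signal-in/constant-signal-out contract on trial-length windows.

## The model

With trials $x_i \in \mathbb{R}^{pd}$ and labels $g_i \in \{1,\dots,M\}$,
class probabilities follow the multinomial logistic model with reference
class $M$:

$$\Pr(g_i = m \mid x_i) = \frac{\exp(x_i^\top \beta_{\cdot m} + b_m)}
  {\sum_{l=1}^{M} \exp(x_i^\top \beta_{\cdot l} + b_l)},
  \qquad \beta_{\cdot M} = 0,\; b_M = 0.$$

The fitted criterion is

$$\min_\beta\; -\ell(\beta) \;+\;
  \lambda (1-\alpha) \sum_{J=1}^{p} w_J \lVert \beta^{(J)} \rVert_2
  \;+\; \lambda \alpha \lVert \beta \rVert_1,$$

where $\ell$ is the log-likelihood, group $J$ collects all free-class
coefficients of channel $J$ (size $d \times (M-1)$), and
$\alpha \in [0,1]$ interpolates between the Group Lasso ($\alpha = 0$,
whole channels in or out) and the Lasso ($\alpha = 1$, individual
features). Nonzero coefficients *are* the selection: a feature is selected
iff some class coefficient is nonzero, a channel iff some feature in its
block is.

Design choices where the formulation is open:

* **Intercepts.** An unpenalized per-class intercept is fitted by default
  (`intercept = FALSE` gives the literal no-intercept model). Without one,
  $\lambda_{\max}$ on uncentered data is dominated by the class imbalance
  rather than by signal.
* **Group weights.** $w_J = 1$ by default; $w_J = \sqrt{d(M-1)}$ via
  `group_weight_mode = "sqrt_size"` (the conventional group-lasso scaling).
* **Standardization.** Columns are z-scored with *training-fold* statistics
  inside `sgl_cv()` (stored in the model and re-applied at prediction);
  a common $\lambda$ across feature families as heterogeneous as band
  powers and entropies is meaningless otherwise.

## The three-loop estimator

`sgl_fit()` implements a coordinate gradient descent scheme:

1. **Outer loop.** At the current iterate build the quadratic model
   $Q(\beta) = q^\top(\beta-\tilde\beta) + \tfrac12 (\beta-\tilde\beta)^\top
   H (\beta-\tilde\beta)$ with the exact gradient $q$ and a per-feature
   block-diagonal curvature $H$: for feature row $j$,
   $H_{jj} = \sum_i x_{ij}^2 (\mathrm{diag}(p_i) - p_i p_i^\top)$ over the
   free classes, and zero across rows. (The exact multinomial Hessian is
   not block-diagonal; this restriction is what makes the blockwise
   subproblem separable, and the line search guarantees descent
   regardless.) The subproblem minimizer $\hat\beta$ defines the step
   direction $\Delta = \hat\beta - \tilde\beta$, accepted by Armijo
   backtracking on the *true* penalized objective
   ($t \in \{1, \rho, \rho^2, \dots\}$, $\rho = 0.5$, sufficient-decrease
   constant $10^{-4}$).
2. **Middle loop.** Blockwise coordinate descent over channel groups in
   cyclic order. Each group is first screened by the subgradient zero test
   $\lVert S(g^{(J)}, \lambda\alpha) \rVert_2 \le \lambda(1-\alpha) w_J$
   ($S$ = soft-thresholding), which produces exact group zeros.
3. **Inner loop.** Modified coordinate descent inside a group. Each
   coordinate minimizes
   $\omega(b) = cb + \tfrac{h}{2} b^2 + \gamma\sqrt{b^2 + r} + \xi |b|$:
   closed-form soft-thresholding when $r = 0$ or $\gamma = 0$, zero when
   $|c| \le \xi$, otherwise the root of
   $c + \xi s + h b + \gamma b (b^2 + r)^{-1/2} = 0$, $s = -\mathrm{sign}(c)$,
   by a safeguarded Newton/bisection bracket. A group parked at zero that
   fails the zero test re-enters along the soft-thresholded negative
   gradient $\Delta_i = -S(g_i, \lambda\alpha)$ with a halving line search.

The middle and inner loops run in compiled code; the solver is entirely
deterministic, and all zeros it reports are hard zeros produced by
thresholding, never rounded floats.

Numerical defaults (`solver_settings()`): relative objective tolerance
$10^{-6}$ (outer), coefficient-change tolerances $10^{-8}$ (middle/inner),
iteration caps 200/200/1000, at-zero threshold $10^{-10}$. For
oracle-comparison work the suite tightens these to
$10^{-14}/10^{-12}/10^{-12}$, which drives the KKT residual of small
instances below $10^{-5}$. `kkt_lambda_max()` rounds its root up by a
relative $10^{-9}$ so the returned value itself passes every zero test
despite the root-finder tolerance.

## Paths, cross-validation and the selection rule

`build_lambda_path()` constructs a geometric grid from $\lambda_{\max}$
(the smallest $\lambda$ with an all-zero solution, computed from the KKT
conditions at the null model) down to `lambda_min_ratio` times it
(defaults: 50 values, ratio 0.01). Fits are warm-started along the path.

`sgl_cv()` runs stratified $k$-fold cross-validation (default 10) jointly
over an $\alpha$ grid and the $\lambda$ path, scoring held-out accuracy;
folds are fixed by `fold_seed`, standardization is refit per training fold,
and the final model is refit on all training data at the chosen pair.
Because the unscaled likelihood grows with $n$, a fold fit on $n_{\text{tr}}$
of $N$ samples uses $\lambda \cdot n_{\text{tr}}/N$ — the per-observation
penalty convention — so the full-data refit reproduces the penalty strength
the folds were scored under. A
fixed single-$\alpha$ grid reproduces the per-$\alpha$ experiment layout;
the joint grid search is the default.

**Selection rule.** Reading "highest training accuracy rate" as the raw
argmax of mean held-out accuracy (ties toward sparser models) turns out to
be self-defeating for support recovery: on the grouped-design testbed the
accuracy curve plateaus once the true channels are in, the argmax lands
slightly past the plateau's sparse end on noise-level differences
($<0.5\%$), and exact ties at $1/N$ accuracy resolution essentially never
occur — so the tie-break never engages and the model over-selects. The
default rule is therefore the one-standard-error variant of the same
criterion: every $(\alpha, \lambda)$ within one standard error (across
folds) of the best mean accuracy is treated as statistically tied, and the
sparsest of the ties (largest $\lambda$, then largest $\alpha$) wins.
`selection_rule = "best"` restores the literal argmax.

## What the synthetic data does and does not show

`gen_eeg_trials()` emulates only the *shape* of a motor-imagery recording:
59 channels × 400 samples at 100 Hz, two classes, a planted subset of
channels whose 8–12 Hz oscillation amplitude depends on the class (2 vs
0.5 by default, against 1/f background noise of unit scale, spectral
exponent 1). Phase and exact frequency are randomized per trial so band
power, not phase, carries the information. It is not a physiological
model: there is no volume conduction or channel correlation, no artifacts,
no nonstationarity, and the discriminative signal is confined to one band.
Passing tests on this generator demonstrates that the estimator finds
planted band-power structure through the full fused feature set — not that
it attains any particular accuracy on real EEG.

`gen_design()` is the solver-side testbed: standard-normal design, known
group-sparse coefficients (defaults: $n = 400$, 20 groups × 5 features,
3 active groups, 60% within-group density, magnitude 1.5), labels drawn
from the logistic law at those coefficients. The automated checks measure
two selection qualities on this testbed: the feature-level nonzero-pattern
F1 of the CV-chosen model, and how often the selected group set equals the
planted one exactly. The second is the harder target, and it exposes a
structural tension of wrapped selection worth understanding before trusting
any CV-chosen support: the prediction-optimal $\lambda$ is systematically
smaller than the selection-consistent one, because at the $\lambda$ where
the support is exactly right the coefficients are still strongly shrunk and
the held-out accuracy sits below its plateau. The 1-SE rule absorbs much of
that gap, and the per-observation fold-$\lambda$ scaling removes a
refit-density bias, but on a minority of seeds the exact-support stretch of
the path remains more than one fold-SE below the best accuracy, and no rule
that respects the CV-accuracy band can land there. Exact support recovery
by CV-wrapped Sparse Group Lasso should therefore be read as a
high-probability outcome at strong signal, not a guarantee — which is also
why the selection report includes per-channel feature counts rather than a
bare channel list.

Degenerate inputs are handled explicitly: constant signals are rejected by
the AR fitter (no AR representation), signals shorter than the PSD window
or the 6-level DWT fail with the minimum length named, a class missing
from a training fold raises an error suggesting fewer folds, and label
draws that happen to miss a class in the design generator are patched
deterministically so downstream fits always see all $M$ classes.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
sizes chosen to exercise every code path while keeping a single-CPU run
comfortable: oracle comparisons on $n = 50$, 4-group instances across
$\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ and $M \in \{2, 3\}$; support
recovery over 50 seeds of the default `design_sim_spec()` with a 20-value
$\lambda$ path; and an end-to-end pipeline on 100 simulated trials
(50 per class) of the full 59-channel layout with $\alpha$ fixed at 0.5, a
15-value path and 10-fold CV. The independent optima come from a long-run
FISTA proximal-gradient solver (the closed-form Sparse Group Lasso
proximal operator makes it an algorithmically distinct route to the same
convex optimum) and, for the $\alpha = 1$ endpoint, from glmnet's
L1-penalized logistic regression; the one-dimensional inner problem is
checked against golden-section search.

## Known limitations

* Binary and small-$M$ multiclass problems are the design point; the
  per-feature curvature blocks make each outer iteration $O(N p d M^2)$.
* Groups must be contiguous, non-overlapping column blocks (channels);
  overlapping or hierarchical penalties are out of scope.
* The CV-chosen $\lambda$ targets predictive accuracy; exact support
  recovery additionally relies on the 1-SE rule and a sufficiently strong
  signal, and no finite-sample guarantee is claimed.
* Trial readers target the package's delimited-text layout; MATLAB
  containers and EDF/BIDS are not supported.
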