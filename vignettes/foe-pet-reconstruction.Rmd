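---
title: "Cross-entropy PET reconstruction with a Field-of-Experts prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-entropy PET reconstruction with a Field-of-Experts prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petfoe)
```

## The problem

Positron emission tomography measures coincidence counts
$y = (y_1, \dots, y_I)$ along lines of response; each bin is an
independent Poisson variable with mean
$\bar y_i = \sum_j a_{ij} x_j$, where $x \ge 0$ is the unknown activity
image and $A = (a_{ij})$ the system matrix. At low count rates —
the clinically interesting regime, because counts trade off against
dose and scan time — maximum-likelihood reconstruction becomes noisy
and unstable, and some form of regularization is needed.

`petfoe` implements a regularized reconstruction whose data-fidelity
term is the cross-entropy (Kullback–Leibler divergence)

$$ D(y, Ax) \;=\; \sum_i \Big( y_i \ln y_i - y_i \ln (Ax)_i - y_i +
(Ax)_i \Big), $$

whose minimizer over $x \ge 0$ coincides with the Poisson maximum
likelihood estimate, together with a *Field-of-Experts* (FoE) image
prior: a Markov-random-field model whose potentials are Student-t
"expert" functions of the responses of $K$ learned $5\times 5$ linear
filters $J^{(k)}$,

$$ E(x) \;=\; \sum_{k=1}^{K} \sum_{p} \alpha_k
\ln\!\Big(1 + \tfrac12 \big(J^{(k)} \!\ast x\big)_p^2\Big), \qquad
\phi(z, \alpha) = \big(1 + z^2/2\big)^{-\alpha}, $$

the sum over $p$ running over all filter positions fully inside the
image. The reconstruction minimizes the penalized objective

$$ J_{\mathrm{FoE}}(x) \;=\; D(y, Ax) + \beta\, E(x) $$

by a gradient scheme with the variable per-pixel step size
$x_j / s_j$ (with $s_j = \sum_i a_{ij}$ the sensitivity):

$$ x_j^{(n+1)} = x_j^{(n)} - \frac{x_j^{(n)}}{s_j}
\frac{\partial J_{\mathrm{FoE}}}{\partial x_j}\Big|_{x^{(n)}}. $$

With $\beta = 0$ this step is *algebraically identical* to the
classical ML-EM multiplicative update — the package asserts, rather
than assumes, this identity to $10^{-12}$ in its test suite. The
default settings are $\beta = 0.5$ and a fixed budget of 27
iterations; the unregularized EM baseline runs 12 iterations, and a
one-step-late baseline with a relative-difference prior ("CP", with
$\beta = 0.01$, $\gamma = 0.1$ and a geometric relaxation
$\lambda = 0.97$ per iteration) is included for comparison.

## Design choices, and why

### Projector

The acquisition model is an idealized 2D parallel-beam geometry:
Siddon-style ray tracing yields exact ray–pixel intersection lengths,
collected in a sparse matrix. The back projector is the exact
transpose, so the inner-product identity
$\langle Ax, y\rangle = \langle x, A^{\mathsf T} y\rangle$ holds to
floating point and the gradient of $D(y, Ax)$ is exactly
$s - A^{\mathsf T}(y/Ax)$. No attenuation, scatter, randoms, positron
range or detector blur is modeled: the reconstruction mathematics
only requires a non-negative linear $A$, and the idealization keeps
every experiment deterministic and desk-scale. Rays that miss the
field of view keep all-zero rows; every algorithm skips
zero-sensitivity bins and freezes zero-sensitivity pixels instead of
dividing by zero. A ray running exactly along an interior pixel
boundary splits its weight evenly between the two adjacent pixels, so
symmetric geometries produce symmetric matrices.

### The prior's gradient and boundary rule

The energy uses *valid* filter positions only (no padding); the
gradient scatters the influence values
$\psi_k(z) = \alpha_k z/(1+z^2/2)$ back through the exact adjoint of
the filtering operator. This makes the analytic gradient the true
derivative of the implemented energy — checked against central finite
differences at relative error $\le 10^{-5}$ — without inventing
boundary statistics. $\psi$ is odd and bounded by
$\alpha/\sqrt 2$ (attained at $z = \sqrt 2$), which is what makes the
prior edge-tolerant: large filter responses (edges) are penalized
much less than a quadratic penalty would.

### Non-negativity

The gradient step can propose negative pixels. The safeguard clamps
them to zero and, if the clamped iterate fails to decrease
$J_{\mathrm{FoE}}$, halves the step toward the previous iterate
(re-clamping each time) up to 10 times, falling back to the previous
iterate. Consequently the objective trace is non-increasing *by
construction*, which the suite verifies on full 27-iteration runs.
Pure clamping without backtracking is available via
`recon_config(..., safeguard = FALSE)`.

### Filter training and the shipped bank

Filters are trained by contrastive divergence (CD-1): chains start at
a minibatch of DC-removed $5\times5$ data patches, take one Langevin
step under the current model, and the parameters move along the
difference between the data and model expectations of
$\partial E/\partial\theta$; filters are projected back to zero mean
after every update and $\log\alpha_k$ is bounded for stability. The
defaults (6000 patches, 500 updates, batch 500, learning rate 0.05)
were chosen once for stable convergence at this problem size.

The shipped default bank (`default_filter_bank()`, 24 filters of
$5\times5$) is trained on *synthetic* images only — random
multi-ellipse anatomies with nested uptake levels, overlaid with 25%
multiplicative noise. The noise matters: reconstructed emission
images carry residual noise texture, and a prior trained on
noise-free piecewise-constant images becomes so confident that, at
$\beta = 0.5$, it flattens genuine structure. The bank is a synthetic
stand-in for priors trained on clinical corpora, and any bank written
by `write_filter_bank()` can be substituted.

CD determines only the *relative* expert weights; the absolute energy
scale of a trained bank depends on its corpus, while the
regularization weight is fixed at $\beta = 0.5$. The shipped bank is
therefore normalized to a total expert weight
$\sum_k \alpha_k = 4$ (`rescale_filter_bank()`), chosen once so that
the default $\beta$ smooths gently: on the default rod study the
regularized reconstruction reduces the background standard deviation
by roughly half while keeping the rod contrast-resolution within a
few percent of EM's. There is no claim that this scale transfers to
other banks or geometries; it is a property of the shipped bank.

### Phantoms and simulation

The rod phantom is a cylindrical body disk with rows of hot
cylindrical inserts (defaults: diameters 2, 3, 4, 5 mm, three rods
per row, activity 8:1 over background — activity ratios are read with
the insert *hotter* than background, since cold inserts would make
both the profiles and the detection task meaningless). The lesion
phantom is a multi-ellipse anatomy with a circular lesion of known
location at 5:1 or 3:1 over its local background. Rasterization is by
pixel-center inclusion, exactly testable against brute-force
counting. The simulator forward projects the truth, rescales the
expected sinogram to a target total count, and draws independent
Poisson bins from a private, restored RNG stream; count levels are
specified as *expected* totals.

What the synthetic data do not emulate: scanner physics (scatter,
randoms, attenuation, detector blur), anatomical realism, and 3D
effects. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the algorithms under an idealized Poisson
model, not clinical performance.

### Study sizes

The default study geometry is a $96\times96$ image (0.8 mm pixels)
with $128\times120$ sinogram bins; the low-count rod study uses
$5\times10^5$ expected counts, a proportional stand-in for the
multi-million-count regimes of full-scale simulations (the package
keeps the same 6:1 high/low ratio: $3\times10^6$ vs $5\times10^5$).
Replicated studies (three seeds, 25-vs-25 observer studies) run at
half scale ($48\times48$, $64\times60$ bins, $1.25\times10^5$ counts
— the same counts per pixel) so a full suite completes in minutes.
The lesion diameter defaults to 3 mm (about two pixels at desk
scale): small enough that the observer operates in its discriminative
range rather than saturating at AUC $= 1$.

### The observer

The channelized Hotelling observer extracts a patch at the known
lesion location, projects it onto four octave-spaced rotationally
symmetric difference-of-Gaussians channels, forms the Hotelling
template $w = S^{-1}(\bar v_+ - \bar v_-)$ from the average
within-class channel covariance (ridge-regularized by $10^{-6}$ of
the mean diagonal by default), and scores the area under the ROC
curve by the Mann–Whitney statistic. Templates are estimated by
resubstitution at the study's $25+25$ scale, which is optimistic by a
few hundredths of AUC (leave-one-out, available via
`method = "loo"`, errs the opposite way); the suite calibrates the
machinery against the multivariate-normal closed form
$\Phi(d_A/\sqrt 2)$ at a training size where that bias is inside a
0.02 band, and asserts that the bias shrinks with training size.
Because every method is scored by the same observer on the same
realizations, the between-method *ranking* is insensitive to this
bias.

### Numerical guards

Ratio denominators $\,(Ax)_i$ are floored at
$\varepsilon = 10^{-12}\,\overline{y_{>0}}$ when the corresponding
$y_i > 0$; bins with $y_i = 0$ contribute only their sensitivity
term. Initialization is a uniform positive image scaled so the
projected counts match the measured total. The one-step-late CP
denominator is floored at $0.1\,s_j$ to keep the multiplicative
update positive when the penalty gradient is strongly negative.

## What the package reproduces

At desk scale, with the synthetic shipped prior, the suite reproduces
the method's qualitative behavior: the regularized reconstruction has
a non-increasing objective, markedly lower background noise than EM
at a matched iteration count with rod contrast preserved within 10%,
and a lesion-detectability AUC at least as high as the 12-iteration
EM baseline on the majority of seeds of the replicated 25-vs-25
study. Absolute published contrast values from measured scanner data
are out of reach (they depend on an external dataset and a scanner
model this package deliberately does not include) and are not
claimed. All quantitative statements above are computed by the test
suite and by `scripts/acceptance.R`, not asserted from memory.

## Known limitations

* 2D only; list-mode, time-of-flight and 3D geometries are out of
  scope.
* The shipped prior is a synthetic stand-in; none of its filters have
  seen clinical anatomy, so no claim of anatomical fidelity attaches
  to it.
* The CP baseline follows the standard relative-difference
  formulation with a geometric relaxation of its weight; the exact
  published variant it stands in for is not fully specified by its
  three parameters.
* The Hotelling observer uses known-location detection
  (no search, no internal noise, no human-observer calibration).
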