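---
title: "Federated unrolled reconstruction for accelerated multi-coil MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated unrolled reconstruction for accelerated multi-coil MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedunroll)
```

## The problem

Accelerated MRI acquires only a subset of k-space (the spatial-frequency
domain) to shorten scan time, which makes image recovery an ill-posed
inverse problem. Learned reconstruction models need fully sampled training
scans, but clinical sites rarely hold many of those, and raw patient data
cannot be pooled across institutions. `fedunroll` implements, at desk
scale, the full experimental pipeline for studying one answer to this
tension: **federated training of unrolled model-based reconstruction
networks**, where only model weights — never k-space or images — travel
between clients and a server, followed by **client-side personalization**
of the broadcast model by fine-tuning on local data alone.

## Forward model and operators

A slice is a complex image $x \in \mathbb{C}^{H \times W}$. Each of $N_c$
receive coils sees it through a smooth complex sensitivity map $S_i$; a
Cartesian acquisition masks whole phase-encode (PE) columns with a binary
selector $P$. The per-coil measurement is

$$y_i = P F S_i x + n_i,$$

with $F$ the centered orthonormal 2-D Fourier transform and $n_i$ zero-mean
complex white Gaussian noise; $A = PFS$ collects all coils. Conventions
fixed across the package:

* **FFT**: centered (DC at the matrix center) and orthonormal, so the
  adjoint equals the inverse under full sampling and the adjoint identity
  $\langle Ax, y\rangle = \langle x, A^H y\rangle$ holds to machine
  precision (tested at 1e-10).
* **Mask**: a 1-D random pattern along the PE (column) axis replicated
  along readout, with a contiguous, centered auto-calibration (ACS) block
  of `round(0.08 * n_pe)` lines always sampled and `round(n_pe / R)` lines
  total (acceleration `R = 4` by default). The mask is drawn once per
  slice at dataset creation and never resampled.
* **Normalization**: every sample is divided by the maximum pixel of the
  RSS image reconstructed from the ACS lines alone, which makes all
  downstream metrics invariant to global k-space scaling.
* Arrays are column-major `H x W (x Nc)` with the coil axis last and the
  PE direction on the columns.

Because the mask removes whole PE columns, the readout-direction transform
cancels inside the normal operator: $F^H P F$ acts per coil as a single
precomputed $W \times W$ Hermitian matrix applied from the right. The CG
solver exploits this; the identity `gram == A^H(A(.))` is tested to 1e-13.

## The unrolled model

Reconstruction solves
$\arg\min_x \|y - Ax\|_2^2 + \lambda \|D(x;\Theta) - x\|_2^2$ by
alternating, for $N_u$ unrolls,

1. a **data-consistency step**
   $z_{n+1} = (A^H A + \lambda I)^{-1} (A^H y + \lambda x_n)$, approximated
   by a fixed number $N_{CG}$ of conjugate-gradient iterations warm-started
   at $x_n$ (iteration-count stopping only, so the graph has fixed depth);
2. a **learned denoiser** $x_{n+1} = D(z_{n+1};\Theta)$, a compact
   encoder–decoder with skip connections acting on the real/imaginary
   channel pair, with a residual connection and a zero-initialized output
   convolution (a fresh network is exactly the identity).

One weight collection $\Theta$ is shared across all unrolls, so the
parameter count is independent of $N_u$. The initialization is the
zero-filled adjoint $x_0 = A^H y$.

Training minimizes $-\mathrm{SSIM}$ between the coil-combined magnitude of
$x_{N_u}$ and the reference RSS image, per slice, with single-sample Adam
steps. The SSIM gradient is computed analytically (verified against finite
differences); gradients flow through the data-consistency block via the
implicit rule $\partial z / \partial x_n = \lambda (A^H A + \lambda I)^{-1}$,
itself applied with the same fixed-iteration CG. Because the forward solve
is truncated, this gradient is exact for the converged solve and
approximate for the truncated one — the standard choice for this model
class; descent is verified empirically (a tiny model overfits a single
slice past SSIM 0.9 within 500 steps).

### Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_unrolls` | unroll count $N_u$ | 6 | desk preset uses 4 |
| `n_cg` | CG iterations per block | 6 | desk preset uses 4 |
| `lam` | data-consistency coupling $\lambda$ | 0.05 | fixed, not learned (a learnable $\lambda$ would break the fixed-depth determinism we test for) |
| `denoiser_spec()` | scales / base channels | 2 / 8 | sized so one training step costs ~10 ms on one CPU; channels double per scale |
| `local_lr` | local Adam rate | 1e-4 | personalization searches its own rate |

The denoiser is deliberately small: the study's conclusions concern the
*federated optimization* of an unrolled model, not absolute image quality,
and a 2-scale/8-channel network keeps the full three-experiment suite
within minutes on a single CPU while preserving the architecture family
(encoder–decoder with skips). Both knobs scale the model up; the parameter
count of the full-scale network in the literature is not matched.

## Synthetic multi-site data

The generator replaces real multi-site raw data with ellipse phantoms
while preserving the statistical structure the study depends on. A
`client_profile` fixes three heterogeneity axes that stand in for the
clinical ones:

* **content family** (support shape and internal ellipse geometry) —
  stands in for anatomy;
* **contrast parameters** (region-intensity range, smooth within-region
  texture level) — stand in for pulse-sequence contrast;
* **SNR in dB** — stands in for field strength (the noise level of
  retrospectively under-sampled public data is never stated; an explicit
  SNR knob is our surrogate, defaults 14 and 20 dB).

Slices from one *subject* share ellipse geometry up to a small
deterministic shift and scale, so subject-level train/validation splits
are meaningful; each subject has its own smooth coil maps (Gaussian lobes
centered just outside the FOV at equispaced angles, SOS-normalized to 1).
Noise is injected into the full k-space *before* masking, so the
ACS-based normalization sees noise, emulating retrospective under-sampling
of an already-noisy acquisition. The default federation has 10 sites, each
with 5 training subjects of 10 slices (50 local slices) plus 2 held-out
validation subjects (20 slices); i.i.d. mode draws every site from one
profile with globally disjoint subjects, non-i.i.d. mode gives every site
a distinct (family, contrast, SNR) triple. All generation is a pure
function of one master seed, with per-client streams derived by fixed
offsets so adding a site never perturbs the others.

What the phantoms do **not** emulate: anatomical texture statistics,
coil-array geometry of real scanners, motion or off-resonance artifacts,
and inter-vendor reconstruction differences. Passing tests therefore
certify the *optimization and generalization machinery* under controlled
heterogeneity, not clinical image quality.

## Federated optimization

Training is synchronous with full participation: every round the server
broadcasts $\Theta_G$, every client runs `steps_per_round` local steps,
and all clients upload. Five server rules are implemented:

* **FedAvg** — elementwise mean of client weights.
* **FedAdam / FedYogi / FedAdaGrad** — the server treats
  $\Delta = \overline{\Theta_k} - \Theta_G$ as a pseudo-gradient and
  applies the corresponding adaptive recursion
  ($m \leftarrow \beta_1 m + (1-\beta_1)\Delta$; second moment per
  variant; $\Theta_G \leftarrow \Theta_G + \eta_g\, m / (\sqrt{v} + \tau)$).
  Server hyper-parameters follow the conventional adaptive federated
  optimization defaults — $\beta_1 = 0.9$, $\beta_2 = 0.99$,
  $\tau = 10^{-3}$, $\eta_g = 10^{-2}$ — all exposed in `fed_config()`.
* **Scaffold** — control variates $c_k$ (client) and $c_g$ (server)
  estimate client drift; the correction $-c_k + c_g$ is applied to the raw
  gradient *before* it enters the local optimizer (the original algorithm
  is written for plain SGD; applying the correction at the gradient level
  is the natural composition with Adam clients, and `local_optimizer =
  "sgd"` recovers the textbook form). The control-variate update uses
  option (ii), the cheap difference form
  $c_k^+ = c_k - c_g + (\Theta_G - \Theta_k)/(S\eta_l)$ — but note this
  displacement form is an SGD identity: under SGD the displacement divided
  by $S\eta_l$ *is* the mean corrected gradient, so
  $c_k^+ = \overline{g}$, the mean raw gradient over the visited iterates.
  Under Adam the displacement lives on the optimizer's normalized step
  scale (order 1 per coordinate) while variates are added to raw
  gradients, so the literal formula injects wildly mis-scaled corrections;
  we therefore use the gradient-unit form $c_k^+ = \overline{g}$ for
  adaptive clients (algebraically identical for SGD clients, which keep
  the displacement form). Option (i), a fresh gradient at the final
  weights, is available in config. With variates pinned to zero and SGD
  clients, Scaffold reproduces FedAvg trajectories exactly (tested).

The communication-budget axis holds the total local step count fixed and
varies the round count: `make_schedule(total, rounds)` enforces
`rounds * steps_per_round = total` exactly (the full-scale study uses
24,000 steps over 240/120/80/60/40/24/4 rounds; the desk preset uses 400
steps over 20/10/4). Local Adam state is reset at each broadcast — whether client optimizer
state should persist between rounds is a genuinely open choice, and
resetting is the one consistent with "clients start from the broadcast
weights". The pooled **centralized** baseline trains one model on the
union of all client data with the same total step budget as a single
client; clients are processed in fixed id order, and aggregation is
order-independent by construction.

## Personalization

After the final broadcast, a client may fine-tune the global model on its
own slices only (the server is never contacted again — enforced by the
interface, which hands `personalize_client()` nothing but weights and the
local dataset). Two hyper-parameters are selected by 5-fold
cross-validation on the ~50 local slices: the fine-tuning rate `r_fine`
(grid default {1e-5, 1e-4})
and the epoch count `n_fine` (early stopping at the epoch maximizing mean
held-out SSIM; epoch 0 — no fine-tuning — is a candidate, so
personalization can decline to move the model). Folds are assigned at the
slice level, stratified by subject, so every fold sees every subject;
ties break toward the smaller rate, then the smaller epoch count (least
perturbation of the global model). The `max_epochs` ceiling defaults to
200 at full scale; desk experiments use 3–4.

## Numerical choices and degenerate inputs

* SSIM: 7×7 **uniform** windows fully contained in the image,
  sample-covariance normalization ($N/(N-1)$), $k_1 = 0.01$, $k_2 = 0.03$,
  data range = per-slice reference maximum — the convention of the
  standard accelerated-MRI evaluation stack (published evaluation
  protocols differ on Gaussian versus uniform windows; ours is declared,
  not inferred). Images smaller than the window are rejected.
* NRMSE: $\|x - \hat{x}\|_2 / \|x\|_2$; a zero-norm reference is an error,
  as is a zero baseline in percent change.
* Percent changes round half away from zero (base R rounds half to even,
  which does not reproduce printed tables), at 2 decimals for SSIM and 0
  for NRMSE.
* CG uses iteration-count stopping only; a zero residual exits early; the
  $\lambda \to \infty$ limit returns the warm start (tested at
  $\lambda = 10^6$).
* All-zero ACS regions raise a degenerate-normalization error rather than
  producing NaNs.
* The compiled kernels compute the centered DFT as cached unitary matrix
  products, which at 32–64 pixel sizes is faster than generic FFTs and
  bit-stable across calls; R-level `fft2c()` and the compiled path agree
  to 1e-13 and both are exercised by tests.

## Desk-scale problem sizes

All shipped experiments and tests run on one CPU with these sizes, chosen
once as the package's reduced study conditions: 32×32 slices, 4 coils,
$N_u = N_{CG} = 4$, 10 clients × 50 slices (+20 validation), 400 local
steps over 20 rounds (federation experiments), 200 steps over 10 rounds
(personalization experiments), and a 600-step budget for the per-size
models of the low-data sweep — enough that every grid size trains to its
validation plateau, mirroring the full-scale study's per-size training to
saturation (at 300 steps the 250-slice model is still ascending, which
inverts the plateau). The full-scale configuration remains expressible
through the same constructors (`unroll_config(6, 6, ...)`,
`make_schedule(24000, 240)`), but is documentation, not a tested surface.

One caveat the desk scale imposes: with a few hundred total local steps,
the *un-personalized* model's sensitivity to the communication budget is
within run-to-run noise (SSIM differences of order 1e-3 between 20 and 5
rounds), so the full-scale phenomenon of personalization flattening the
budget curve cannot be measured here — only the robust half of it, that
cross-validated fine-tuning helps the unseen site at every budget point,
is asserted by the tests. The budget axis becomes informative in the
24,000-step regime, which the same functions express.

## Known limitations

* Phantom realism as above; absolute SSIM/NRMSE values are not comparable
  to numbers obtained on full-resolution clinical raw data and are not
  asserted anywhere.
* The truncated-CG gradient is approximate (exact only at CG convergence).
* Client dropout, asynchronous updates, secure aggregation, and
  adversarial feature-alignment baselines are out of scope.
* Sensitivity maps are known by construction (no ESPIRiT-style
  estimation); the map-estimation error of real pipelines is absent.
* `eta_g`, `beta1`, `beta2`, `tau` defaults are conventions and deserve
  a sweep before any quantitative claim about the adaptive variants'
  ranking.
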