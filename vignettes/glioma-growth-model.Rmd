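---
title: "Modeling glioma growth, invasion and clonal competition on a voxel lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glioma growth, invasion and clonal competition on a voxel lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gliovox)
```

## The model

gliovox simulates glioblastoma growth and invasion on a 2D lattice of 4 mm²
voxels. Each voxel carries live-cell densities $n_i$ for one or more clones
(distinguished by ploidy), dead cells $N_d$, dissolved oxygen $N_o$ (mg/L),
glucose $N_g$ (mM), a recruited-vessel count $V$, and a baseline tissue
stiffness. Writing $N = \sum_i n_i$, each clone evolves by

$$\frac{\partial n_i}{\partial t}
 = \underbrace{\gamma_i\, n_i \Big(1 - \tfrac{N + N_d}{\sigma}\Big)\,
   \Gamma_i(N_o, N_g)}_{\text{proliferation}}
 \;-\; \underbrace{d_i(N_o, N_g, T_r, T_c)\, n_i}_{\text{death}}
 \;+\; \underbrace{\nabla\!\cdot\!\big(K_i(N_g, S)\, \nabla n_i\big)}_{\text{migration}},$$

with dead cells accumulating from every death term and clearing at rate
$c_d$. Resources are local (no spatial resource diffusion): oxygen is consumed
at $\iota_o N_o N$ and supplied at $\omega_o V$; glucose analogously, with the
consumption coefficient switching between $\iota_g$ and $\iota_{g2}$.

**Metabolic switch.** Cells run oxidative phosphorylation while
$N_o \ge O_{th}$ and glycolysis below it; ties resolve to oxphos
($H(0) = 1$ throughout the package). The switch selects *which* substrate
gates proliferation and survival: under oxphos
$\Gamma_i = N_o / (N_o + \alpha_g)$ and survival saturates in oxygen with
half-max $\alpha_d$; under glycolysis both use glucose, with clone-specific
half-max constants $\beta_{g,i}$ and $\beta_{d,i}$. The switched ("or") form
is deliberate: a product form would make both substrates limiting at once,
which is not how the metabolic states are described. One consequence worth
knowing: oxphos survival is glucose-independent, so glucose-mediated
starvation only acts on hypoxic (glycolytic) tissue.

**Starvation death** is $d_R (1 - \mathrm{Sv})$ with $\mathrm{Sv}$ the
saturating survival factor above. Because the shrinkage rate
$d_R = 0.171$/day exceeds the proliferation rate $\gamma = 0.063$/day, net
growth under glycolysis is negative at any physiological brain glucose
(≤ 2.7 mM): glycolytic tissue always shrinks, faster for clones with larger
$\beta_{d,i}$. Sustained growth therefore requires oxygen — pristine baseline
or recruited vessels.

**Migration.** The coefficient is
$K_i = v_{max}\, \phi_i(N_g)/\Phi \cdot \hat f(S)$, where
$\phi_i(g) = e^{-a_{mig} g} - e^{-b_{mig} g}$ is the biphasic glucose
response (zero without glucose, peaked at $\ln(b/a)/(b-a)$), $\Phi$ is the
largest peak across active clones — so the fastest clone tops out at exactly
$v_{max}$ and relative clone differences are preserved — and $\hat f$ is the
stiffness parabola $c_2 S^2 + c_3 S$ clamped to $[0, f_{opt}]$ and normalized
by its maximum. The measured 2N curve (0.53, 0.57 1/mM) is much flatter than
the 4N curve (0.34, 0.95 1/mM), so after shared-peak normalization diploid
cells migrate roughly an order of magnitude slower than tetraploid cells at
every glucose level. The parabola's optimum (≈ 85 kPa) lies far above brain
stiffness, so over the physiological 0–3 kPa range the modifier is small
(≈ 0.02–0.07) and effectively increasing. The transport term is implemented
as conservative diffusion $\nabla\!\cdot\!(K \nabla n)$ on a 5-point stencil
(face coefficients are arithmetic means, zero-flux boundaries): cell mass is
conserved to round-off, which we audit in the tests. The explicit scheme
requires $\max(K)\,\Delta t \le 1/4$ and refuses to run otherwise.

**Stochastic angiogenesis.** Once a voxel's combined density reaches a
quarter of carrying capacity, vessels are recruited with per-day probability
$p_0 \sum_j N_j N_{d,j} / (N_j + N_{d,j})^2$ over the four edge neighbors.
Each neighbor term is maximal (1/4) at a 50:50 live/dead mix, so on the von
Neumann neighborhood $p_0 = 0.2$ is the literal ceiling. Recruitment is the
model's only stochastic element; one Bernoulli draw per voxel per simulated
day, fully determined by the run seed. The focal voxel is excluded from the
neighbor sum, and vessels never regress.

**Therapy.** Radiation fractions act as instantaneous pulses at the start of
the fraction day: survival is linear-quadratic in an effective dose
$d \cdot \mathrm{OER}(N_o)/r^*$, with an Alper–Howard-Flanders-style
enhancement curve $\mathrm{OER} = (r^* N_o + K_m)/(N_o + K_m)$ whose
half-effect constant $K_m$ we tie to the model's oxygen survival scale
$\alpha_d$ (the source model names $r^*$ but gives no curve; this is the
standard dose-modifying form, anchored so anoxic tissue is exactly
$r^*$-fold protected). Killed cells transfer to the dead compartment and
each fraction increments a global delivered-fraction counter that softens
stiffness by a factor $c_0$ (no per-voxel dose map is modeled, since no dose
distribution is specified). Temozolomide adds an oxygen-saturating death
rate on active days. Surgery zeroes all cells inside the cavity, removes a
tenth of baseline stiffness and half of both resources there, and
accumulates the cavity mask; repeating a resection repeats the reductions
(deliberately not idempotent). Clones do not differ in therapy sensitivity —
a deliberate simplification carried over from the source model.

**Update order.** Each simulated day applies: scheduled surgery; the day's
radiation pulse; then, per Euler substep (default $\Delta t$ = 0.1 day):
death (starvation + TMZ) → dead-cell clearance → proliferation → migration →
resource update; and finally the daily vasculature draw and derived-stiffness
recomputation. Death-before-proliferation follows the stated ordering of the
source model; resources are updated after movement so that recruitment and
consumption see post-growth densities. Non-negativity is clamped after every
substep and audited at every snapshot.

## Parameters

Defaults are the literature-informed values of the source model's parameter
table (`sim_params()`), e.g. $\gamma = 0.063$/day, $\sigma = 15{,}448$
cells/voxel, $p_0 = 0.2$, $\omega_g = 0.18204$ mM/day,
$O_{th} = 0.051$ mg/L, LQ $\alpha = 0.102$/Gy, $\beta = 0.008$/Gy²,
$r^* = 3$. Two groups deserve comment.

**Clone constants.** The two aneuploid clones fitted to longitudinal patient
data (`fitted_patient_clones()`) have ploidies 1.98 and 2.29 with survival
half-max 1.17 vs 2.13 mM and proliferation half-max 1.66 vs 1.72 mM. For
diploid/tetraploid experiments these are extrapolated along ploidy
(`extrapolate_clone_params()`); linear extrapolation is the default — the
minimal assumption given that only two fitted points exist, and it keeps the
4N constants in a plausible range (β_d ≈ 7.4 mM) where the log-linear
power-law alternative (≈ 21 mM) would make tetraploid cells almost
non-viable under glycolysis. Migration constants are not extrapolated; the
target clone inherits the measured 2N or 4N curve by nearest canonical
ploidy. Clone-specific proliferation rates default to the shared $\gamma$;
whether the fitted clones differed in $\gamma$ is not reported, so we do not
invent a difference.

**Consumption rates.** The per-cell consumption rates $\iota_o, \iota_g,
\iota_{g2}$ are not in the published table (they live in supplementary data
we do not ship). We bracket them by two structural requirements and fix them
once. (i) A crowded voxel must become hypoxic on a clinically sensible
timescale — about a week at carrying capacity:
$\iota_o \ge \ln(N_o^0/O_{th}) / (7\sigma) \approx 1.2\times10^{-5}$.
(ii) A small premalignant focus (~10³ cells) growing at $\gamma$ must be able
to reach the angiogenic switch density $\sigma/4$ before exhausting local
oxygen — otherwise stochastic vessel recruitment, a central model mechanism,
could never activate from a small seed; accounting for logistic slowdown and
migration export this gives $\iota_o \lesssim 1.3\times10^{-5}$. We use
$\iota_o = \iota_g = 1.2\times10^{-5}$ per cell per day, with glycolysis
consuming glucose twice as fast ($\iota_{g2} = 2.4\times10^{-5}$). All three
are config-exposed and should be re-fit when calibrating to data.

## Resource atlases, real and synthetic

Imaging-derived maps convert to model inputs through three transforms:
`suvr_to_glucose()` reflects an FDG-PET SUVr map (uptake is inversely related
to free glucose) and min-max scales it to the physiological brain range
1.0–2.7 mM — the transform is invariant to positive affine rescaling of the
input and uses plain min-max over valid voxels; `oef_to_do2()` multiplies a
qBOLD oxygen extraction fraction by the capillary oxygen content 0.4655
mg/L; `excess_glucose()` converts regional vascular-density fold differences
(tumor core vs infiltrating zone) into an excess supply rate, clamped at
zero because regions less vascular than normal brain supply no extra
resource.

`synthetic_atlases()` replaces downloaded imaging with smooth correlated
random fields (white noise low-pass filtered with a Gaussian kernel,
correlation length 4 voxels by default), standardized and mapped into the
physiological ranges. The `low_glucose` and `high_glucose` presets emulate
the glucose-poor and glucose-rich brain regions of the competition
experiments, with spatial mean glucose 1.22 and 2.36 mM. Because perfusion
delivers glucose and oxygen together — and because glucose-mediated
starvation only acts on glycolytic tissue — the glucose-poor preset is
modeled as a poorly perfused region with mean dissolved oxygen 0.04 mg/L,
just below the metabolic switch threshold, while the glucose-rich preset is
well perfused (0.186 mg/L ≈ an oxygen extraction fraction of 0.4 times the
capillary content). These means were fixed from that mechanistic argument;
they are generator settings, not fitted quantities.

What the generator does *not* emulate: anatomical structure (white/gray
matter tracts, ventricles), the empirical covariance between the three maps,
age effects, and out-of-brain masking. Tests passing on synthetic atlases
demonstrate the machinery and the qualitative resource logic, not
patient-level predictive accuracy.

## The premalignant competition and recurrence experiments

`experiment_premalignant()` seeds 1,000 cells (half diploid, half
tetraploid, constants extrapolated from the fitted clones) into a single
central voxel and lets them compete for three years. Extinction is declared
on the first day a clone's maximum per-voxel representation falls below one
cell — the wording of the source criterion, taken literally. In the
glucose-poor preset the tissue is glycolytic from the outset, so survival is
glucose-gated: the tetraploid clone, whose survival half-max (≈ 7.4 mM) far
exceeds ambient glucose (≈ 1.2 mM), dies at near-maximal rate and goes
extinct within weeks, well before the diploid clone. In the glucose-rich
preset the focus grows aerobically, outruns its oxygen, crosses the
angiogenic density gate, and recruited vessels restore oxygen (the
glycolysis/oxphos switchback); both clones persist to year three. Because
recruitment is stochastic, the packaged checks run five seeds per preset and
require the qualitative outcome in at least three.

`experiment_recurrence()` initializes the same synthetic post-surgery tumor
bed (a Gaussian bolus of 2.1 million cells, truncated at carrying capacity)
with a purely diploid or purely tetraploid population, with or without the
standard chemoradiation preset (30 × 2 Gy weekday fractions with concurrent
temozolomide, then six adjuvant cycles), and summarizes progression as the
slope of log total burden over the final 90 days — a formula-free "rate of
progression" made concrete.

## Parameter fitting

`fit_simulation_params()` minimizes the voxelwise squared error between
simulated and observed total-density maps over a chosen subset of
parameters (`v_max`, `delta_R`, per-clone glucose constants). The simulation
RNG is frozen per evaluation, making the stochastic model's objective
deterministic given the parameters. Fitting runs in two stages — first with
a single aggregate clone, then per-clone from the stage-1 solution —
mirroring the two-iteration scheme used for the patient fit. The optimizer
is derivative-free (golden-section in 1D, Nelder–Mead with deterministic
multi-starts otherwise) because the objective is stepped by the daily
stochastic recruitment and not smooth. A voxelwise objective was chosen over
mask-overlap alternatives as the more informative default given full density
maps.

## The transwell assay model

The two-chamber migration assay is modeled with three compartments: top
alive ($T_a$), bottom alive ($B_a$), top dead ($T_d$), with
$\dot T_a = (\lambda_T - \mu - \delta) T_a$, $\dot B_a = \mu T_a$,
$\dot T_d = \delta T_a$. The solution is closed-form (with the
$k \to 0$ limit handled analytically), and `transwell_fit()` performs
non-negative least squares of all three trajectories against the observed
counts, equally weighted on raw counts (the assay is designed so the
compartment counts are comparable in magnitude), with a seeded residual
bootstrap for per-rate uncertainty. Bottom-chamber proliferation is omitted:
the model as formulated tracks growth only in the top chamber, and bottom
counts rise solely by arrival. Starting values come from a log-linear decay
estimate of $k = \lambda_T - \mu - \delta$ plus linear projections for
$\mu$ and $\delta$, which are exact for noise-free data — so noise-free
recovery is limited only by floating point. One identifiability caveat:
when proliferation is minimal (as observed in the assay), $\lambda_T$ is
determined only as $k + \mu + \delta$; its absolute error stays small
(~0.001/h at 5% count noise) but its relative error is large simply because
the true value is near zero. The recovery checks therefore report the median
relative error across rates and replicates, per-rate relative errors for
$\mu$ and $\delta$, and an absolute error for $\lambda_T$.

## Numerical choices and problem sizes

Forward Euler throughout with default $\Delta t$ = 0.1 day (the step must
divide one day evenly so the daily recruitment draw stays aligned);
non-negativity clamps after every substep; the diffusion stability bound is
enforced with an error, not a silent fix; the logistic single-voxel
benchmark agrees with the closed form to 0.4% at $\Delta t$ = 0.05 over 100
days and halving the step changes trajectories by well under 5%. Degenerate
inputs fail loudly: constant SUVr maps, identical fitted ploidies, all-zero
assay counts, out-of-range extraction fractions, stability violations.

The packaged experiments use 64×64 grids — large enough for the invasion
and angiogenesis dynamics to express themselves while keeping a three-year
two-clone run around twenty seconds — with five-seed ensembles for the
stochastic competition outcomes, 20 replicate assays for transwell recovery,
and 30-day self-consistency fits for parameter recovery.

## Known limitations

No spatial diffusion of oxygen or glucose and no vascular geometry; no
vessel regression, occlusion or permeability differences; a global (not
per-voxel) radiation stiffness effect; no ploidy-dependent therapy
sensitivity or cell size; 2D only. The biphasic migration form
(difference of exponentials) is a reconstruction consistent with the
published 1/mM constants and the observation that tetraploid cells
out-migrate diploid cells at all glucose concentrations; the original
supplementary functional form may differ in detail.
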