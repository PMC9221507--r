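---
title: "Measuring leaf shape from boundary polygons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf shape from boundary polygons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(leafmorph)
```

## The measurement problem

Flat, entire (unlobed) leaves such as those of alpine oaks are routinely
digitised as closed boundary polygons: an ordered trace of planar
coordinates around the lamina edge, in physical units after scan
calibration. `leafmorph` takes such polygons — with two landmark
vertices marking the petiole insertion (base) and the apex — and derives
the quantities that leaf-economics and leaf-allometry work is built on:
lamina area $A$, length $L$, maximum width $W$ and its axial position
$L_W$, widths at fixed fractions of the length, the areas of the two
sides of the length axis, and leaf dry mass per unit area (LMA).

Upstream image processing (scanning, thresholding, edge extraction) is
deliberately out of scope: the package consumes coordinates, so any
segmentation tool can feed it. Landmark-based geometric morphometrics
(Procrustes superposition, centroid size) is also out of scope — entire
leaves offer too few reliable landmarks, which is exactly why the
index-based description below is used instead.

## The canonical frame and its conventions

All measurements are taken in a canonical frame
(`orient_leaf()`): the base at the origin, the apex on the positive
$x$ axis, winding counter-clockwise. Three operational conventions are
needed that published descriptions usually leave implicit; they are
design choices of this package:

* **Length axis.** $L$ is the base-to-apex *chord*. When landmarks are
  missing, the farthest-apart vertex pair is used as a documented
  fallback. (An alternative — the maximal caliper length — coincides
  with the chord for the shapes treated here.)
* **Width.** The width at an axial station is the spread
  $\max(y)-\min(y)$ of the boundary crossings of the perpendicular line
  at that station, not a summed interior chord. The two definitions
  agree for laminas that are single-valued above and below the axis;
  they differ for lobed edges, which this package does not target.
* **Left/right.** "Left" is the positive-$y$ side of the canonical
  frame. Scanning does not record adaxial orientation, so the *sign* of
  the bilateral area ratio is arbitrary; only its magnitude is
  orientation-free, and the tests rely on $|\ln\mathrm{AR}|$ only.

The width profile of a polygon is piecewise linear with knots at the
vertex stations, so `max_width()` scans a uniform grid (default 1001
stations) *plus* all vertex stations, then refines the bracketing
interval by golden-section search to an axial tolerance of
$10^{-6} L$. On a width plateau (e.g. a rectangle) the smallest axial
position is reported, and the refinement step is only accepted when it
strictly improves the width, so this tie-break is stable.

## The six shape indices

From one measurement pass (`measure_leaf()`), `shape_indices()`
computes:

$$\mathrm{RWL} = \frac{W}{L}, \qquad
  \mathrm{EI} = \frac{A}{\tfrac{\pi}{4} L W}, \qquad
  \mathrm{CR} = \frac{L_W}{L},$$

$$\ln\mathrm{PRI} = \ln\frac{W_{1/4L}}{W_{3/4L}}, \qquad
  \ln\mathrm{DRI} = \ln\frac{W_{1/8L}}{W_{7/8L}}, \qquad
  \ln\mathrm{AR} = \ln\frac{A_{\mathrm{left}}}{A_{\mathrm{right}}}.$$

EI (the ellipticalness index) is 1 for an exact ellipse, $4/\pi$ for a
rectangle and $2/\pi$ for a rhombus; CR above 0.5 marks an obovate
lamina (widest towards the apex). All six are dimensionless and scale
invariant. LMA is `dry_mass / (A * 1e-4)` in g m⁻² for $A$ in cm².

## Area–dimension scaling

Three log-scale fits cover the standard allometric questions
(`fit_montgomery()`, `fit_power_free()`, `fit_similarity_fixed2()`):

* the Montgomery proportionality $A = \mathrm{MP}\cdot L W$, fitted as
  $\ln A = a + \ln(LW)$ with slope fixed at 1 and
  $\mathrm{MP} = e^{a}$; MP and EI are the same quantity up to the
  ellipse constant, $\mathrm{MP} = \tfrac{\pi}{4}\mathrm{EI}$;
* the free power law $\ln A = b + \gamma \ln L$ (ordinary least
  squares);
* the principle-of-similarity model $\ln A = c + 2\ln L$.

Numerical conventions, stated because they change third-decimal
results: RMSE uses $n-1$ residual degrees of freedom for the
one-parameter fixed-slope fits and $n-2$ for the free fit; $r$ is the
Pearson correlation between $\ln A$ and the model's regressor on the
log scale; intervals use the $t$ distribution. With zero regressor
variance $r$ is reported `NA` with a warning rather than an error, so
degenerate trees do not abort a population run.

`rmse_vs_cv()` formalises the diagnostic that the similarity model
degrades where leaf proportions vary: per tree it pairs the fixed-slope
RMSE with the coefficient of variation of RWL, and reports the
cross-tree correlation.

## Superellipse theory

A superellipse $|x/\alpha|^n + |y/\beta|^n = 1$ interpolates rhombus
($n=1$), ellipse ($n=2$) and rectangle ($n\to\infty$). Its area is
$\mathrm{MP}(n)\, L W$ with

$$\mathrm{MP}(n) = \frac{\Gamma(1+1/n)^2}{\Gamma(1+2/n)}
 = 4^{-1/n}\sqrt{\pi}\,\frac{\Gamma(1+1/n)}{\Gamma(1/2+1/n)},$$

the two forms being equal by the Legendre duplication formula. One
published rendering of the right-hand form carries $\pi$ where
$\sqrt{\pi}$ must stand; the $\sqrt{\pi}$ resolution is forced by three
independent checks ($\mathrm{MP}(1)=\tfrac12$,
$\mathrm{MP}(2)=\tfrac{\pi}{4}$, $\mathrm{MP}(n)\to 1$) and the package
asserts the equivalence of both forms to $10^{-12}$ over
$n \in [0.5, 100]$. `se_area_coefficient()` evaluates the
duplication-reduced form via `lgamma()` for stability at large $n$.
`ei_of_n()` is $\mathrm{MP}(n)/(\pi/4)$: a strictly increasing sigmoid
approaching $4/\pi \approx 1.27$ from below.

`se_boundary()` discretises the curve on a uniform parameter grid
(not arc length), so vertices cluster at the corners for large $n$;
the discretisation-convergence tests use $\geq 4096$ vertices, where
polygon areas agree with the closed form to $10^{-4}$ relative.
Floating-point sines at the landmark angles are snapped to zero before
the $2/n$ power is taken, because $\epsilon^{2/n}$ is $O(1)$ for large
$n$ and would otherwise displace the base and apex vertices.

## The synthetic population generator

`simulate_population()` emulates the study design the analysis is meant
for: sites as random-intercept levels, 30 trees per site with DBH
(diameter at breast height) uniform on 8.6–96.4 cm, and 100–110 leaves
per tree. Five free latent traits per leaf — area, LMA, RWL, CR and
lnAR — follow DBH-linear models
$\mathrm{trait} = \beta_0 + \beta_1\,\mathrm{DBH} + \alpha_{\mathrm{site}} + \varepsilon$
with $\alpha \sim N(0,\sigma_\alpha^2)$,
$\varepsilon \sim N(0,\sigma_\varepsilon^2)$. A boundary cannot
independently realise EI, lnPRI and lnDRI once length, width, CR,
exponents and asymmetry are fixed, so those three indices are
*emergent* properties of the realised shape rather than extra model
dials; recovery tests therefore target the five free traits.

Leaves are realised as **piecewise superellipses**: a basal
half-superellipse on $[0, \mathrm{CR}\,L]$ and an apical one on
$[\mathrm{CR}\,L, L]$, both attaining width $W$ at the junction, with
the upper half-width scaled by $1+\epsilon$ and the lower by
$1-\epsilon$. This construction has closed-form area, width profile
and left/right ratio (`pse_area()`, `pse_width()`,
$A_L/A_R = (1+\epsilon)/(1-\epsilon)$), which is what makes every
geometry operation testable against an independent oracle. It is an
explicit stand-in for ovate/obovate lamina models in the literature,
not a reimplementation of any of them.

Generator defaults are the package's own order-of-magnitude choices on
the study-system scales (lamina area of order 10 cm² rising with DBH,
LMA of order 200 g m⁻² falling with DBH, RWL near 0.68, CR slightly
obovate at 0.52, lnAR centred on 0). Two constraints shaped them:

* the positivity and domain guards (area > 0, CR in (0,1), …) must be
  *inactive* in ordinary operation — draws violating them are resampled
  with a warning and counted, and if resampling were routine the
  realised trait distribution would no longer follow the stated linear
  model, silently biasing recovery studies. Defaults keep the
  violation probability below about 0.2%.
* the superellipse exponent range (default 1.5–2.5) keeps the shape
  family's effective area coefficient in the 0.70–0.82 band typical of
  elliptical-to-obovate leaves, i.e. EI scattered around 1.

Boundary vertex jitter is available (`boundary_noise_sd`) but defaults
to 0 so that oracle tests stay exact; with jitter on, the analytic
area/width oracles hold only in expectation. What the generator does
*not* emulate: measurement error from segmentation, petiole remnants,
lobed or toothed margins, non-Gaussian trait tails, and any biological
mechanism behind the site contrast ("growth pattern" is modelled as
nothing more than a random intercept). Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under
the stated model, not robustness to real-world artefacts.

## The mixed-model stage

`fit_mixed()` estimates the random-intercept model per trait by REML
(the conventional default of the mixed-model framework; the criterion
choice matters for $\sigma_\alpha$ with few groups) and reports Wald
p-values for the fixed effects — adequate at the reporting granularity
of significance thresholds, and deliberately not Satterthwaite or
Kenward–Roger. The intraclass correlation coefficient is

$$\rho = \frac{\sigma_\alpha^2}{\sigma_\alpha^2 + \sigma_\varepsilon^2},$$

0 when sites do not differ and approaching 1 when the site contrast
dominates. Field designs with only two sites are permitted — and are
the design this analysis descends from — but the package warns that
variance components from two levels are weakly identified; simulation
studies here use 10 sites where the ICC itself is the target. A
boundary fit $\sigma_\alpha = 0$ is allowed and flagged rather than
treated as an error. The test suite cross-checks `fit_mixed()` against
an independent dense-matrix profile-REML implementation, and the
tree-to-tree ANOVA/Tukey comparisons of the original workflow are
intentionally left to standard tools (`aov()`, `TukeyHSD()`).

## Problem sizes and determinism

Everything is reproducible from integer seeds, and the simulation
sizes used in the shipped tests are the package's own choices: oracle
geometry at 1024–4096 vertices; Montgomery identity checks on 500
measured ellipse polygons; the RMSE-versus-CV property on 30 trees of
80 leaves; slope/ICC recovery on 50 replicates of 10 sites × 30 trees
× 100–110 leaves (traits-only mode — realising 1.5 million polygons
would add nothing to a trait-level recovery check); and a scaled-down
full-pipeline run (4 sites × 8 trees × 30 leaves at 256 vertices) that
exercises geometry → indices → mixed model end to end.

## A compact worked example

```{r example}
cfg <- synthetic_config(n_sites = 2, trees_per_site = 5,
                        leaves_per_tree_range = c(20, 25),
                        n_vertices = 256, seed = 42)
pop <- simulate_population(cfg)
df  <- measure_population(pop, resolution = 201)

# pooled Montgomery fit and its EI equivalent
fit <- fit_montgomery(df)
fit
mp_to_ei(fit$MP)

# per-tree structure
head(per_tree_summary(df)[, c("tree_id", "n_leaves", "MP", "r", "CR_mean")])

# the mixed-model table (two sites: expect the identifiability warning)
table2_fit(df, traits = c("A", "RWL", "CR"))
```

## Known limitations

* Lobed or toothed margins violate the width convention's assumptions;
  widths are still well defined (crossing spread) but lose their usual
  interpretation.
* The self-intersection scan is quadratic and therefore skipped by
  default above 600 vertices; generated boundaries are simple by
  construction, but hand-made large polygons should be checked with
  `is_simple_polygon()` once.
* `L_W` on width plateaus is reported at the smallest attaining
  station; the centroid ratio of near-rectangular laminas is
  accordingly pinned to the plateau edge.
* Variance components from two grouping levels are weakly identified;
  the two-site default mirrors the emulated design, not an inferential
  recommendation.
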