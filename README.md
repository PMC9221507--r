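# leafmorph

Leaf shape morphometrics from boundary coordinates, for studies of
entire (unlobed) laminas — alpine oaks and similar elliptical-to-obovate
leaves — where the questions are: how do leaf size, shape and dry mass
per unit area (LMA) vary across trees of different size, and does the
proportionality between leaf area and the length–width product survive
that variation?

The package takes closed boundary polygons of the lamina edge (planar
coordinates in cm, with base and apex landmark vertices) and provides:

* **Geometry** — canonical orientation along the base–apex chord, then
  lamina area *A* (shoelace), length *L*, the width profile, maximum
  width *W* and its axial position *L_W*, widths at 1/8, 1/4, 3/4 and
  7/8 of *L*, and the areas of the two sides of the length axis.
* **Six shape indices** — RWL = W/L; the ellipticalness index
  EI = A / ((π/4)·L·W) (1 for an exact ellipse); the proximal and
  distal ratio indices ln PRI = ln(W₁/₄L / W₃/₄L) and
  ln DRI = ln(W₁/₈L / W₇/₈L); the bilateral area ratio
  ln AR = ln(A_left / A_right); and the centroid ratio CR = L_W / L
  (> 0.5 marks an obovate lamina). Plus LMA = dry mass / area in g m⁻².
* **Scaling fits** — the Montgomery proportionality A = MP·L·W fitted
  as ln A = a + ln(LW) with slope fixed at 1 (MP = eᵃ,
  MP = (π/4)·EI); the free power law ln A = b + γ·ln L; the
  principle-of-similarity model ln A = c + 2·ln L; and the per-tree
  diagnostic correlating similarity-fit RMSE with the coefficient of
  variation of RWL.
* **Superellipse theory** — boundaries of |x/α|ⁿ + |y/β|ⁿ = 1, the
  gamma-function area coefficient MP(n) = Γ(1+1/n)²/Γ(1+2/n), and the
  EI(n) curve rising sigmoidally to 4/π ≈ 1.27 as n → ∞.
* **Synthetic populations** — a seeded site → tree → leaf generator
  (DBH-linear trait models with site random intercepts, leaves realised
  as piecewise superellipses with closed-form oracles) so every stage
  can be validated by parameter recovery without any external data.
* **Mixed-model stage** — per-trait random-intercept models
  y = β₀ + β₁·DBH + α_site + ε fitted by REML, with the intraclass
  correlation ρ = σ²_α / (σ²_α + σ²_ε), plus per-tree summary tables.

## Worked example

Measure one asymmetric obovate leaf with known ground truth:

```r
library(leafmorph)

b <- piecewise_superellipse_boundary(10, 4, CR = 0.6, n_base = 2, n_apex = 3,
                                     eps = 0.1, n_vertices = 2048,
                                     leaf_id = "demo")
m <- measure_leaf(b, dry_mass = 0.55)
m
#> <leaf_measurements 'demo': A=32.98  L=10  W=4  L_W=6  LMA=166.8 g/m^2>
shape_indices(m)
#> <shape_indices 'demo': RWL=0.4000 EI=1.0499 lnPRI=-0.1899 lnDRI=-0.3617 lnAR=+0.2007 CR=0.6000>
```

The measured area matches the closed form
`pse_area(10, 4, 0.6, 2, 3)` = 32.983, CR recovers the generating 0.6,
and ln AR equals ln(1.1/0.9) = 0.2007 — the leaf was built with its
upper half scaled by 1.1 and lower by 0.9. EI above 1 says the lamina
is fuller than the ellipse with the same L and W.

Simulate a small two-site population, measure every polygon, and run
the scaling and mixed-model stages:

```r
cfg <- synthetic_config(n_sites = 2, trees_per_site = 5,
                        leaves_per_tree_range = c(20, 25),
                        n_vertices = 256, seed = 42)
pop <- simulate_population(cfg)
df  <- measure_population(pop, resolution = 201)

fit_montgomery(df)
#> <scaling_fit montgomery: n=223  intercept=-0.2533  slope=1  MP=0.7762  r=0.9908  RMSE=0.0433>

head(per_tree_summary(df)[, c("tree_id", "n_leaves", "MP", "r", "CR_mean")], 3)
#>   tree_id n_leaves        MP         r   CR_mean
#> 1    T001       23 0.7639582 0.9785574 0.5329117
#> 2    T002       21 0.7723978 0.9911191 0.5209460
#> 3    T003       23 0.7644466 0.9816544 0.5560183

table2_fit(df, traits = c("A", "RWL", "CR"))
#>   trait  intercept     dbh_slope  p_intercept      p_slope      site_sd residual_sd          icc
#> 1     A 10.5510708  1.048675e-01 8.921573e-08 9.032080e-40 2.676928e+00  3.37694836 3.858939e-01
#> 2   RWL  0.6778782  3.793437e-04 0.000000e+00 5.739421e-02 9.266296e-03  0.08484236 1.178791e-02
#> 3    CR  0.5293371 -5.604119e-05 0.000000e+00 7.460790e-01 6.517941e-11  0.07355882 7.851477e-19
```

The pooled Montgomery parameter 0.776 sits just below π/4 ≈ 0.785
(EI equivalent `mp_to_ei(0.7762)` = 0.988), the per-tree log–log
correlations are all ≥ 0.98, and the mixed model recovers the
generative area model (true intercept 10, true DBH slope 0.1) from the
measured polygons. With only two sites the variance components are
weakly identified — the package warns about this — and the CR site
variance collapses to the boundary (σ_α ≈ 0, ICC ≈ 0).

A command-line wrapper with `simulate`, `measure` and `analyze`
subcommands lives at `inst/scripts/leafmorph-cli.R`; the methods
vignette (`vignettes/leaf-shape-methods.Rmd`) documents the
measurement conventions, the generator's assumptions and the design
decisions.

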