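test_that("piecewise-superellipse boundaries match their analytic oracles", {
  # reduction: CR = 0.5, n = 2, eps = 0 is an exact ellipse
  b <- piecewise_superellipse_boundary(10, 4, CR = 0.5, n_base = 2,
                                       n_apex = 2, n_vertices = 2048)
  expect_equal(polygon_area(b), pi / 4 * 40, tolerance = 1e-5)
  x <- b$vertices[, 1]; y <- b$vertices[, 2]
  expect_lt(max(abs(((x - 5) / 5)^2 + (y / 2)^2 - 1)), 1e-10)

  cases <- expand.grid(CR = c(0.4, 0.6), n_base = c(2, 1.6),
                       n_apex = c(3, 2.2), eps = c(0, 0.1))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    bb <- piecewise_superellipse_boundary(9, 3.6, cs$CR, cs$n_base,
                                          cs$n_apex, cs$eps,
                                          n_vertices = 4096)
    m <- measure_leaf(bb)
    expect_equal(m$A, pse_area(9, 3.6, cs$CR, cs$n_base, cs$n_apex),
                 tolerance = 1e-4)
    expect_equal(m$L_W / m$L, cs$CR, tolerance = 1e-3)
    expect_equal(m$W, 3.6, tolerance = 1e-6)
    if (cs$eps > 0)
      expect_equal(log(m$A_left / m$A_right),
                   log((1 + cs$eps) / (1 - cs$eps)), tolerance = 1e-4)
    # width profile against the closed form
    for (f in c(1 / 8, 1 / 4, 3 / 4, 7 / 8))
      expect_equal(width_at(bb, f),
                   pse_width(f * 9, 9, 3.6, cs$CR, cs$n_base, cs$n_apex),
                   tolerance = 1e-4)
  }

  expect_error(piecewise_superellipse_boundary(10, 4, CR = 1.2),
               "CR")
  expect_error(piecewise_superellipse_boundary(10, 4, CR = 0.5, eps = 1),
               "eps")
  expect_error(piecewise_superellipse_boundary(-1, 4, CR = 0.5), "> 0")
})

test_that("population simulation is reproducible and honours the config", {
  cfg <- synthetic_config(n_sites = 2, trees_per_site = 4,
                          leaves_per_tree_range = c(8, 10),
                          n_vertices = 128, seed = 99)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$latent, p2$latent)
  expect_identical(p1$trees[[3]]$leaves[[2]]$vertices,
                   p2$trees[[3]]$leaves[[2]]$vertices)

  expect_identical(length(p1$trees), 8L)
  counts <- vapply(p1$trees, function(t) length(t$leaves), integer(1))
  expect_true(all(counts >= 8 & counts <= 10))
  dbh <- vapply(p1$trees, `[[`, numeric(1), "DBH")
  expect_true(all(dbh >= 8.6 & dbh <= 96.4))
  # every boundary satisfies the polygon invariants
  for (b in p1$trees[[1]]$leaves) {
    expect_s3_class(b, "leaf_boundary")
    expect_true(is_simple_polygon(b))
  }
})

test_that("degenerate config (all sd = 0, slope = 0) gives identical leaves", {
  tm <- default_trait_models()
  for (tr in names(tm)) {
    tm[[tr]]$dbh_slope <- 0
    tm[[tr]]$site_sd <- 0
    tm[[tr]]$residual_sd <- 0
  }
  cfg <- synthetic_config(n_sites = 2, trees_per_site = 3,
                          leaves_per_tree_range = c(5, 5),
                          trait_models = tm, n_exponent_range = c(2, 2),
                          n_vertices = 128, seed = 3)
  pop <- simulate_population(cfg)
  lat <- pop$latent
  for (col in c("area", "LMA", "RWL", "CR", "lnAR", "L", "W"))
    expect_lt(diff(range(lat[[col]])), 1e-12)
})

test_that("a positive area-DBH slope shows up as cross-tree correlation", {
  tm <- default_trait_models()
  tm$area <- list(intercept = 7, dbh_slope = 0.1, site_sd = 0.1,
                  residual_sd = 0.5)
  cfg <- synthetic_config(n_sites = 2, trees_per_site = 15,
                          leaves_per_tree_range = c(10, 12),
                          trait_models = tm, seed = 17)
  pop <- simulate_population(cfg, boundaries = FALSE)
  agg <- aggregate(area ~ tree_id + DBH, data = pop$latent, FUN = mean)
  expect_gt(cor(agg$DBH, agg$area), 0.9)
})

test_that("out-of-domain latent draws are resampled and counted", {
  tm <- default_trait_models()
  tm$CR <- list(intercept = 0.9, dbh_slope = 0, site_sd = 0,
                residual_sd = 0.15)   # frequently outside (0, 1)
  cfg <- synthetic_config(n_sites = 1, trees_per_site = 4,
                          leaves_per_tree_range = c(30, 30),
                          trait_models = tm, seed = 8)
  expect_warning(pop <- simulate_population(cfg, boundaries = FALSE),
                 "resampled")
  expect_gt(pop$truth$n_resampled, 0)
  expect_true(all(pop$latent$CR > 0 & pop$latent$CR < 1))
})

test_that("obovate configurations yield measured mean CR above 0.5", {
  tm <- default_trait_models()
  tm$CR <- list(intercept = 0.57, dbh_slope = 0, site_sd = 0,
                residual_sd = 0.03)
  cfg <- synthetic_config(n_sites = 1, trees_per_site = 4,
                          leaves_per_tree_range = c(10, 10),
                          trait_models = tm, n_vertices = 512, seed = 31)
  df <- measure_population(simulate_population(cfg))
  expect_gt(mean(df$CR), 0.5)
  # measured CR tracks the latent CR leaf by leaf
  pop <- simulate_population(cfg)
  expect_equal(df$CR, pop$latent$CR, tolerance = 0.01)
})

test_that("measured traits recover the generative DBH slopes end to end", {
  # geometry -> indices -> mixed model on a scaled-down population
  tm <- default_trait_models()
  tm$area <- list(intercept = 7, dbh_slope = 0.1, site_sd = 1, residual_sd = 2)
  tm$RWL <- list(intercept = 0.6, dbh_slope = 5e-4, site_sd = 0.01,
                 residual_sd = 0.04)
  cfg <- synthetic_config(n_sites = 4, trees_per_site = 8,
                          leaves_per_tree_range = c(28, 32),
                          trait_models = tm, n_vertices = 256, seed = 12)
  df <- measure_population(simulate_population(cfg), resolution = 151)
  for (tr in list(c("A", "area"), c("RWL", "RWL"), c("CR", "CR"),
                  c("lnAR", "lnAR"), c("LMA", "LMA"))) {
    fit <- suppressWarnings(fit_mixed(df[[tr[1]]], df$DBH, df$site,
                                      trait = tr[1]))
    truth <- tm[[tr[2]]]$dbh_slope
    expect_lt(abs(fit$beta1 - truth), 2 * fit$se_beta1 + 1e-12)
  }
})

test_that("population files round-trip through the CSV/JSON interfaces", {
  cfg <- synthetic_config(n_sites = 2, trees_per_site = 2,
                          leaves_per_tree_range = c(3, 3),
                          n_vertices = 64, seed = 5)
  pop <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  expect_true(all(file.exists(file.path(dir, c("boundaries.csv", "trees.csv",
                                               "truth.json")))))
  got <- read_boundary_csv(file.path(dir, "boundaries.csv"))
  expect_identical(length(got), 4L * 3L)
  b0 <- pop$trees[[1]]$leaves[[1]]
  expect_equal(got[[b0$leaf_id]]$vertices, b0$vertices, tolerance = 1e-12)
  meta <- utils::read.csv(file.path(dir, "trees.csv"))
  expect_identical(nrow(meta), 4L)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$config$seed, 5)
  expect_identical(length(truth$latent$leaf_id), nrow(pop$latent))
})
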