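test_that("icc follows its closed form, limits and scale invariance", {
  expect_equal(icc(0, 1), 0)
  expect_equal(icc(1, 1), 0.5)
  expect_equal(icc(3, 4), 9 / 25)
  expect_gt(icc(100, 1), 0.999)        # dominant between-group variation
  expect_equal(icc(2.5 * 3, 2.5 * 4), icc(3, 4), tolerance = 1e-15)
  expect_error(icc(0, 0), "undefined")
  expect_error(icc(-1, 1), ">= 0")
})

simulate_sites <- function(seed, n_sites, trees_per_site, leaves_per_tree,
                           beta0 = 10, beta1 = 0.1, sigma_alpha = 2,
                           sigma_eps = 4) {
  set.seed(seed)
  site <- rep(paste0("S", seq_len(n_sites)),
              each = trees_per_site * leaves_per_tree)
  alpha <- rnorm(n_sites, 0, sigma_alpha)[as.integer(factor(site))]
  dbh_tree <- runif(n_sites * trees_per_site, 8.6, 96.4)
  dbh <- rep(dbh_tree, each = leaves_per_tree)
  y <- beta0 + beta1 * dbh + alpha + rnorm(length(dbh), 0, sigma_eps)
  data.frame(y = y, dbh = dbh, site = site)
}

test_that("fit_mixed agrees with an independent profile-REML oracle", {
  d <- simulate_sites(2, n_sites = 6, trees_per_site = 5,
                      leaves_per_tree = 4)
  fit <- fit_mixed(d$y, d$dbh, d$site)
  ora <- reml_oracle(d$y, d$dbh, d$site)
  expect_equal(fit$beta0, ora$beta[1], tolerance = 1e-5)
  expect_equal(fit$beta1, ora$beta[2], tolerance = 1e-5)
  expect_equal(fit$sigma_alpha, ora$sigma_alpha, tolerance = 1e-4)
  expect_equal(fit$sigma_eps, ora$sigma_eps, tolerance = 1e-5)
  expect_equal(fit$rho, icc(ora$sigma_alpha, ora$sigma_eps),
               tolerance = 1e-4)
})

test_that("fit_mixed handles boundary and extreme variance structures", {
  # no between-site variation: boundary estimate rho ~ 0, slope recovered
  d0 <- simulate_sites(4, n_sites = 8, trees_per_site = 6,
                       leaves_per_tree = 6, sigma_alpha = 0)
  f0 <- fit_mixed(d0$y, d0$dbh, d0$site)
  expect_lt(f0$rho, 0.05)
  expect_lt(abs(f0$beta1 - 0.1), 2 * f0$se_beta1)

  # huge between-site shifts dominate: rho > 0.9
  d1 <- simulate_sites(6, n_sites = 6, trees_per_site = 6,
                       leaves_per_tree = 6, sigma_alpha = 50, sigma_eps = 2)
  f1 <- fit_mixed(d1$y, d1$dbh, d1$site)
  expect_gt(f1$rho, 0.9)

  # two sites (the field design): fits, but warns about identifiability
  d2 <- simulate_sites(8, n_sites = 2, trees_per_site = 10,
                       leaves_per_tree = 8)
  expect_warning(f2 <- fit_mixed(d2$y, d2$dbh, d2$site), "weakly identified")
  expect_equal(f2$n_groups, 2L)
})

test_that("fit_mixed reduces to ordinary least squares with one group", {
  d <- simulate_sites(3, n_sites = 1, trees_per_site = 12,
                      leaves_per_tree = 5, sigma_alpha = 0)
  expect_warning(f <- fit_mixed(d$y, d$dbh, d$site), "single grouping level")
  ols <- lm(y ~ dbh, data = d)
  expect_equal(f$beta0, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(f$beta1, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f$sigma_alpha, 0)
  expect_equal(f$rho, 0)
})

test_that("average REML estimates recover the generative parameters", {
  reps <- 20
  b1 <- numeric(reps)
  sa <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- simulate_sites(100 + i, n_sites = 10, trees_per_site = 12,
                        leaves_per_tree = 8, sigma_alpha = 2, sigma_eps = 4)
    f <- fit_mixed(d$y, d$dbh, d$site)
    b1[i] <- f$beta1
    sa[i] <- f$sigma_alpha
  }
  expect_lt(abs(mean(b1) / 0.1 - 1), 0.05)
  expect_lt(abs(mean(sa) / 2 - 1), 0.15)
})

test_that("table2_fit assembles one mixed-model row per trait", {
  cfg <- synthetic_config(n_sites = 4, trees_per_site = 6,
                          leaves_per_tree_range = c(15, 18), seed = 44)
  pop <- simulate_population(cfg, boundaries = FALSE)
  df <- pop$latent
  df$A <- df$area
  tab <- table2_fit(df, traits = c("A", "LMA", "RWL", "CR", "lnAR"))
  expect_identical(nrow(tab), 5L)
  expect_named(tab, c("trait", "intercept", "dbh_slope", "p_intercept",
                      "p_slope", "site_sd", "residual_sd", "icc"))
  expect_true(all(tab$icc >= 0 & tab$icc <= 1))
  fits <- attr(tab, "fits")
  expect_identical(length(fits), 5L)
  expect_s3_class(fits[[1]], "mixed_model_result")
})

test_that("per_tree_summary matches hand computation and flags tiny trees", {
  df <- data.frame(
    tree_id = rep(c("t1", "t2"), each = 3),
    A = c(10, 12, 14, 8, 9, 10), L = c(5, 5.5, 6, 4, 4.2, 4.4),
    W = c(2.5, 2.7, 2.9, 2, 2.1, 2.2), RWL = c(0.5, 0.49, 0.48, 0.5, 0.5, 0.5))
  s <- per_tree_summary(df, traits = c("A", "RWL"))
  expect_identical(nrow(s), 2L)
  expect_equal(s$A_mean, c(12, 9))
  expect_equal(s$A_median, c(12, 9))
  expect_equal(s$A_cv, c(sd(c(10, 12, 14)) / 12, sd(c(8, 9, 10)) / 9))
  a1 <- mean(log(df$A[1:3]) - log(df$L[1:3] * df$W[1:3]))
  expect_equal(s$MP[1], exp(a1), tolerance = 1e-12)

  # identical leaves in a tree: zero CV, Montgomery r undefined
  same <- data.frame(tree_id = "t", A = rep(10, 4), L = rep(5, 4),
                     W = rep(2.5, 4))
  s2 <- suppressWarnings(per_tree_summary(same, traits = c("A", "L")))
  expect_equal(s2$A_cv, 0)
  expect_true(is.na(s2$r))

  # a 2-leaf tree is excluded from the fit with a warning
  tiny <- rbind(df, data.frame(tree_id = "t3", A = c(5, 6), L = c(3, 3.2),
                               W = c(1.5, 1.6), RWL = c(0.5, 0.5)))
  expect_warning(s3 <- per_tree_summary(tiny, traits = "A"), "t3")
  expect_true(is.na(s3$MP[s3$tree_id == "t3"]))
})

test_that("per-tree Montgomery correlations are high on a low-noise population", {
  tm <- default_trait_models()
  tm$area$residual_sd <- 3   # ample within-tree size spread
  cfg <- synthetic_config(n_sites = 2, trees_per_site = 5,
                          leaves_per_tree_range = c(12, 14),
                          trait_models = tm,
                          n_exponent_range = c(1.9, 2.15), # mild shape noise
                          n_vertices = 256, seed = 23)
  df <- measure_population(simulate_population(cfg), resolution = 151)
  s <- per_tree_summary(df)
  expect_identical(nrow(s), 10L)
  expect_true(all(s$r > 0.98))
  expect_true(all(s$MP > 0.5 & s$MP < 1))
})
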