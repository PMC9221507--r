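#' Piecewise-superellipse lamina boundary
#'
#' A concrete elliptical-to-obovate lamina model with a controllable
#' maximum-width position and bilateral asymmetry.  The outline is built
#' from two half-superellipses sharing the full width `W` at the axial
#' station `x = CR * L`: a basal piece with exponent `n_base` on
#' `[0, CR L]` and an apical piece with exponent `n_apex` on `[CR L, L]`.
#' Bilateral asymmetry is introduced by scaling the upper half-width by
#' `1 + eps` and the lower by `1 - eps`, which leaves the total width
#' profile unchanged and makes the left/right area ratio exactly
#' `(1 + eps) / (1 - eps)`.
#'
#' Closed-form oracles for the generated shape are exposed alongside:
#' [pse_area()] and [pse_width()].  With `CR = 0.5`,
#' `n_base = n_apex = 2` and `eps = 0` the shape reduces to an exact
#' ellipse.
#'
#' @param L leaf length, > 0.
#' @param W maximum total width, > 0.
#' @param CR centroid ratio (fractional station of maximum width), in
#'   (0, 1).
#' @param n_base,n_apex superellipse exponents of the basal and apical
#'   pieces, > 0.
#' @param eps bilateral asymmetry, `|eps| < 1`.
#' @param n_vertices total number of boundary vertices, >= 64.
#' @param leaf_id identifier stored on the boundary.
#' @return a [leaf_boundary] in the canonical frame (base at the origin,
#'   apex at `(L, 0)`).
#' @export
#' @examples
#' b <- piecewise_superellipse_boundary(10, 4, CR = 0.6, n_base = 2,
#'                                      n_apex = 3, eps = 0.1)
#' measure_leaf(b)$A      # matches pse_area(10, 4, 0.6, 2, 3)
piecewise_superellipse_boundary <- function(L, W, CR, n_base = 2, n_apex = 2,
                                            eps = 0, n_vertices = 1024,
                                            leaf_id = "pse") {
  if (L <= 0 || W <= 0 || n_base <= 0 || n_apex <= 0)
    stop("invalid geometry: L, W and the exponents must be > 0", call. = FALSE)
  if (CR <= 0 || CR >= 1)
    stop("invalid geometry: CR must lie in (0, 1)", call. = FALSE)
  if (abs(eps) >= 1)
    stop("invalid geometry: |eps| must be < 1", call. = FALSE)
  if (n_vertices < 64) stop("'n_vertices' must be >= 64", call. = FALSE)

  half <- floor(n_vertices / 2)
  m_b <- max(8L, round(half * CR))
  m_a <- max(8L, half - m_b)

  # upper boundary, base -> junction -> apex
  qcurve <- function(a, n, m, from, to) {
    t <- seq(from, to, length.out = m)
    ct <- cos(t); st <- sin(t)
    ct[abs(ct) < 1e-12] <- 0
    st[abs(st) < 1e-12] <- 0
    list(x = sign(ct) * abs(ct)^(2 / n) * a,
         y = abs(st)^(2 / n))
  }
  bas <- qcurve(CR * L, n_base, m_b + 1L, pi, pi / 2)
  api <- qcurve((1 - CR) * L, n_apex, m_a + 1L, pi / 2, 0)
  ux <- c(CR * L + bas$x, CR * L + api$x[-1])
  uy <- c(bas$y, api$y[-1]) * (W / 2)
  k <- length(ux)                       # apex is vertex k
  # lower boundary, apex -> base (shared endpoints dropped)
  lx <- rev(ux[-c(1, k)])
  ly <- -rev(uy[-c(1, k)])
  vx <- c(ux, lx)
  vy <- c(uy * (1 + eps), ly * (1 - eps))
  leaf_boundary(cbind(vx, vy), base_index = 1L, apex_index = k,
                leaf_id = leaf_id, check_simple = FALSE)
}

#' Closed-form area of the piecewise-superellipse lamina
#'
#' `W * L * (MP(n_base) * CR + MP(n_apex) * (1 - CR))`, with `MP` the
#' superellipse area coefficient [se_area_coefficient()].  Independent of
#' the asymmetry `eps` (the upper and lower scalings average out).
#'
#' @inheritParams piecewise_superellipse_boundary
#' @return the lamina area.
#' @export
pse_area <- function(L, W, CR, n_base = 2, n_apex = 2) {
  W * L * (se_area_coefficient(n_base) * CR +
             se_area_coefficient(n_apex) * (1 - CR))
}

#' Closed-form width profile of the piecewise-superellipse lamina
#'
#' Total width at axial position `x` from the base:
#' `W * (1 - |x/(CR L) - 1|^n_base)^(1/n_base)` on the basal piece and the
#' apical analogue beyond `CR * L`.  Independent of `eps`.
#'
#' @inheritParams piecewise_superellipse_boundary
#' @param x axial position(s) in `[0, L]`.
#' @return numeric vector of widths.
#' @export
pse_width <- function(x, L, W, CR, n_base = 2, n_apex = 2) {
  if (any(x < 0) || any(x > L)) stop("'x' must lie in [0, L]", call. = FALSE)
  u <- ifelse(x <= CR * L,
              abs(x / (CR * L) - 1),
              (x - CR * L) / ((1 - CR) * L))
  n <- ifelse(x <= CR * L, n_base, n_apex)
  W * (pmax(1 - u^n, 0))^(1 / n)
}

#' Configuration for the synthetic tree-population generator
#'
#' Defines the generative study design: `n_sites` sites of
#' `trees_per_site` trees, each tree carrying a uniform DBH (diameter at
#' breast height, cm) and 100-110 leaves, with per-leaf latent traits
#' following DBH-linear models with a site-level random intercept and a
#' leaf-level residual:
#' `trait = intercept + dbh_slope * DBH + alpha_site + eps_leaf`,
#' `alpha_site ~ N(0, site_sd^2)`, `eps_leaf ~ N(0, residual_sd^2)`.
#'
#' Trait models are supplied for the five free latent traits — `area`
#' (cm^2), `LMA` (g m^-2), `RWL`, `CR` and `lnAR` — from which each leaf's
#' boundary is realised: `eps` from `lnAR`, the length from
#' `L = sqrt(area / (MP_eff * RWL))` where `MP_eff` is the shape family's
#' area coefficient, `W = RWL * L`, and dry mass from `LMA * area`.  The
#' remaining indices (EI, lnPRI, lnDRI) emerge from the realised shape.
#' Default coefficients are order-of-magnitude choices on the scales of
#' the study system, not fitted values.
#'
#' @param n_sites number of sites (random-intercept levels); default 2.
#' @param trees_per_site trees per site; default 30.
#' @param leaves_per_tree_range integer range of leaves per tree; default
#'   `c(100, 110)`.
#' @param dbh_range_cm DBH range (cm); default `c(8.6, 96.4)`.
#' @param trait_models named list of lists, each with elements
#'   `intercept, dbh_slope, site_sd, residual_sd`, for traits
#'   `area, LMA, RWL, CR, lnAR`.
#' @param shape_family `"piecewise_superellipse"` or `"superellipse"`
#'   (the latter forces CR = 0.5 geometry with a single exponent).
#' @param n_exponent_range range of the superellipse exponent(s), drawn
#'   uniformly per leaf; default `c(1.5, 2.5)`, bracketing the ellipse and
#'   keeping the shape family's area coefficient in the 0.7-0.8 band
#'   typical of elliptical-to-obovate laminas.
#' @param boundary_noise_sd radial vertex jitter SD as a fraction of the
#'   local radius; default 0 so analytic oracles stay exact.
#' @param n_vertices vertices per generated boundary; default 512.
#' @param seed integer seed making the population fully reproducible.
#' @return an object of class `synthetic_config` (a named list).
#' @seealso [simulate_population()]
#' @export
synthetic_config <- function(n_sites = 2, trees_per_site = 30,
                             leaves_per_tree_range = c(100L, 110L),
                             dbh_range_cm = c(8.6, 96.4),
                             trait_models = default_trait_models(),
                             shape_family = c("piecewise_superellipse",
                                              "superellipse"),
                             n_exponent_range = c(1.5, 2.5),
                             boundary_noise_sd = 0,
                             n_vertices = 512, seed = 1L) {
  shape_family <- match.arg(shape_family)
  stopifnot(n_sites >= 1, trees_per_site >= 1,
            length(leaves_per_tree_range) == 2,
            leaves_per_tree_range[1] >= 1, leaves_per_tree_range[2] <= 1e4,
            diff(leaves_per_tree_range) >= 0,
            length(dbh_range_cm) == 2, dbh_range_cm[1] > 0,
            diff(dbh_range_cm) >= 0,
            length(n_exponent_range) == 2, n_exponent_range[1] > 0,
            boundary_noise_sd >= 0, n_vertices >= 64)
  need <- c("area", "LMA", "RWL", "CR", "lnAR")
  if (!all(need %in% names(trait_models)))
    stop("'trait_models' must define ", paste(need, collapse = ", "),
         call. = FALSE)
  for (tm in trait_models)
    if (tm$site_sd < 0 || tm$residual_sd < 0)
      stop("trait model SDs must be >= 0", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 trees_per_site = as.integer(trees_per_site),
                 leaves_per_tree_range = as.integer(leaves_per_tree_range),
                 dbh_range_cm = dbh_range_cm,
                 trait_models = trait_models,
                 shape_family = shape_family,
                 n_exponent_range = n_exponent_range,
                 boundary_noise_sd = boundary_noise_sd,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default trait models of the generator
#'
#' Round-number DBH-linear models on the study-system scales: lamina area
#' of order 10 cm^2 growing with DBH, LMA of order 200 g m^-2 declining
#' with DBH, RWL near 0.68, CR slightly above 0.5 (weakly obovate), lnAR
#' centred on 0 (bilateral symmetry on average).
#'
#' @return named list of trait models (see [synthetic_config()]).
#' @export
default_trait_models <- function() {
  list(
    area = list(intercept = 10,   dbh_slope = 0.1,     site_sd = 2,    residual_sd = 3),
    LMA  = list(intercept = 190,  dbh_slope = -0.15,   site_sd = 15,   residual_sd = 30),
    RWL  = list(intercept = 0.68, dbh_slope = 3e-4,    site_sd = 0.04, residual_sd = 0.09),
    CR   = list(intercept = 0.52, dbh_slope = 5e-5,    site_sd = 0.005, residual_sd = 0.07),
    lnAR = list(intercept = 0,    dbh_slope = 2e-4,    site_sd = 0.02, residual_sd = 0.16)
  )
}

#' Simulate a site-tree-leaf population with known ground truth
#'
#' Draws the hierarchy defined by a [synthetic_config()]: one DBH per tree
#' (uniform in range), one site intercept per site per trait, and per-leaf
#' latent traits; leaves are then realised as piecewise-superellipse
#' boundaries with dry mass set from the latent LMA and realised area.
#' Leaves whose latent draw is outside the physical domain (CR or RWL
#' outside bounds, non-positive area or LMA, |eps| >= 1) have their
#' residuals redrawn; the number of redraws is counted and reported with a
#' warning.
#'
#' The returned `truth` element holds everything needed for parameter
#' recovery: the realised site intercepts, the per-leaf latent trait
#' table, and the config.  Everything is reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param boundaries realise boundary polygons?  With `FALSE`, only the
#'   latent trait table is generated (fast path for trait-level studies
#'   such as mixed-model recovery).
#' @return an object of class `tree_population`: a list with elements
#'   `trees` (list of `tree_id, site, DBH, leaves` — each leaf a
#'   [leaf_boundary] with a `dry_mass` attribute), `latent` (data frame of
#'   per-leaf latent traits with `leaf_id, tree_id, site, DBH`), and
#'   `truth` (site effects, config, resample count).
#' @export
simulate_population <- function(config, boundaries = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tm <- config$trait_models
  traits <- names(tm)
  n_sites <- config$n_sites
  sites <- paste0("S", seq_len(n_sites))

  site_eff <- sapply(traits, function(tr)
    stats::rnorm(n_sites, 0, tm[[tr]]$site_sd))
  site_eff <- matrix(site_eff, nrow = n_sites,
                     dimnames = list(sites, traits))

  n_trees <- n_sites * config$trees_per_site
  tree_site <- rep(sites, each = config$trees_per_site)
  tree_id <- sprintf("T%03d", seq_len(n_trees))
  dbh <- stats::runif(n_trees, config$dbh_range_cm[1], config$dbh_range_cm[2])
  leaf_counts <- seq(config$leaves_per_tree_range[1],
                     config$leaves_per_tree_range[2])
  n_leaves <- leaf_counts[sample.int(length(leaf_counts), n_trees,
                                     replace = TRUE)]

  resampled <- 0L
  latent_rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    k <- n_leaves[i]
    draw <- function() {
      d <- lapply(traits, function(tr) {
        m <- tm[[tr]]
        m$intercept + m$dbh_slope * dbh[i] + site_eff[tree_site[i], tr] +
          stats::rnorm(k, 0, m$residual_sd)
      })
      names(d) <- traits
      as.data.frame(d)
    }
    d <- draw()
    bad <- invalid_latent(d)
    tries <- 0L
    while (any(bad) && tries < 100L) {
      repl <- draw()
      d[bad, ] <- repl[bad, , drop = FALSE]
      resampled <- resampled + sum(bad)
      bad <- invalid_latent(d)
      tries <- tries + 1L
    }
    if (any(bad))
      stop("could not draw physically valid traits for tree ", tree_id[i],
           "; check the trait models", call. = FALSE)
    d$n_base <- stats::runif(k, config$n_exponent_range[1],
                             config$n_exponent_range[2])
    d$n_apex <- stats::runif(k, config$n_exponent_range[1],
                             config$n_exponent_range[2])
    if (config$shape_family == "superellipse") {
      d$CR <- 0.5
      d$n_apex <- d$n_base
    }
    d$eps <- (exp(d$lnAR) - 1) / (exp(d$lnAR) + 1)
    mp_eff <- se_area_coefficient(d$n_base) * d$CR +
      se_area_coefficient(d$n_apex) * (1 - d$CR)
    d$L <- sqrt(d$area / (mp_eff * d$RWL))
    d$W <- d$RWL * d$L
    d$dry_mass <- d$LMA * d$area * 1e-4
    d <- cbind(data.frame(leaf_id = sprintf("%s_L%03d", tree_id[i], seq_len(k)),
                          tree_id = tree_id[i], site = tree_site[i],
                          DBH = dbh[i]), d)
    latent_rows[[i]] <- d
  }
  latent <- do.call(rbind, latent_rows)
  rownames(latent) <- NULL
  if (resampled > 0)
    warning(resampled, " latent trait draw(s) outside the physical domain ",
            "were resampled", call. = FALSE)

  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    d <- latent_rows[[i]]
    leaves <- NULL
    if (boundaries) {
      leaves <- lapply(seq_len(nrow(d)), function(j) {
        b <- piecewise_superellipse_boundary(
          d$L[j], d$W[j], d$CR[j], d$n_base[j], d$n_apex[j], d$eps[j],
          n_vertices = config$n_vertices, leaf_id = d$leaf_id[j])
        if (config$boundary_noise_sd > 0) b <- jitter_boundary(b, config$boundary_noise_sd)
        attr(b, "dry_mass") <- d$dry_mass[j]
        b
      })
    }
    trees[[i]] <- list(tree_id = tree_id[i], site = tree_site[i],
                       DBH = dbh[i], leaves = leaves)
  }
  structure(list(trees = trees, latent = latent,
                 truth = list(site_effects = site_eff, config = config,
                              n_resampled = resampled)),
            class = "tree_population")
}

invalid_latent <- function(d) {
  d$CR <= 0.02 | d$CR >= 0.98 | d$RWL <= 0.05 | d$area <= 0 |
    d$LMA <= 0 | abs((exp(d$lnAR) - 1) / (exp(d$lnAR) + 1)) >= 0.9
}

# radial Gaussian jitter about the vertex centroid, landmarks kept fixed
jitter_boundary <- function(b, sd_frac) {
  v <- b$vertices
  ctr <- colMeans(v)
  dx <- v[, 1] - ctr[1]
  dy <- v[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  scale <- 1 + stats::rnorm(nrow(v), 0, sd_frac)
  keep <- c(b$base_index, b$apex_index)
  scale[keep] <- 1
  v2 <- cbind(ctr[1] + dx * scale, ctr[2] + dy * scale)
  leaf_boundary(v2, b$base_index, b$apex_index, b$leaf_id,
                check_simple = FALSE)
}

#' @export
print.tree_population <- function(x, ...) {
  n_leaves <- sum(vapply(x$trees, function(t)
    nrow(x$latent[x$latent$tree_id == t$tree_id, ]), numeric(1)))
  cat(sprintf("<tree_population: %d sites, %d trees, %d leaves%s>\n",
              x$truth$config$n_sites, length(x$trees), nrow(x$latent),
              if (is.null(x$trees[[1]]$leaves)) " (traits only)" else ""))
  invisible(x)
}

#' Measure every leaf of a simulated population
#'
#' Runs [measure_leaf()] and [shape_indices()] over all boundaries of a
#' [simulate_population()] result and returns the joined per-leaf table
#' (measurements, indices, tree metadata), the input for the scaling and
#' mixed-model stages.
#'
#' @param population a `tree_population` with boundaries.
#' @param resolution grid resolution for [max_width()].
#' @return data frame with columns `leaf_id, tree_id, site, DBH`, the
#'   measurement columns of [measurements_table()] and the index columns
#'   of [indices_table()].
#' @export
measure_population <- function(population, resolution = 201) {
  stopifnot(inherits(population, "tree_population"))
  if (is.null(population$trees[[1]]$leaves))
    stop("population was simulated without boundaries", call. = FALSE)
  rows <- lapply(population$trees, function(tr) {
    ms <- lapply(tr$leaves, function(b)
      measure_leaf(b, dry_mass = attr(b, "dry_mass"),
                   resolution = resolution))
    mt <- measurements_table(ms)
    it <- indices_table(lapply(ms, shape_indices))
    cbind(data.frame(tree_id = tr$tree_id, site = tr$site, DBH = tr$DBH),
          mt, it[, setdiff(names(it), "leaf_id"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated population to disk
#'
#' Writes the boundary CSV (dialect of [read_boundary_csv()]), the tree
#' metadata CSV (`tree_id, site, DBH_cm`), and a ground-truth JSON (site
#' effects, config, per-leaf latent traits) for recovery tests.
#'
#' @param population a `tree_population`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "tree_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(population$trees[[1]]$leaves)) {
    all_leaves <- unlist(lapply(population$trees, `[[`, "leaves"),
                         recursive = FALSE)
    write_boundary_csv(all_leaves, file.path(dir, "boundaries.csv"))
  }
  meta <- do.call(rbind, lapply(population$trees, function(t)
    data.frame(tree_id = t$tree_id, site = t$site, DBH_cm = t$DBH)))
  utils::write.csv(meta, file.path(dir, "trees.csv"), row.names = FALSE)
  truth <- list(site_effects = as.data.frame(population$truth$site_effects),
                config = unclass(population$truth$config),
                n_resampled = population$truth$n_resampled,
                latent = population$latent)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
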