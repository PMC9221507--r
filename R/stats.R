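#' Random-intercept mixed model of a leaf trait on tree size
#'
#' Fits `y = beta0 + beta1 * DBH + alpha_site + eps` by restricted maximum
#' likelihood (REML, via [lme4::lmer()]), with tree size (DBH, cm) as the
#' fixed effect and site as the random-intercept grouping factor, and
#' derives the intraclass correlation coefficient
#' `rho = sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)`.  Fixed-effect
#' p-values are Wald (normal approximation on the t statistic).
#'
#' A boundary estimate `sigma_alpha = 0` is allowed and flagged in the
#' result.  With a single site level the model degenerates to ordinary
#' least squares (`sigma_alpha = 0`, `rho = 0`), with a warning; with only
#' two or three levels the variance components are weakly identified and a
#' small-group-number warning is raised.
#'
#' @param y per-leaf trait values.
#' @param dbh per-leaf DBH of the carrying tree (cm), same length as `y`.
#' @param site per-leaf site labels, same length as `y`.
#' @param trait trait name carried into the result.
#' @return an object of class `mixed_model_result`: a list with elements
#'   `trait, beta0, beta1, se_beta0, se_beta1, p_beta0, p_beta1,
#'   sigma_alpha, sigma_eps, rho, boundary_fit, n_obs, n_groups,
#'   converged`.
#' @seealso [icc()], [table2_fit()]
#' @export
fit_mixed <- function(y, dbh, site, trait = "trait") {
  if (length(y) != length(dbh) || length(y) != length(site))
    stop("'y', 'dbh' and 'site' must have equal length", call. = FALSE)
  keep <- is.finite(y) & is.finite(dbh) & !is.na(site)
  y <- y[keep]; dbh <- dbh[keep]; site <- factor(site[keep])
  n <- length(y)
  if (n < 10) stop("insufficient data: need >= 10 observations", call. = FALSE)
  g <- nlevels(site)

  if (g < 2) {
    warning("single grouping level: fitting ordinary least squares, ",
            "sigma_alpha = 0", call. = FALSE)
    fit <- stats::lm(y ~ dbh)
    co <- summary(fit)$coefficients
    return(structure(list(trait = trait,
                          beta0 = co[1, 1], beta1 = co[2, 1],
                          se_beta0 = co[1, 2], se_beta1 = co[2, 2],
                          p_beta0 = wald_p(co[1, 1], co[1, 2]),
                          p_beta1 = wald_p(co[2, 1], co[2, 2]),
                          sigma_alpha = 0, sigma_eps = summary(fit)$sigma,
                          rho = 0, boundary_fit = TRUE,
                          n_obs = n, n_groups = g, converged = TRUE),
                     class = "mixed_model_result"))
  }
  if (g <= 3)
    warning("only ", g, " grouping levels: the site variance component ",
            "is weakly identified", call. = FALSE)

  dat <- data.frame(y = y, dbh = dbh, site = site)
  fit <- lme4::lmer(y ~ dbh + (1 | site), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_alpha <- vc$sdcor[vc$grp == "site"]
  sigma_eps <- vc$sdcor[vc$grp == "Residual"]
  co <- summary(fit)$coefficients
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(trait = trait,
                 beta0 = co[1, 1], beta1 = co[2, 1],
                 se_beta0 = co[1, 2], se_beta1 = co[2, 2],
                 p_beta0 = wald_p(co[1, 1], co[1, 2]),
                 p_beta1 = wald_p(co[2, 1], co[2, 2]),
                 sigma_alpha = sigma_alpha, sigma_eps = sigma_eps,
                 rho = icc(sigma_alpha, sigma_eps),
                 boundary_fit = sigma_alpha < 1e-8 * sigma_eps,
                 n_obs = n, n_groups = g,
                 converged = is.null(msgs)),
            class = "mixed_model_result")
}

wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result '%s': beta0=%.5g (p=%.3g)  beta1=%.5g (p=%.3g)\n  sigma_site=%.5g  sigma_resid=%.5g  ICC=%.4f  [n=%d, groups=%d%s]>\n",
    x$trait, x$beta0, x$p_beta0, x$beta1, x$p_beta1,
    x$sigma_alpha, x$sigma_eps, x$rho, x$n_obs, x$n_groups,
    if (x$boundary_fit) ", boundary sigma_alpha" else ""))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' `rho = sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)`: the share of
#' total variance attributable to the grouping level.  0 when there is no
#' between-group variation; approaches 1 when between-group variation
#' dominates.  Scale-invariant: `icc(k * a, k * e) = icc(a, e)`.
#'
#' @param sigma_alpha between-group (site) standard deviation, >= 0.
#' @param sigma_eps within-group (residual) standard deviation, >= 0.
#' @return rho in `[0, 1]`.
#' @export
#' @examples
#' icc(0, 1)  # 0
#' icc(1, 1)  # 0.5
icc <- function(sigma_alpha, sigma_eps) {
  if (any(sigma_alpha < 0) || any(sigma_eps < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (any(sigma_alpha == 0 & sigma_eps == 0))
    stop("undefined: both variance components are zero", call. = FALSE)
  sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)
}

#' Mixed-model table over the standard trait set
#'
#' Runs [fit_mixed()] for each trait column present in a per-leaf table
#' (as produced by [measure_population()], which must carry `DBH` and
#' `site` columns) and assembles the summary table with one row per trait:
#' `trait, intercept, dbh_slope, p_intercept, p_slope, site_sd,
#' residual_sd, icc`.
#'
#' @param df per-leaf data frame with `DBH`, `site` and trait columns.
#' @param traits character vector of trait column names; defaults to the
#'   intersection of `c("A", "LMA", "RWL", "EI", "lnPRI", "lnDRI",
#'   "lnAR", "CR")` with `names(df)`.
#' @return a data frame, one row per trait, plus the list of fitted
#'   `mixed_model_result`s as attribute `"fits"`.
#' @export
table2_fit <- function(df, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(c("A", "LMA", "RWL", "EI", "lnPRI", "lnDRI",
                          "lnAR", "CR"), names(df))
  stopifnot(all(c("DBH", "site") %in% names(df)), length(traits) > 0)
  no_data <- vapply(traits, function(tr)
    sum(is.finite(df[[tr]])) < 10, logical(1))
  if (any(no_data)) {
    warning("trait(s) without enough finite observations skipped: ",
            paste(traits[no_data], collapse = ", "), call. = FALSE)
    traits <- traits[!no_data]
    if (!length(traits)) stop("no traits left to fit", call. = FALSE)
  }
  fits <- lapply(traits, function(tr)
    fit_mixed(df[[tr]], df$DBH, df$site, trait = tr))
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(trait = f$trait, intercept = f$beta0, dbh_slope = f$beta1,
               p_intercept = f$p_beta0, p_slope = f$p_beta1,
               site_sd = f$sigma_alpha, residual_sd = f$sigma_eps,
               icc = f$rho)))
  attr(out, "fits") <- fits
  out
}

#' Per-tree summary of a measured population
#'
#' For each tree: leaf count, mean/median/CV of every trait column, and
#' the Montgomery parameter and log-scale correlation from
#' [fit_montgomery()] over the tree's leaves.  Trees with fewer than 3
#' leaves are excluded from the Montgomery fit (MP and r reported `NA`)
#' with a warning.
#'
#' @param df per-leaf data frame with a `tree_id` column, columns `A, L,
#'   W` for the Montgomery fit, and any number of trait columns.
#' @param traits trait columns to summarise; defaults to the numeric
#'   measurement/index columns present.
#' @return a data frame with one row per tree: `tree_id, n_leaves`, then
#'   `<trait>_mean`, `<trait>_median`, `<trait>_cv` per trait, then
#'   `MP, r`.
#' @export
per_tree_summary <- function(df, traits = NULL) {
  stopifnot("tree_id" %in% names(df))
  if (is.null(traits))
    traits <- intersect(c("A", "L", "W", "L_W", "LMA", "RWL", "EI",
                          "lnPRI", "lnDRI", "lnAR", "CR"), names(df))
  small <- character(0)
  rows <- lapply(split(df, df$tree_id), function(d) {
    row <- data.frame(tree_id = d$tree_id[1], n_leaves = nrow(d))
    for (tr in traits) {
      v <- d[[tr]]
      v <- v[is.finite(v)]
      row[[paste0(tr, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(tr, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
      row[[paste0(tr, "_cv")]] <- if (length(v) > 1 && mean(v) != 0)
        stats::sd(v) / abs(mean(v)) else NA_real_
    }
    if (nrow(d) >= 3 && all(c("A", "L", "W") %in% names(d))) {
      fit <- fit_montgomery(d)
      row$MP <- fit$MP
      row$r <- fit$r
    } else {
      if (nrow(d) < 3) small <<- c(small, as.character(d$tree_id[1]))
      row$MP <- NA_real_
      row$r <- NA_real_
    }
    row
  })
  if (length(small))
    warning("tree(s) with fewer than 3 leaves excluded from Montgomery ",
            "fits: ", paste(small, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
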