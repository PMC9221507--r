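#' Log-log scaling fits of leaf area
#'
#' Three fits of lamina area against linear leaf dimensions, all on the
#' natural-log scale:
#'
#' * `fit_montgomery()` — the Montgomery proportionality `A = MP * L * W`,
#'   fitted as `ln A = a + ln(LW)` with the slope fixed at 1; the
#'   Montgomery parameter is `MP = exp(a)`.  `a` is the least-squares
#'   estimate `mean(ln A - ln(LW))`.
#' * `fit_power_free()` — ordinary least squares of `ln A` on `ln L`
#'   (free slope), the empirical power law of area versus length.
#' * `fit_similarity_fixed2()` — the principle-of-similarity model
#'   `ln A = c + 2 ln L` with the slope fixed at 2.
#'
#' Residual RMSE uses `n - 1` degrees of freedom for the one-parameter
#' fixed-slope fits and `n - 2` for the free-slope fit.  The Pearson
#' correlation `r` is between `ln A` and the model's regressor (`ln(LW)`
#' or `ln L`); with zero variance it is reported as `NA` with a warning.
#' 95% intervals use the t distribution (for MP, on the intercept, then
#' exponentiated).
#'
#' @param leaves a data frame with positive columns `A`, `L` and (for the
#'   Montgomery fit) `W` — e.g. from [measurements_table()] or
#'   [measure_population()] — or a list of `leaf_measurements`.
#' @return an object of class `scaling_fit`: a list with elements `model`,
#'   `intercept`, `slope`, `MP` (Montgomery fit only), `r`, `RMSE`,
#'   `ci95_slope` or `ci95_MP`, `n_leaves`.
#' @seealso [rmse_vs_cv()], [mp_to_ei()]
#' @export
#' @examples
#' leaves <- data.frame(L = seq(5, 12, length.out = 40))
#' leaves$W <- 0.5 * leaves$L
#' leaves$A <- pi / 4 * leaves$L * leaves$W  # exact ellipses
#' fit_montgomery(leaves)$MP                 # pi/4
fit_montgomery <- function(leaves) {
  d <- scaling_data(leaves, need_W = TRUE)
  n <- nrow(d)
  if (n < 3) stop("insufficient data: Montgomery fit needs n >= 3", call. = FALSE)
  lnA <- log(d$A)
  lnLW <- log(d$L * d$W)
  res0 <- lnA - lnLW
  a <- mean(res0)
  res <- res0 - a
  RMSE <- sqrt(sum(res^2) / (n - 1))
  se_a <- stats::sd(res0) / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  r <- safe_cor(lnA, lnLW)
  structure(list(model = "montgomery", intercept = a, slope = 1,
                 MP = exp(a), r = r, RMSE = RMSE,
                 ci95_MP = exp(c(a - tq * se_a, a + tq * se_a)),
                 n_leaves = n),
            class = "scaling_fit")
}

#' @rdname fit_montgomery
#' @export
fit_power_free <- function(leaves) {
  d <- scaling_data(leaves, need_W = FALSE)
  n <- nrow(d)
  if (n < 3) stop("insufficient data: free-slope fit needs n >= 3", call. = FALSE)
  lnA <- log(d$A)
  lnL <- log(d$L)
  if (stats::sd(lnL) == 0)
    stop("singular fit: zero variance in ln L", call. = FALSE)
  fit <- stats::lm(lnA ~ lnL)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  RMSE <- sqrt(sum(res^2) / (n - 2))
  ci <- stats::confint(fit, "lnL", level = 0.95)
  structure(list(model = "power_free", intercept = unname(co[1]),
                 slope = unname(co[2]), r = safe_cor(lnA, lnL),
                 RMSE = RMSE, ci95_slope = unname(ci[1, ]),
                 n_leaves = n),
            class = "scaling_fit")
}

#' @rdname fit_montgomery
#' @export
fit_similarity_fixed2 <- function(leaves) {
  d <- scaling_data(leaves, need_W = FALSE)
  n <- nrow(d)
  if (n < 2) stop("insufficient data: similarity fit needs n >= 2", call. = FALSE)
  lnA <- log(d$A)
  lnL <- log(d$L)
  res0 <- lnA - 2 * lnL
  cc <- mean(res0)
  res <- res0 - cc
  RMSE <- sqrt(sum(res^2) / (n - 1))
  se_c <- stats::sd(res0) / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  structure(list(model = "similarity_fixed2", intercept = cc, slope = 2,
                 r = safe_cor(lnA, lnL), RMSE = RMSE,
                 ci95_intercept = c(cc - tq * se_c, cc + tq * se_c),
                 n_leaves = n),
            class = "scaling_fit")
}

scaling_data <- function(leaves, need_W) {
  if (is.list(leaves) && !is.data.frame(leaves) &&
      all(vapply(leaves, inherits, logical(1), "leaf_measurements")))
    leaves <- measurements_table(leaves)
  leaves <- as.data.frame(leaves)
  need <- c("A", "L", if (need_W) "W")
  if (!all(need %in% names(leaves)))
    stop("'leaves' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- leaves[, need, drop = FALSE]
  if (any(!is.finite(as.matrix(d))) || any(as.matrix(d) <= 0))
    stop("'A', 'L', 'W' must be finite and > 0", call. = FALSE)
  d
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined, reported as NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit %s: n=%d  intercept=%.4f  slope=%.4g%s  r=%.4f  RMSE=%.4f>\n",
              x$model, x$n_leaves, x$intercept, x$slope,
              if (!is.null(x$MP)) sprintf("  MP=%.4f", x$MP) else "",
              x$r, x$RMSE))
  invisible(x)
}

#' Serialize a scaling fit to a JSON record
#'
#' @param fit a `scaling_fit`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
scaling_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "scaling_fit"))
  rec <- list(model = fit$model, intercept = fit$intercept,
              slope = fit$slope, MP = fit$MP, r = fit$r, RMSE = fit$RMSE,
              ci95 = fit$ci95_MP %||% fit$ci95_slope %||% fit$ci95_intercept,
              n = fit$n_leaves)
  rec <- rec[!vapply(rec, is.null, logical(1))]
  js <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity-fit error versus width-to-length variability, across trees
#'
#' For each tree, fits the fixed-slope-2 similarity model and computes the
#' coefficient of variation of RWL (`sd(RWL) / mean(RWL)`) over its leaves,
#' then correlates RMSE with CV across trees.  A positive correlation means
#' the area-versus-length-squared law degrades exactly where leaf
#' proportions vary more within a tree.
#'
#' @param trees either a named list of per-tree leaf data frames (each with
#'   columns `A`, `L`, and `RWL` or `W`), or one data frame with a
#'   `tree_id` column.
#' @return a list with `per_tree` (data frame `tree_id, n, RMSE, CV_RWL`)
#'   and `r`, the cross-tree Pearson correlation of RMSE with CV (NA with a
#'   warning if either has zero variance).
#' @export
rmse_vs_cv <- function(trees) {
  if (is.data.frame(trees)) {
    if (!"tree_id" %in% names(trees))
      stop("data frame input needs a 'tree_id' column", call. = FALSE)
    trees <- split(trees, trees$tree_id)
  }
  if (length(trees) < 3)
    stop("insufficient data: need >= 3 trees", call. = FALSE)
  if (is.null(names(trees))) names(trees) <- as.character(seq_along(trees))
  per <- lapply(names(trees), function(id) {
    d <- as.data.frame(trees[[id]])
    if (nrow(d) < 3)
      stop("tree '", id, "' has fewer than 3 leaves", call. = FALSE)
    rwl <- if ("RWL" %in% names(d)) d$RWL else d$W / d$L
    data.frame(tree_id = id, n = nrow(d),
               RMSE = fit_similarity_fixed2(d)$RMSE,
               CV_RWL = stats::sd(rwl) / mean(rwl))
  })
  per <- do.call(rbind, per)
  list(per_tree = per, r = safe_cor(per$RMSE, per$CV_RWL))
}
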