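#' Six leaf-shape indices
#'
#' Computes, from one [measure_leaf()] pass:
#' \describe{
#'   \item{RWL}{ratio of maximum width to length, `W / L`.}
#'   \item{EI}{ellipticalness index, `A / ((pi/4) * L * W)`; exactly 1 for
#'     an ellipse, above 1 for shapes fuller than an ellipse (rectangle:
#'     `4/pi`), below 1 for slimmer shapes (rhombus: `2/pi`).}
#'   \item{lnPRI}{proximal ratio index, `ln(W_{1/4 L} / W_{3/4 L})` —
#'     along-axis asymmetry of the inner width stations.}
#'   \item{lnDRI}{distal ratio index, `ln(W_{1/8 L} / W_{7/8 L})` —
#'     along-axis asymmetry of the outer width stations.}
#'   \item{lnAR}{bilateral asymmetry, `ln(A_left / A_right)`; its sign
#'     depends on scan orientation, so only `|lnAR|` is orientation-free.}
#'   \item{CR}{centroid ratio `L_W / L`, the fractional position of the
#'     maximum width along the length axis; above 0.5 indicates an obovate
#'     lamina (widest towards the apex).}
#' }
#' All six are dimensionless and invariant under uniform scaling.
#'
#' @param m a `leaf_measurements` object.
#' @return an object of class `shape_indices`: a named list with elements
#'   `RWL, EI, lnPRI, lnDRI, lnAR, CR` (and `leaf_id`).
#' @seealso [measure_leaf()], [indices_table()]
#' @export
#' @examples
#' m <- measure_leaf(se_boundary(10, 4, n = 2, n_vertices = 2048))
#' shape_indices(m)  # RWL 0.4, EI ~ 1, asymmetries ~ 0, CR ~ 0.5
shape_indices <- function(m) {
  stopifnot(inherits(m, "leaf_measurements"))
  for (fld in c("A", "L", "W", "L_W"))
    if (!is.numeric(m[[fld]]) || m[[fld]] <= 0)
      stop("measurement field '", fld, "' must be positive", call. = FALSE)
  ratio <- function(num, den, index) {
    if (den == 0)
      stop("undefined index ", index, ": zero denominator", call. = FALSE)
    num / den
  }
  structure(list(
    leaf_id = m$leaf_id,
    RWL = ratio(m$W, m$L, "RWL"),
    EI = ratio(m$A, (pi / 4) * m$L * m$W, "EI"),
    lnPRI = log(ratio(m$W_f[["1/4"]], m$W_f[["3/4"]], "lnPRI")),
    lnDRI = log(ratio(m$W_f[["1/8"]], m$W_f[["7/8"]], "lnDRI")),
    lnAR = log(ratio(m$A_left, m$A_right, "lnAR")),
    CR = ratio(m$L_W, m$L, "CR")
  ), class = "shape_indices")
}

#' @export
print.shape_indices <- function(x, ...) {
  cat(sprintf(
    "<shape_indices '%s': RWL=%.4f EI=%.4f lnPRI=%+.4f lnDRI=%+.4f lnAR=%+.4f CR=%.4f>\n",
    x$leaf_id, x$RWL, x$EI, x$lnPRI, x$lnDRI, x$lnAR, x$CR))
  invisible(x)
}

#' Leaf dry mass per unit area
#'
#' LMA in g m^-2 from a dry mass in grams and a lamina area in cm^2:
#' `dry_mass / (A * 1e-4)`.  The reciprocal is the specific leaf area
#' (SLA, m^2 g^-1).
#'
#' @param dry_mass leaf dry mass (g), > 0.
#' @param A lamina area (cm^2), > 0.
#' @return LMA in g m^-2.
#' @export
#' @examples
#' lma(0.2, 10)  # 200 g m^-2
lma <- function(dry_mass, A) {
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0))
    stop("'dry_mass' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(A)) || any(A <= 0))
    stop("'A' must be finite and > 0", call. = FALSE)
  dry_mass / (A * 1e-4)
}

#' Tabulate shape indices
#'
#' Flattens one or more `shape_indices` into a data frame with columns
#' `leaf_id, RWL, EI, lnPRI, lnDRI, lnAR, CR`, ready to join onto the
#' measurements table.
#'
#' @param indices a `shape_indices` or list of them.
#' @return a data frame, one row per leaf.
#' @export
indices_table <- function(indices) {
  if (inherits(indices, "shape_indices")) indices <- list(indices)
  do.call(rbind, lapply(indices, function(s)
    data.frame(leaf_id = s$leaf_id, RWL = s$RWL, EI = s$EI,
               lnPRI = s$lnPRI, lnDRI = s$lnDRI, lnAR = s$lnAR, CR = s$CR)))
}
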