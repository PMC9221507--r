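#' Superellipse area coefficient
#'
#' Area coefficient (Montgomery parameter) of a superellipse
#' \eqn{|x/\alpha|^n + |y/\beta|^n = 1}: the area equals
#' \eqn{\mathrm{MP}(n) \cdot L \cdot W} with \eqn{L = 2\alpha},
#' \eqn{W = 2\beta} and
#' \deqn{\mathrm{MP}(n) = \frac{\Gamma(1 + 1/n)^2}{\Gamma(1 + 2/n)}.}
#'
#' An equivalent published form of the coefficient is
#' \eqn{4^{-1/n} \sqrt{\pi}\, \Gamma(1 + 1/n) / \Gamma(0.5 + 1/n)}; the two
#' agree by the Legendre duplication formula and this equivalence is
#' asserted in the test suite to 1e-12 over \eqn{n \in [0.5, 100]}.  The
#' duplication-reduced form above is evaluated via [lgamma()] for numerical
#' stability at large `n`.  Limiting cases: \eqn{\mathrm{MP}(1) = 1/2}
#' (rhombus), \eqn{\mathrm{MP}(2) = \pi/4} (ellipse),
#' \eqn{\mathrm{MP}(n) \to 1} as \eqn{n \to \infty} (rectangle).
#'
#' @param n shape exponent(s), > 0. Vectorised.
#' @return numeric vector of area coefficients.
#' @seealso [ei_of_n()], [se_area()], [se_boundary()]
#' @export
#' @examples
#' se_area_coefficient(2)    # pi/4
#' se_area_coefficient(1)    # 1/2
#' se_area_coefficient(1e6)  # -> 1 (rectangle limit)
se_area_coefficient <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0))
    stop("shape exponent 'n' must be finite and > 0", call. = FALSE)
  exp(2 * lgamma(1 + 1 / n) - lgamma(1 + 2 / n))
}

#' Superellipse area coefficient, direct published form
#'
#' The \eqn{4^{-1/n}\sqrt{\pi}\,\Gamma(1+1/n)/\Gamma(0.5+1/n)} form of the
#' superellipse area coefficient, kept as an independent route for the
#' duplication-formula equivalence check.
#'
#' @inheritParams se_area_coefficient
#' @return numeric vector of area coefficients.
#' @keywords internal
#' @export
se_area_coefficient_direct <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0))
    stop("shape exponent 'n' must be finite and > 0", call. = FALSE)
  exp(-log(4) / n + 0.5 * log(pi) + lgamma(1 + 1 / n) - lgamma(0.5 + 1 / n))
}

#' Superellipse area
#'
#' Closed-form area of a superellipse with length `L` (= \eqn{2\alpha}),
#' width `W` (= \eqn{2\beta}) and shape exponent `n`:
#' `se_area_coefficient(n) * L * W`.
#'
#' @param L length (twice the semi-axis along x), > 0.
#' @param W width (twice the semi-axis along y), > 0.
#' @param n shape exponent, > 0.
#' @return area in squared length units.
#' @export
se_area <- function(L, W, n) {
  if (any(L <= 0) || any(W <= 0))
    stop("'L' and 'W' must be > 0", call. = FALSE)
  se_area_coefficient(n) * L * W
}

#' Ellipticalness index of a superellipse
#'
#' The ellipticalness index EI of a lamina is its area divided by the area
#' of the ellipse with the same length and width, \eqn{A / ((\pi/4) L W)}.
#' For an exact superellipse this is \eqn{\mathrm{EI}(n) =
#' \mathrm{MP}(n) / (\pi/4)}: 1 at \eqn{n = 2} (ellipse), \eqn{2/\pi}
#' at \eqn{n = 1} (rhombus), rising sigmoidally to \eqn{4/\pi \approx 1.27}
#' as \eqn{n \to \infty}.
#'
#' @inheritParams se_area_coefficient
#' @return numeric vector of EI values.
#' @export
#' @examples
#' ei_of_n(2)    # 1
#' ei_of_n(1e6)  # -> 4/pi ~ 1.27
ei_of_n <- function(n) {
  se_area_coefficient(n) / (pi / 4)
}

#' Convert between the Montgomery parameter and the ellipticalness index
#'
#' MP and EI differ only by the ellipse constant:
#' \eqn{\mathrm{MP} = (\pi/4)\,\mathrm{EI}}.
#'
#' @param MP,EI positive numeric value(s).
#' @return the converted value(s).
#' @export
#' @examples
#' mp_to_ei(pi / 4)  # 1
#' ei_to_mp(1)       # pi/4
mp_to_ei <- function(MP) {
  if (any(!is.finite(MP)) || any(MP <= 0))
    stop("'MP' must be finite and > 0", call. = FALSE)
  MP / (pi / 4)
}

#' @rdname mp_to_ei
#' @export
ei_to_mp <- function(EI) {
  if (any(!is.finite(EI)) || any(EI <= 0))
    stop("'EI' must be finite and > 0", call. = FALSE)
  EI * (pi / 4)
}

#' Generate a superellipse boundary polygon
#'
#' Discretises \eqn{|x/\alpha|^n + |y/\beta|^n = 1} on a uniform parameter
#' grid \eqn{t \in [0, 2\pi)}, with vertices
#' \eqn{(\alpha\,\mathrm{sgn}(\cos t)|\cos t|^{2/n},\;
#'       \beta\,\mathrm{sgn}(\sin t)|\sin t|^{2/n})},
#' then shifts the base to the origin so the boundary is already in the
#' canonical frame: base at (0, 0), apex at (L, 0).  Uniform parameter
#' spacing (not arc length) is used; vertices cluster near the corners for
#' large `n`, which the discretisation-convergence tests account for.
#'
#' @inheritParams se_area
#' @param n_vertices number of boundary vertices, >= 64.
#' @param leaf_id identifier stored on the boundary.
#' @return a [leaf_boundary] in the canonical frame.
#' @export
#' @examples
#' b <- se_boundary(10, 4, n = 2, n_vertices = 256)  # an ellipse
#' polygon_area(b)  # ~ pi/4 * 10 * 4
se_boundary <- function(L, W, n, n_vertices = 1024, leaf_id = "superellipse") {
  if (n_vertices < 64) stop("'n_vertices' must be >= 64", call. = FALSE)
  if (any(L <= 0) || any(W <= 0) || any(n <= 0))
    stop("'L', 'W' and 'n' must be > 0", call. = FALSE)
  alpha <- L / 2
  beta <- W / 2
  # start at t = pi (the base) so the base and apex land exactly on vertices
  t <- pi + seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ct <- cos(t)
  st <- sin(t)
  # snap values that are zero up to floating error: |eps|^(2/n) is O(1)
  # for large n, so unsnapped roundoff would displace landmark vertices
  ct[abs(ct) < 1e-12] <- 0
  st[abs(st) < 1e-12] <- 0
  x <- alpha * sign(ct) * abs(ct)^(2 / n)
  y <- beta * sign(st) * abs(st)^(2 / n)
  apex_index <- which.max(x)
  leaf_boundary(cbind(x + alpha, y),
                base_index = 1L, apex_index = apex_index,
                leaf_id = leaf_id, check_simple = FALSE)
}
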