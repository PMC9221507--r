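#' Polygon area by the shoelace formula
#'
#' Absolute value of the signed (shoelace) area of the boundary polygon.
#' Invariant under rotation of the vertex list, reflection, and rigid
#' motion of the coordinates.
#'
#' @param boundary a [leaf_boundary], or a two-column coordinate matrix
#'   with at least 3 rows.
#' @return the enclosed area (squared input units, cm^2 for cm input).
#' @export
polygon_area <- function(boundary) {
  v <- if (inherits(boundary, "leaf_boundary")) boundary$vertices
       else as.matrix(boundary)
  if (nrow(v) < 3)
    stop("invalid geometry: a polygon needs at least 3 vertices", call. = FALSE)
  abs(signed_area(v))
}

#' Leaf length
#'
#' The base-to-apex chord length: in the canonical frame, the x coordinate
#' of the apex landmark.  The boundary is oriented first if needed.
#'
#' @param boundary a [leaf_boundary].
#' @return leaf length L (input units).
#' @export
leaf_length <- function(boundary) {
  b <- as_canonical(boundary)
  as.numeric(b$vertices[b$apex_index, 1])
}

# Widths of the polygon cut by vertical lines at the sorted station
# positions `xs` (canonical frame).  For each station the width is
# max(y) - min(y) over all crossings of the line with boundary edges,
# with crossings interpolated linearly along edges.  Stations with no
# crossing get width 0 and are reported in the "missed" attribute.
#
# Implementation: each non-vertical edge spans a contiguous run of
# stations (closed interval [min x, max x]); the runs are expanded with
# sequence() so the whole profile is computed vectorised, with total work
# proportional to the number of crossings (~2 per station for laminas
# that are single-valued above and below the axis).
width_profile <- function(vertices, xs) {
  n <- nrow(vertices)
  nxt <- c(2:n, 1L)
  x1 <- vertices[, 1]; y1 <- vertices[, 2]
  x2 <- vertices[nxt, 1]; y2 <- vertices[nxt, 2]

  vert <- x1 == x2
  exlo <- pmin(x1, x2)
  exhi <- pmax(x1, x2)
  # first/last station index covered by each edge
  fi <- findInterval(exlo, xs, left.open = TRUE) + 1L
  li <- findInterval(exhi, xs)
  cnt <- pmax(li - fi + 1L, 0L)
  cnt[vert] <- 0L

  ne <- which(cnt > 0L)
  edge <- rep(ne, cnt[ne])
  st <- sequence(cnt[ne], from = fi[ne])
  ys <- y1[edge] + (xs[st] - x1[edge]) * (y2[edge] - y1[edge]) / (x2[edge] - x1[edge])

  # vertical edges contribute both endpoints at their exact station
  vi <- which(vert)
  if (length(vi)) {
    m <- match(x1[vi], xs)
    ok <- !is.na(m)
    if (any(ok)) {
      st <- c(st, m[ok], m[ok])
      ys <- c(ys, y1[vi][ok], y2[vi][ok])
    }
  }

  w <- numeric(length(xs))
  if (length(st)) {
    o <- order(st, ys)
    so <- st[o]; yo <- ys[o]
    first <- !duplicated(so)
    last <- !duplicated(so, fromLast = TRUE)
    w[so[first]] <- yo[last] - yo[first]
  }
  missed <- setdiff(seq_along(xs), unique(st))
  attr(w, "missed") <- missed
  w
}

#' Leaf width at a fractional station along the length axis
#'
#' Intersects the vertical line `x = f * L` (canonical frame) with the
#' boundary polygon; the width is the spread (max minus min) of the y
#' coordinates of all crossings, computed by linear interpolation along
#' edges.  If the line misses the lamina entirely the width is 0 and a
#' warning is raised.
#'
#' @param boundary a [leaf_boundary].
#' @param f station as a fraction of leaf length, in (0, 1).  Vectorised.
#' @return numeric vector of widths (input units).
#' @export
#' @examples
#' e <- se_boundary(10, 4, n = 2, n_vertices = 1024)
#' width_at(e, 0.5)   # ~ 4, the maximum width of the ellipse
#' width_at(e, 0.25)  # ~ 4 * sqrt(3)/2
width_at <- function(boundary, f) {
  if (any(f <= 0) || any(f >= 1))
    stop("'f' must lie strictly inside (0, 1)", call. = FALSE)
  b <- as_canonical(boundary)
  L <- as.numeric(b$vertices[b$apex_index, 1])
  xs <- f * L
  o <- order(xs)
  w <- width_profile(b$vertices, xs[o])
  if (length(attr(w, "missed")))
    warning("station(s) outside the lamina support; width reported as 0",
            call. = FALSE)
  out <- numeric(length(xs))
  out[o] <- as.numeric(w)
  out
}

#' Maximum leaf width and its axial position
#'
#' Scans the width profile on a uniform axial grid of `resolution` stations
#' (plus every vertex x position, where the piecewise-linear profile has its
#' knots), takes the maximum, and refines it by golden-section search in the
#' bracketing grid interval to an axial tolerance of `1e-6 * L`.  On a
#' plateau of equal maxima the smallest axial position is reported.
#'
#' @param boundary a [leaf_boundary].
#' @param resolution number of uniform grid stations, >= 100
#'   (default 1001).
#' @return named numeric vector `c(W = ..., L_W = ...)`: the maximum width
#'   and the distance from the base to the station attaining it.
#' @export
max_width <- function(boundary, resolution = 1001) {
  if (resolution < 100) stop("'resolution' must be >= 100", call. = FALSE)
  b <- as_canonical(boundary)
  v <- b$vertices
  L <- as.numeric(v[b$apex_index, 1])
  xs <- sort(unique(c(seq(0, L, length.out = resolution),
                      v[v[, 1] >= 0 & v[, 1] <= L, 1])))
  w <- as.numeric(width_profile(v, xs))
  k <- which.max(w)   # first index on exact plateaus -> smallest station
  W <- w[k]
  L_W <- xs[k]
  lo <- if (k > 1) xs[k - 1] else xs[k]
  hi <- if (k < length(xs)) xs[k + 1] else xs[k]
  if (hi > lo) {
    ref <- golden_max(function(x) as.numeric(width_profile(v, x)),
                      lo, hi, tol = 1e-6 * L)
    # keep the refinement only if it strictly improves, so plateau
    # tie-breaking (smallest station) is preserved
    if (ref$value > W) {
      W <- ref$value
      L_W <- ref$arg
    }
  }
  c(W = W, L_W = L_W)
}

golden_max <- function(fn, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- fn(c1); f2 <- fn(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- fn(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- fn(c1)
    }
  }
  if (f1 >= f2) list(arg = c1, value = f1) else list(arg = c2, value = f2)
}

#' Areas of the two sides of the length axis
#'
#' Clips the canonical polygon by the length axis (the x axis) and returns
#' the lamina area on each side.  With the base at the origin and the apex
#' on the positive x axis, "left" is the side with positive y — the paper
#' orientation of the scan fixes which anatomical side that is, so only the
#' magnitude of the left/right contrast is orientation-free.  Degenerate
#' clip slivers below 1e-12 area are dropped.  `A_left + A_right` equals
#' [polygon_area()] to within 1e-6 relative tolerance.
#'
#' @param boundary a [leaf_boundary].
#' @return named numeric vector `c(A_left = ..., A_right = ...)`.
#' @export
split_areas <- function(boundary) {
  b <- as_canonical(boundary)
  v <- b$vertices
  upper <- clip_halfplane(v, +1)
  lower <- clip_halfplane(v, -1)
  area_of <- function(p) {
    if (is.null(p) || nrow(p) < 3) return(0)
    a <- abs(signed_area(p))
    if (a < 1e-12) 0 else a
  }
  c(A_left = area_of(upper), A_right = area_of(lower))
}

# Sutherland-Hodgman clip of a simple polygon against the half-plane
# sign * y >= 0.  Spurious zero-width seams possibly produced for
# non-convex subjects do not affect the enclosed area.
clip_halfplane <- function(v, sgn) {
  n <- nrow(v)
  y <- sgn * v[, 2]
  if (all(y >= 0)) return(v)
  if (all(y <= 0)) return(NULL)
  nxt <- c(2:n, 1L)
  outx <- numeric(2 * n)
  outy <- numeric(2 * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    yi <- y[i]; yj <- y[j]
    if (yi >= 0) {
      k <- k + 1L; outx[k] <- v[i, 1]; outy[k] <- v[i, 2]
    }
    if ((yi > 0 && yj < 0) || (yi < 0 && yj > 0)) {
      t <- yi / (yi - yj)
      k <- k + 1L
      outx[k] <- v[i, 1] + t * (v[j, 1] - v[i, 1])
      outy[k] <- 0
    }
  }
  if (k < 3) return(NULL)
  cbind(outx[seq_len(k)], outy[seq_len(k)])
}

#' Measure a leaf boundary
#'
#' One measurement pass over a boundary polygon: orients it to the
#' canonical frame, then computes lamina area A, length L, maximum width W
#' and its axial position L_W, the widths at 1/8, 1/4, 3/4 and 7/8 of the
#' length from the base, the left/right split areas, and — when a dry mass
#' is supplied — the leaf dry mass per unit area (LMA, g m^-2, with A in
#' cm^2).  All downstream shape indices are computed from this single pass
#' via [shape_indices()].
#'
#' @param boundary a [leaf_boundary].
#' @param dry_mass leaf dry mass in grams, or `NULL`.
#' @param resolution grid resolution for [max_width()].
#' @return an object of class `leaf_measurements`: a list with elements
#'   `leaf_id, A, L, W, L_W, W_f` (named vector over fractions
#'   `"1/8", "1/4", "3/4", "7/8"`), `A_left, A_right, dry_mass, LMA`.
#' @export
#' @examples
#' m <- measure_leaf(se_boundary(10, 4, n = 2, n_vertices = 2048),
#'                   dry_mass = 0.5)
#' m$A    # ~ pi/4 * 40
#' m$LMA  # g m^-2
measure_leaf <- function(boundary, dry_mass = NULL, resolution = 1001) {
  b <- as_canonical(boundary)
  A <- polygon_area(b)
  L <- as.numeric(b$vertices[b$apex_index, 1])
  if (L <= 0) stop("invalid geometry: non-positive leaf length", call. = FALSE)
  mw <- max_width(b, resolution = resolution)
  fr <- c(1 / 8, 1 / 4, 3 / 4, 7 / 8)
  W_f <- width_at(b, fr)
  names(W_f) <- c("1/8", "1/4", "3/4", "7/8")
  sa <- split_areas(b)
  LMA <- NULL
  if (!is.null(dry_mass)) {
    LMA <- lma(dry_mass, A)
  }
  structure(list(leaf_id = b$leaf_id, A = A, L = L,
                 W = unname(mw["W"]), L_W = unname(mw["L_W"]),
                 W_f = W_f, A_left = unname(sa["A_left"]),
                 A_right = unname(sa["A_right"]),
                 dry_mass = dry_mass, LMA = LMA),
            class = "leaf_measurements")
}

#' @export
print.leaf_measurements <- function(x, ...) {
  cat(sprintf("<leaf_measurements '%s': A=%.4g  L=%.4g  W=%.4g  L_W=%.4g%s>\n",
              x$leaf_id, x$A, x$L, x$W, x$L_W,
              if (is.null(x$LMA)) "" else sprintf("  LMA=%.4g g/m^2", x$LMA)))
  invisible(x)
}

#' Tabulate leaf measurements
#'
#' Flattens one or more `leaf_measurements` into the one-row-per-leaf
#' measurements table with columns `leaf_id, A, L, W, L_W, W_eighth,
#' W_quarter, W_threequarter, W_seveneighth, A_left, A_right, dry_mass,
#' LMA` (missing mass yields `NA`).
#'
#' @param measurements a `leaf_measurements` or list of them.
#' @return a data frame, one row per leaf.
#' @export
measurements_table <- function(measurements) {
  if (inherits(measurements, "leaf_measurements"))
    measurements <- list(measurements)
  do.call(rbind, lapply(measurements, function(m) {
    data.frame(leaf_id = m$leaf_id, A = m$A, L = m$L, W = m$W, L_W = m$L_W,
               W_eighth = m$W_f[["1/8"]], W_quarter = m$W_f[["1/4"]],
               W_threequarter = m$W_f[["3/4"]],
               W_seveneighth = m$W_f[["7/8"]],
               A_left = m$A_left, A_right = m$A_right,
               dry_mass = if (is.null(m$dry_mass)) NA_real_ else m$dry_mass,
               LMA = if (is.null(m$LMA)) NA_real_ else m$LMA)
  }))
}
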