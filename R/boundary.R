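#' Construct a leaf boundary polygon
#'
#' A `leaf_boundary` is an ordered, closed, simple planar polygon tracing a
#' lamina edge, with two landmark vertices identifying the leaf base (the
#' petiole insertion) and the apex.  Coordinates are in physical length
#' units (cm) after upstream scan calibration; pixel-to-cm conversion is the
#' caller's responsibility.
#'
#' The polygon is treated as closed (the first vertex follows the last); a
#' duplicated closing vertex is dropped.  If the landmarks are not supplied
#' they are auto-detected as the farthest-apart vertex pair (searched on the
#' convex hull), with the vertex of smaller index taken as the base — the
#' documented fallback when base/apex are unknown.
#'
#' Self-intersection is checked by a pairwise segment-intersection scan,
#' which is quadratic in the vertex count; by default the scan runs only for
#' polygons with at most 600 vertices (`check_simple = NULL`).  Pass
#' `check_simple = TRUE`/`FALSE` to force or skip it, or call
#' [is_simple_polygon()] directly.
#'
#' @param vertices two-column numeric matrix (or data frame) of x, y
#'   coordinates, at least 16 rows.
#' @param base_index,apex_index integer indices (1-based) of the base and
#'   apex landmark vertices, or `NULL` to auto-detect.
#' @param leaf_id identifier carried through measurement output.
#' @param check_simple run the self-intersection scan? `NULL` (default)
#'   runs it for polygons with <= 600 vertices.
#' @return an object of class `leaf_boundary`: a list with elements
#'   `vertices` (n x 2 matrix), `base_index`, `apex_index`, `leaf_id`.
#' @seealso [orient_leaf()], [measure_leaf()], [read_boundary_csv()]
#' @export
leaf_boundary <- function(vertices, base_index = NULL, apex_index = NULL,
                          leaf_id = "leaf", check_simple = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || !is.numeric(vertices))
    stop("'vertices' must be a two-column numeric matrix", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("'vertices' must be finite", call. = FALSE)
  n <- nrow(vertices)
  # drop a duplicated closing vertex
  if (n > 1 && all(abs(vertices[n, ] - vertices[1, ]) < 1e-12)) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
    if (!is.null(base_index) && base_index > n) base_index <- 1L
    if (!is.null(apex_index) && apex_index > n) apex_index <- 1L
  }
  if (n < 16)
    stop("a leaf boundary needs at least 16 vertices, got ", n, call. = FALSE)

  if (is.null(base_index) || is.null(apex_index)) {
    fp <- farthest_vertex_pair(vertices)
    if (is.null(base_index) && is.null(apex_index)) {
      base_index <- fp[1]
      apex_index <- fp[2]
    } else if (is.null(apex_index)) {
      apex_index <- if (fp[1] == base_index) fp[2] else fp[1]
    } else {
      base_index <- if (fp[1] == apex_index) fp[2] else fp[1]
    }
  }
  base_index <- as.integer(base_index)
  apex_index <- as.integer(apex_index)
  if (base_index < 1 || base_index > n || apex_index < 1 || apex_index > n)
    stop("landmark index out of range", call. = FALSE)
  if (base_index == apex_index)
    stop("base and apex landmarks must differ", call. = FALSE)

  if (abs(signed_area(vertices)) < 1e-300)
    stop("degenerate polygon: signed area is zero", call. = FALSE)

  if (is.null(check_simple)) check_simple <- n <= 600
  if (check_simple && !is_simple_polygon(vertices))
    stop("polygon is self-intersecting", call. = FALSE)

  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, base_index = base_index,
                 apex_index = apex_index, leaf_id = as.character(leaf_id)),
            class = "leaf_boundary")
}

#' @export
print.leaf_boundary <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("<leaf_boundary '%s': %d vertices, base #%d (%.4g, %.4g), apex #%d (%.4g, %.4g)>\n",
              x$leaf_id, nrow(v),
              x$base_index, v[x$base_index, 1], v[x$base_index, 2],
              x$apex_index, v[x$apex_index, 1], v[x$apex_index, 2]))
  invisible(x)
}

# farthest-apart vertex pair, searched on the convex hull (the diameter of a
# point set is attained between hull vertices)
farthest_vertex_pair <- function(vertices) {
  h <- grDevices::chull(vertices)
  hv <- vertices[h, , drop = FALSE]
  d <- as.matrix(stats::dist(hv))
  ij <- arrayInd(which.max(d), dim(d))
  pair <- sort(c(h[ij[1]], h[ij[2]]))
  as.integer(pair)
}

# shoelace signed area; positive for counter-clockwise winding
signed_area <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection scan over all non-adjacent edge pairs
#' (quadratic in the vertex count).  Edges sharing a vertex are allowed to
#' touch at that vertex only.
#'
#' @param vertices two-column numeric matrix of polygon vertices (closed
#'   implicitly), or a [leaf_boundary].
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_polygon <- function(vertices) {
  if (inherits(vertices, "leaf_boundary")) vertices <- vertices$vertices
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1L)
  p1x <- v[, 1]; p1y <- v[, 2]
  p2x <- v[nxt, 1]; p2y <- v[nxt, 2]
  for (i in seq_len(n - 2)) {
    # skip adjacent edges (i-1, i, i+1); edge n is adjacent to edge 1
    j <- (i + 2):n
    if (i == 1) j <- j[j < n]
    if (!length(j)) next
    if (any(segments_cross(p1x[i], p1y[i], p2x[i], p2y[i],
                           p1x[j], p1y[j], p2x[j], p2y[j])))
      return(FALSE)
  }
  TRUE
}

# vectorised proper/improper intersection test of segment (a1,a2) against
# segments (b1,b2)
segments_cross <- function(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y) {
  orient <- function(px, py, qx, qy, rx, ry)
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  d1 <- orient(a1x, a1y, a2x, a2y, b1x, b1y)
  d2 <- orient(a1x, a1y, a2x, a2y, b2x, b2y)
  d3 <- orient(b1x, b1y, b2x, b2y, a1x, a1y)
  d4 <- orient(b1x, b1y, b2x, b2y, a2x, a2y)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  # collinear overlap: all orientations zero and bounding boxes overlap
  col <- (d1 == 0) & (d2 == 0) & (d3 == 0) & (d4 == 0)
  if (any(col)) {
    overlap <- pmin(a1x, a2x) <= pmax(b1x, b2x) & pmax(a1x, a2x) >= pmin(b1x, b2x) &
      pmin(a1y, a2y) <= pmax(b1y, b2y) & pmax(a1y, a2y) >= pmin(b1y, b2y)
    proper <- proper | (col & overlap)
  }
  proper
}

#' Rigidly transform a boundary into the canonical measurement frame
#'
#' Translates and rotates the polygon so the base landmark sits at the
#' origin and the apex landmark lies on the positive x axis at distance
#' `|apex - base|`; the winding is normalised to counter-clockwise by
#' reversing the vertex order if needed (a reversal, not a reflection, so
#' left/right sides are preserved).  All downstream measurements
#' ([polygon_area()], [width_at()], [max_width()], [split_areas()]) assume
#' this frame; [measure_leaf()] applies it automatically.
#'
#' @param boundary a [leaf_boundary].
#' @return the transformed `leaf_boundary`, with attribute `"canonical"`
#'   set to `TRUE`.
#' @export
orient_leaf <- function(boundary) {
  stopifnot(inherits(boundary, "leaf_boundary"))
  v <- boundary$vertices
  base <- v[boundary$base_index, ]
  apex <- v[boundary$apex_index, ]
  d <- apex - base
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("invalid geometry: base and apex landmarks coincide", call. = FALSE)
  ct <- d[1] / len
  st <- d[2] / len
  # rotate by -angle, translate base to origin
  vx <- v[, 1] - base[1]
  vy <- v[, 2] - base[2]
  v2 <- cbind(x = ct * vx + st * vy, y = -st * vx + ct * vy)
  b <- boundary$base_index
  a <- boundary$apex_index
  if (signed_area(v2) < 0) {
    n <- nrow(v2)
    idx <- rev(seq_len(n))
    v2 <- v2[idx, , drop = FALSE]
    b <- n + 1L - b
    a <- n + 1L - a
  }
  out <- boundary
  out$vertices <- v2
  out$base_index <- b
  out$apex_index <- a
  attr(out, "canonical") <- TRUE
  out
}

as_canonical <- function(boundary) {
  if (isTRUE(attr(boundary, "canonical"))) boundary else orient_leaf(boundary)
}

#' Read leaf boundaries from CSV
#'
#' Reads the long-format boundary dialect: columns
#' `leaf_id, vertex_index, x, y` (0-based `vertex_index`), optionally with
#' landmark columns `is_base, is_apex` (0/1 or logical).  Landmarks may
#' instead come from a sidecar table `leaf_id, base_index, apex_index`
#' (0-based indices) passed as `landmarks` (a data frame or a CSV path).
#' Without either, landmarks are auto-detected per leaf (farthest-pair
#' fallback, see [leaf_boundary()]).
#'
#' @param path CSV file path.
#' @param landmarks optional sidecar: data frame or CSV path with columns
#'   `leaf_id, base_index, apex_index` (0-based).
#' @param check_simple passed to [leaf_boundary()].
#' @return named list of [leaf_boundary] objects, one per `leaf_id`.
#' @export
read_boundary_csv <- function(path, landmarks = NULL, check_simple = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("boundary CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lm <- NULL
  if (!is.null(landmarks)) {
    lm <- if (is.character(landmarks))
      utils::read.csv(landmarks, stringsAsFactors = FALSE) else landmarks
    if (!all(c("leaf_id", "base_index", "apex_index") %in% names(lm)))
      stop("landmark sidecar must have columns leaf_id, base_index, apex_index",
           call. = FALSE)
  }
  out <- lapply(split(df, df$leaf_id), function(d) {
    d <- d[order(d$vertex_index), ]
    bi <- ai <- NULL
    if (!is.null(lm)) {
      row <- lm[lm$leaf_id == d$leaf_id[1], ]
      if (nrow(row) == 1) {
        bi <- as.integer(row$base_index) + 1L
        ai <- as.integer(row$apex_index) + 1L
      }
    } else if (all(c("is_base", "is_apex") %in% names(d))) {
      bi <- which(as.logical(d$is_base))[1]
      ai <- which(as.logical(d$is_apex))[1]
    }
    leaf_boundary(cbind(d$x, d$y), base_index = bi, apex_index = ai,
                  leaf_id = d$leaf_id[1], check_simple = check_simple)
  })
  out[unique(df$leaf_id)]
}

#' Write leaf boundaries to CSV
#'
#' Writes the long-format dialect read by [read_boundary_csv()], with
#' landmark flag columns `is_base, is_apex` and 0-based `vertex_index`.
#'
#' @param boundaries a [leaf_boundary] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(boundaries, path) {
  if (inherits(boundaries, "leaf_boundary")) boundaries <- list(boundaries)
  rows <- lapply(boundaries, function(b) {
    n <- nrow(b$vertices)
    data.frame(leaf_id = b$leaf_id, vertex_index = 0:(n - 1),
               x = b$vertices[, 1], y = b$vertices[, 2],
               is_base = as.integer(seq_len(n) == b$base_index),
               is_apex = as.integer(seq_len(n) == b$apex_index))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
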