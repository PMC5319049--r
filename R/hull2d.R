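# 2D hull geometry: QuickHull convex hull, concave hull by edge digging,
# and the concave shell. These operate on the per-slice xy projections of
# C-alpha atoms and are the geometric heart of the classifier.

# cross product z-component of (b-a) x (p-a); > 0 means p is left of a->b
.cross2 <- function(a, b, p) {
  (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
}

# vectorised version over rows of P
.cross2v <- function(a, b, P) {
  (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
}

.as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (!is.matrix(points) || ncol(points) < 2)
    stop("points must be a matrix or data frame with x and y columns")
  storage.mode(points) <- "double"
  if (any(!is.finite(points[, 1:2]))) stop("points must have finite coordinates")
  points[, 1:2, drop = FALSE]
}

.hull_eps <- function(P) {
  span <- max(apply(P, 2, function(v) diff(range(v))), 1)
  span * 1e-9
}

# are all points collinear (within eps)?
.all_collinear <- function(P, eps) {
  n <- nrow(P)
  if (n <= 2) return(TRUE)
  a <- P[1, ]
  i2 <- which(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2) > eps)[1]
  if (is.na(i2)) return(TRUE)        # all points coincide
  b <- P[i2, ]
  all(abs(.cross2v(a, b, P)) <= eps * max(1, vnorm(b - a)))
}

#' 2D convex hull by QuickHull
#'
#' Computes the convex hull of a planar point cloud with the QuickHull
#' scheme: the extreme points in x and y seed an initial polygon, every
#' remaining point is classified inside or outside, and each hull edge is
#' repeatedly expanded by the outside point farthest from it until no
#' outside point remains. Points that fall exactly on a hull edge are kept
#' on the boundary.
#'
#' @param points numeric matrix (or data frame) with columns `x`, `y`; row
#'   names, when present, are preserved as point labels.
#' @return An object of class `hull2d`: a list with `boundary` (indices of
#'   boundary points, counter-clockwise order), `interior` (indices of all
#'   other points), `kind` (`"convex"`), `points` (the input coordinates)
#'   and `degenerate` (`TRUE` when fewer than 3 distinct non-collinear
#'   points were supplied, in which case the boundary is all points).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' colnames(sq) <- c("x", "y")
#' convex_hull(sq)$boundary
#' @export
convex_hull <- function(points) {
  P <- .as_points(points)
  n <- nrow(P)
  if (n < 1) stop("convex_hull requires at least one point")
  eps <- .hull_eps(P)

  if (n <= 2 || .all_collinear(P, eps)) {
    # degenerate: every point is boundary, ordered along the line
    if (n == 1) ord <- 1L
    else {
      dir <- P[which.max(sqrt((P[, 1] - P[1, 1])^2 + (P[, 2] - P[1, 2])^2)), ] - P[1, ]
      ord <- order(P[, 1] * dir[1] + P[, 2] * dir[2])
    }
    return(structure(list(boundary = as.integer(ord), interior = integer(0),
                          kind = "convex", points = P, degenerate = TRUE),
                     class = "hull2d"))
  }

  # seed with the x/y extreme points, ordered counter-clockwise
  seeds <- unique(c(which.min(P[, 1]), which.min(P[, 2]),
                    which.max(P[, 1]), which.max(P[, 2])))
  ctr <- colMeans(P[seeds, , drop = FALSE])
  seeds <- seeds[order(atan2(P[seeds, 2] - ctr[2], P[seeds, 1] - ctr[1]))]

  # recursive edge expansion; boundary kept as an ordered CCW index vector
  boundary <- as.integer(seeds)
  remaining <- setdiff(seq_len(n), boundary)

  expand <- function(a_idx, b_idx, cand) {
    # points in cand strictly right of directed edge a->b are outside
    if (length(cand) == 0) return(list(chain = integer(0), used = integer(0)))
    a <- P[a_idx, ]; b <- P[b_idx, ]
    cr <- .cross2v(a, b, P[cand, , drop = FALSE])
    out <- cand[cr < -eps]
    if (length(out) == 0) return(list(chain = integer(0), used = integer(0)))
    # farthest point from the edge (perpendicular distance ~ |cross|)
    d <- abs(.cross2v(a, b, P[out, , drop = FALSE]))
    far <- out[which.max(d)]
    rest <- setdiff(out, far)
    left <- expand(a_idx, far, rest)
    right <- expand(far, b_idx, setdiff(rest, left$used))
    list(chain = c(left$chain, far, right$chain),
         used = c(out, left$used, right$used))
  }

  k <- length(boundary)
  newb <- integer(0)
  for (i in seq_len(k)) {
    a_idx <- boundary[i]
    b_idx <- boundary[if (i == k) 1L else i + 1L]
    res <- expand(a_idx, b_idx, remaining)
    remaining <- setdiff(remaining, res$chain)
    newb <- c(newb, a_idx, res$chain)
  }
  boundary <- newb

  # retain points lying exactly on a hull edge as boundary points
  interior <- setdiff(seq_len(n), boundary)
  if (length(interior) > 0) {
    k <- length(boundary)
    add_after <- vector("list", k)
    on_edge <- logical(length(interior))
    for (i in seq_len(k)) {
      a <- P[boundary[i], ]
      b <- P[boundary[if (i == k) 1L else i + 1L], ]
      cand <- interior[!on_edge]
      if (length(cand) == 0) next
      Q <- P[cand, , drop = FALSE]
      cr <- abs(.cross2v(a, b, Q))
      ab <- b - a
      t <- ((Q[, 1] - a[1]) * ab[1] + (Q[, 2] - a[2]) * ab[2]) / sum(ab * ab)
      hit <- cr <= eps * max(1, vnorm(ab)) & t > 0 & t < 1
      if (any(hit)) {
        sel <- cand[hit]
        add_after[[i]] <- sel[order(t[hit])]
        on_edge[match(sel, interior)] <- TRUE
      }
    }
    if (any(on_edge)) {
      out <- integer(0)
      for (i in seq_len(k)) out <- c(out, boundary[i], add_after[[i]])
      boundary <- out
      interior <- interior[!on_edge]
    }
  }

  structure(list(boundary = as.integer(boundary),
                 interior = as.integer(interior),
                 kind = "convex", points = P, degenerate = FALSE),
            class = "hull2d")
}

# interior angle at vertex v between rays v->p and v->q, degrees
.angle_at <- function(v, p, q) {
  vangle(c(p - v, 0), c(q - v, 0))
}

# do segments (p1,p2) and (p3,p4) properly intersect (interiors cross)?
.segments_cross <- function(p1, p2, p3, p4, eps) {
  d1 <- .cross2(p3, p4, p1); d2 <- .cross2(p3, p4, p2)
  d3 <- .cross2(p1, p2, p3); d4 <- .cross2(p1, p2, p4)
  ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
    ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))
}

#' Concave hull by edge digging
#'
#' Refines a convex hull into a concave hull: while some boundary edge is
#' longer than `dist_cutoff`, the longest such edge is "dug into" by moving
#' the interior point with the smallest sum of angles to the edge's two
#' endpoints onto the boundary between them. The cutoff acts as the
#' resolution of the hull: smaller cutoffs produce more rugged boundaries.
#' A candidate whose insertion would make the boundary self-intersecting is
#' skipped; an edge with no admissible candidate is left long and marked
#' final, which guarantees termination.
#'
#' @param points the point cloud used to build `convex` (matrix with
#'   columns `x`, `y`).
#' @param convex a `hull2d` of kind `"convex"` over `points`, from
#'   [convex_hull()]. May be omitted (`NULL`) to have it computed.
#' @param dist_cutoff maximum admissible boundary edge length in the same
#'   units as the coordinates (angstroms in the classifier; default 10).
#' @return A `hull2d` of kind `"concave"`; its `edge_final` field flags
#'   edges left longer than the cutoff because no admissible dig existed.
#' @export
concave_hull <- function(points, convex = NULL, dist_cutoff = 10) {
  if (!is.numeric(dist_cutoff) || dist_cutoff <= 0)
    stop("dist_cutoff must be a positive length")
  if (is.null(convex)) convex <- convex_hull(points)
  stopifnot(inherits(convex, "hull2d"))
  P <- convex$points
  eps <- .hull_eps(P)

  if (convex$degenerate) {
    out <- convex
    out$kind <- "concave"
    out$edge_final <- rep(TRUE, length(out$boundary))
    return(out)
  }

  boundary <- convex$boundary
  interior <- convex$interior
  k <- length(boundary)
  final <- rep(FALSE, k)          # final[i]: edge boundary[i] -> boundary[i+1]

  edge_len <- function() {
    nxt <- c(boundary[-1], boundary[1])
    sqrt((P[boundary, 1] - P[nxt, 1])^2 + (P[boundary, 2] - P[nxt, 2])^2)
  }

  repeat {
    lens <- edge_len()
    open <- which(!final & lens > dist_cutoff)
    if (length(open) == 0) break
    if (length(interior) == 0) {        # nothing left to dig with
      final[open] <- TRUE
      break
    }
    i <- open[which.max(lens[open])]
    k <- length(boundary)
    ai <- boundary[i]; bi <- boundary[if (i == k) 1L else i + 1L]
    a <- P[ai, ]; b <- P[bi, ]

    # rank interior candidates by sum of angles at the edge endpoints
    angsum <- vapply(interior, function(j) {
      p <- P[j, ]
      s <- .angle_at(a, b, p) + .angle_at(b, a, p)
      if (is.na(s)) Inf else s
    }, numeric(1))
    mid <- (a + b) / 2
    dmid <- sqrt((P[interior, 1] - mid[1])^2 + (P[interior, 2] - mid[2])^2)
    ord <- order(angsum, dmid, interior)

    dug <- FALSE
    for (j in interior[ord]) {
      if (!is.finite(angsum[match(j, interior)])) break
      p <- P[j, ]
      # admissibility: new edges a-p and p-b must not cross other edges
      ok <- TRUE
      kk <- length(boundary)
      for (e in seq_len(kk)) {
        u <- boundary[e]; v <- boundary[if (e == kk) 1L else e + 1L]
        if (u == ai && v == bi) next
        pu <- P[u, ]; pv <- P[v, ]
        if (!(u == ai || v == ai) && .segments_cross(a, p, pu, pv, eps)) { ok <- FALSE; break }
        if (!(u == bi || v == bi) && .segments_cross(p, b, pu, pv, eps)) { ok <- FALSE; break }
      }
      if (!ok) next
      # splice p into the boundary between a and b
      boundary <- append(boundary, j, after = i)
      final <- append(final, FALSE, after = i)   # new edges a-p, p-b both open
      interior <- setdiff(interior, j)
      dug <- TRUE
      break
    }
    if (!dug) final[i] <- TRUE
  }

  structure(list(boundary = as.integer(boundary),
                 interior = as.integer(interior),
                 kind = "concave", points = P, degenerate = FALSE,
                 edge_final = final),
            class = "hull2d")
}

#' Concave shell: boundary plus nearby points
#'
#' Extends a hull boundary back into a thick shell by adding every point
#' whose planar distance to some boundary point is at most `shell_radius`.
#' This maps the 2D hull back to the 3D structure: all residues whose
#' projected C-alpha falls within the shell are treated as boundary
#' residues.
#'
#' @param points the point cloud of `hull`.
#' @param hull a `hull2d` over `points`.
#' @param shell_radius capture radius in coordinate units (default 6).
#' @return list with `shell` (indices, superset of the boundary) and
#'   `radius`, class `concave_shell`.
#' @export
concave_shell <- function(points, hull = NULL, shell_radius = 6) {
  if (!is.numeric(shell_radius) || shell_radius < 0)
    stop("shell_radius must be >= 0")
  if (is.null(hull)) hull <- concave_hull(points)
  stopifnot(inherits(hull, "hull2d"))
  P <- hull$points
  B <- P[hull$boundary, , drop = FALSE]
  dmin <- vapply(seq_len(nrow(P)), function(i) {
    min(sqrt((B[, 1] - P[i, 1])^2 + (B[, 2] - P[i, 2])^2))
  }, numeric(1))
  shell <- sort(unique(c(hull$boundary, which(dmin <= shell_radius))))
  structure(list(shell = as.integer(shell), radius = shell_radius),
            class = "concave_shell")
}

#' Enclosed area of a hull boundary polygon
#'
#' Shoelace area of the (closed) boundary polygon of a `hull2d`. Degenerate
#' hulls have zero area.
#'
#' @param hull a `hull2d`.
#' @return area in squared coordinate units.
#' @export
hull_area <- function(hull) {
  stopifnot(inherits(hull, "hull2d"))
  b <- hull$boundary
  if (length(b) < 3 || isTRUE(hull$degenerate)) return(0)
  x <- hull$points[b, 1]; y <- hull$points[b, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' @export
print.hull2d <- function(x, ...) {
  cat(sprintf("2D %s hull: %d boundary / %d interior points%s\n",
              x$kind, length(x$boundary), length(x$interior),
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}
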