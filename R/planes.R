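# Oriented planes in world millimetres: {p : normal . p == offset}.
# The sign of signed_distance() decides every downstream half-space label,
# so every constructor fixes the normal's orientation deterministically.

#' Oriented plane
#'
#' An oriented plane is stored as a unit normal `n` and scalar offset `d`, the
#' point set `{p : n . p == d}`. The signed distance of a point `p` is
#' `n . p - d`; its sign selects a half-space and is used throughout the
#' voxel partition, so the orientation of `n` is part of the object's meaning.
#'
#' @param normal numeric length-3 normal vector (need not be unit length; it
#'   is normalised on construction).
#' @param offset scalar offset in mm, or a point on the plane (length-3
#'   vector), in which case the offset is computed as `normal . point`.
#' @param label optional token naming the plane (e.g. `"median"`).
#' @return An object of class `plane3`.
#' @export
plane3 <- function(normal, offset = 0, label = NULL) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L, all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) {
    stop("degenerate geometry: zero-length plane normal", call. = FALSE)
  }
  normal <- normal / nn
  if (length(offset) == 3L) offset <- sum(normal * as.numeric(offset))
  stopifnot(length(offset) == 1L, is.finite(offset))
  structure(list(normal = normal, offset = as.numeric(offset), label = label),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3%s> normal = (%.6f, %.6f, %.6f), offset = %.4f mm\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distance from points to a plane
#'
#' @param plane a [plane3()].
#' @param points a length-3 vector or an `n x 3` matrix of points (mm).
#' @return Numeric vector of signed distances (mm); positive on the side the
#'   normal points into.
#' @export
signed_distance <- function(plane, points) {
  stopifnot(inherits(plane, "plane3"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  drop(points %*% plane$normal) - plane$offset
}

# cross product, 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length ", what, call. = FALSE)
  v / n
}

# Rodrigues rotation of v about unit axis by angle (radians)
rotate_about_axis <- function(v, axis, angle) {
  axis <- unit3(axis, "rotation axis")
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Mid-sagittal plane through three skull-base landmarks
#'
#' The mid-sagittal plane passes through Sella, Nasion and Basion. Its normal
#' is oriented toward the subject's left, which in LPS world coordinates with
#' the usual anatomical arrangement (Nasion anterior to Sella, Basion
#' posterior-inferior) is the direction of `(N - S) x (Ba - S)`.
#'
#' @param S,N,Ba length-3 landmark positions (mm, LPS world coordinates).
#' @return A [plane3()] labelled `"midsagittal"`.
#' @export
midsagittal_plane <- function(S, N, Ba) {
  S <- as.numeric(S); N <- as.numeric(N); Ba <- as.numeric(Ba)
  n <- cross3(N - S, Ba - S)
  if (sqrt(sum(n^2)) < 1e-9 * max(1, sqrt(sum((N - S)^2)) * sqrt(sum((Ba - S)^2)))) {
    stop("degenerate geometry: S, N, Ba are collinear", call. = FALSE)
  }
  plane3(n, S, label = "midsagittal")
}

#' Plane through two points, perpendicular to a reference plane
#'
#' Constructs the plane that contains `p` and `q` and is perpendicular to
#' `ref` (i.e. contains a direction parallel to `ref`'s normal). This is the
#' construction of the Condylion-Gonion plane: the 2D ramus line swept
#' laterally, perpendicular to the mid-sagittal plane.
#'
#' @param p,q length-3 points (mm); must be distinct and `q - p` must not be
#'   parallel to `ref$normal`.
#' @param ref reference [plane3()].
#' @param orient optional length-3 vector; the returned normal is flipped to
#'   have a positive dot product with it (deterministic half-space labels).
#' @param label optional plane label.
#' @return A [plane3()] through `p` and `q`, perpendicular to `ref`.
#' @export
plane_through_two_points_normal_to <- function(p, q, ref, orient = NULL,
                                               label = NULL) {
  stopifnot(inherits(ref, "plane3"))
  p <- as.numeric(p); q <- as.numeric(q)
  d <- q - p
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("degenerate geometry: coincident points", call. = FALSE)
  n <- cross3(d / nd, ref$normal)
  if (sqrt(sum(n^2)) < 1e-9) {
    stop("degenerate geometry: segment parallel to the reference normal",
         call. = FALSE)
  }
  n <- unit3(n)
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  plane3(n, p, label = label)
}

#' Plane through three points
#'
#' @param a,b,c length-3 non-collinear points (mm).
#' @param orient optional length-3 vector fixing the normal orientation (the
#'   normal is flipped to have positive dot product with it), so that any
#'   permutation of the three points yields the identical plane object.
#' @param label optional plane label.
#' @return A [plane3()] containing the three points.
#' @export
plane_through_three_points <- function(a, b, c, orient = NULL, label = NULL) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  n <- cross3(b - a, c - a)
  if (sqrt(sum(n^2)) < 1e-9 * max(1, sqrt(sum((b - a)^2)) * sqrt(sum((c - a)^2)))) {
    stop("degenerate geometry: collinear points", call. = FALSE)
  }
  n <- unit3(n)
  if (!is.null(orient)) {
    if (sum(n * orient) < 0) n <- -n
  } else {
    # canonical orientation: first nonzero component positive
    i <- which(abs(n) > 1e-12)[1]
    if (n[i] < 0) n <- -n
  }
  plane3(n, a, label = label)
}

#' Plane through a point, parallel to a reference plane
#'
#' @param p length-3 point (mm).
#' @param ref reference [plane3()]; the returned plane shares its normal.
#' @param label optional plane label.
#' @return A [plane3()] through `p` with normal `ref$normal`.
#' @export
plane_through_point_parallel_to <- function(p, ref, label = NULL) {
  stopifnot(inherits(ref, "plane3"))
  plane3(ref$normal, as.numeric(p), label = label)
}

#' Bisecting plane of two planes through a shared anchor point
#'
#' Returns the plane through `anchor` whose normal is the normalised sum of
#' the two parent normals after orienting them to agree (non-negative mutual
#' dot product). The result makes equal dihedral angles with both parents.
#' The anchor must lie on both parents (it is the Gonion, shared by
#' construction of the ramus and mandibular-base planes).
#'
#' Two intersecting planes admit two bisecting planes (one per pair of
#' vertical dihedral sectors); both make equal dihedral angles with the
#' parents. By default the normal is `normalize(n1 + n2)` after orienting the
#' parent normals to agree. When `orient_point` and `separate_point` are both
#' given, the bisector that puts the two points on opposite sides is chosen
#' instead -- for the mandibular-angle plane these are Condylion and Menton,
#' which selects the plane through the gonial-angle bisector line.
#'
#' @param p1,p2 parent [plane3()] objects; must not be parallel unless equal.
#' @param anchor length-3 point on both planes (tolerance 1e-3 mm; landmarks
#'   are digitised at ~0.4 mm voxel resolution).
#' @param orient optional length-3 vector fixing the returned normal's
#'   orientation.
#' @param orient_point optional point given a positive signed distance by the
#'   returned plane (used to keep Condylion on the positive side).
#' @param separate_point optional point forced to the negative side; selects
#'   between the two bisectors (see Details).
#' @param label optional plane label.
#' @return A [plane3()] bisecting the dihedral angle between `p1` and `p2`.
#' @export
bisecting_plane <- function(p1, p2, anchor, orient = NULL, orient_point = NULL,
                            separate_point = NULL, label = NULL) {
  stopifnot(inherits(p1, "plane3"), inherits(p2, "plane3"))
  anchor <- as.numeric(anchor)
  if (abs(signed_distance(p1, anchor)) > 1e-3 ||
      abs(signed_distance(p2, anchor)) > 1e-3) {
    stop("anchor point does not lie on both parent planes (tolerance 1e-3 mm)",
         call. = FALSE)
  }
  n1 <- p1$normal
  n2 <- p2$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  cands <- list(n1 + n2)
  if (!is.null(separate_point) && !is.null(orient_point)) {
    cands <- list(n1 + n2, n1 - n2)
  }
  out <- NULL
  for (n in cands) {
    if (sqrt(sum(n^2)) < 1e-9) next
    cand <- plane3(n, anchor, label = label)
    if (!is.null(separate_point) && !is.null(orient_point)) {
      ds <- signed_distance(cand, orient_point) *
        signed_distance(cand, separate_point)
      if (ds < 0) { out <- cand; break }
    } else {
      out <- cand
      break
    }
  }
  if (is.null(out)) {
    stop(if (length(cands) == 1L)
      "degenerate geometry: parent planes are anti-parallel"
      else "no bisecting plane separates the two reference points",
      call. = FALSE)
  }
  if (!is.null(orient) && sum(out$normal * orient) < 0) {
    out <- plane3(-out$normal, anchor, label = label)
  }
  if (!is.null(orient_point) && signed_distance(out, orient_point) < 0) {
    out <- plane3(-out$normal, anchor, label = label)
  }
  out
}

#' Dihedral angle between two planes
#'
#' @param p1,p2 [plane3()] objects.
#' @return Angle in radians in `[0, pi/2]` (orientation-independent).
#' @export
plane_angle <- function(p1, p2) {
  acos(pmin(1, abs(sum(p1$normal * p2$normal))))
}

# apply a rigid transform (3x3 rotation R, translation t) to a plane:
# points map p -> R p + t, so normals rotate and offsets pick up (R n) . t
transform_plane <- function(plane, R, t, label = plane$label) {
  n <- drop(R %*% plane$normal)
  plane3(n, plane$offset + sum(n * t), label = label)
}
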