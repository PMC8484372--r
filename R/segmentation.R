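# Plane-based voxel partition of a mandible mask: thresholding, cavity
# filling, crown removal, per-voxel classification and the condyle/coronoid
# split.
#
# Tie rules (fixed so the brute-force voxel oracle can match exactly):
# voxels are classified at their centre point; "above" the C-point plane
# means strictly positive signed distance; distance-zero ties fall to the
# lower label, except the median-plane tie which goes Left.

#' Threshold a grayscale volume to a binary mask
#'
#' @param volume a [vol3d()] with numeric values.
#' @param lower,upper inclusive intensity window; voxels with
#'   `lower <= value <= upper` become foreground.
#' @return A binary [vol3d()]; warns (does not fail) if the mask is empty.
#' @export
threshold_mask <- function(volume, lower, upper = Inf) {
  stopifnot(inherits(volume, "vol3d"), lower <= upper)
  m <- volume$values >= lower & volume$values <= upper
  if (!any(m)) warning("threshold window produced an empty mask")
  vol3d(m, volume$spacing, volume$origin, volume$direction)
}

#' Fill internal cavities of a binary mask
#'
#' Converts every background component that is not 6-connected to the grid
#' boundary into foreground (foreground connectivity is 26, background 6 --
#' the standard duality). An optional morphological closing (ellipsoidal
#' structuring element of the given radius, spacing-aware) is applied first
#' to seal openings such as the mental foramina of the mandibular canal,
#' which a pure hole fill cannot close.
#'
#' @param mask a binary [vol3d()] with at least one foreground voxel.
#' @param closing_radius_mm radius (mm) of the closing element; `0` skips the
#'   closing and fills only fully enclosed cavities.
#' @return A binary [vol3d()] with internal cavities filled.
#' @export
fill_internal_cavities <- function(mask, closing_radius_mm = 1.0) {
  stopifnot(inherits(mask, "vol3d"), is.logical(mask$values))
  if (!any(mask$values)) stop("empty mask", call. = FALSE)
  m <- mask$values
  d <- dim(m)
  if (closing_radius_mm > 0) {
    r <- closing_radius_mm / mask$spacing
    dil <- array(dilate_ellipsoid_3d(as.vector(m), d, r), dim = d)
    # erosion as the complement of dilating the complement
    m <- !array(dilate_ellipsoid_3d(as.vector(!dil), d, r), dim = d)
  }
  reach <- bg_reachable_from_boundary(as.vector(m), d)
  filled <- m | !array(reach, dim = d)
  vol3d(mask$values | filled, mask$spacing, mask$origin, mask$direction)
}

#' Remove clinical tooth crowns by clipping plane(s)
#'
#' Removes foreground voxels with strictly positive signed distance to the
#' clip plane (whose normal must point occlusally, toward the crowns).
#' Voxels exactly on the plane are retained. With a per-side plane pair, the
#' side of each voxel is decided by the median plane (Left on ties).
#'
#' @param mask a binary [vol3d()].
#' @param crown_clip a [plane3()], or a list `list(L = , R = )` of planes.
#' @param median the median [plane3()]; required when `crown_clip` is a pair.
#' @return A binary [vol3d()]; warns if more than half the mask is removed
#'   (an implausible alveolar plane).
#' @export
remove_crowns <- function(mask, crown_clip, median = NULL) {
  stopifnot(inherits(mask, "vol3d"), is.logical(mask$values))
  idx <- which(mask$values)
  if (!length(idx)) return(mask)
  pts <- voxel_centers(mask, idx)
  if (inherits(crown_clip, "plane3")) {
    remove <- signed_distance(crown_clip, pts) > 0
  } else {
    stopifnot(is.list(crown_clip), all(c("L", "R") %in% names(crown_clip)))
    if (is.null(median)) {
      stop("per-side crown clipping requires the median plane", call. = FALSE)
    }
    isL <- signed_distance(median, pts) >= 0
    remove <- logical(length(idx))
    remove[isL] <- signed_distance(crown_clip$L, pts[isL, , drop = FALSE]) > 0
    remove[!isL] <- signed_distance(crown_clip$R, pts[!isL, , drop = FALSE]) > 0
  }
  if (sum(remove) > length(idx) / 2) {
    warning("crown clipping removed more than half of the mask; ",
            "check the alveolar plane orientation")
  }
  out <- mask$values
  out[idx[remove]] <- FALSE
  vol3d(out, mask$spacing, mask$origin, mask$direction)
}

#' Classify points against the mandibular cutting planes
#'
#' Pure deterministic function of coordinates. Side is Left when the signed
#' distance to the (shared) median plane is `>= 0` (its normal points left);
#' with that side's planes, a point is a condyle candidate when strictly
#' above the C-point plane, else ramus when strictly on the Condylion side of
#' the mandibular-angle plane, else hemibody. Condyle candidates are later
#' split into condyle and coronoid by connected components
#' ([split_coronoid()]).
#'
#' @param points length-3 point or `n x 3` matrix (mm).
#' @param planes_L,planes_R [build_mandibular_planes()] results; they must
#'   share the median plane.
#' @return Character vector of labels: `condyle_candidate_L/R`, `ramus_L/R`,
#'   `hemibody_L/R`.
#' @export
classify_point <- function(points, planes_L, planes_R) {
  stopifnot(inherits(planes_L, "segment_planes"),
            inherits(planes_R, "segment_planes"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  isL <- signed_distance(planes_L$median, points) >= 0
  lab <- character(nrow(points))
  for (s in c("L", "R")) {
    pl <- if (s == "L") planes_L else planes_R
    sel <- if (s == "L") isL else !isL
    if (!any(sel)) next
    p <- points[sel, , drop = FALSE]
    above <- signed_distance(pl$c_point, p) > 0
    ramus <- !above & signed_distance(pl$mandibular_angle, p) > 0
    l <- rep(paste0("hemibody_", s), nrow(p))
    l[above] <- paste0("condyle_candidate_", s)
    l[ramus] <- paste0("ramus_", s)
    lab[sel] <- l
  }
  lab
}

#' Split the supra-notch mask into condyle and coronoid
#'
#' Computes 26-connected components of the above-C-point-plane mask; the
#' component containing (or, if Condylion's voxel is background, nearest to)
#' Condylion is the condyle, all other components are the coronoid process.
#' When only one component exists everything is assigned to the condyle --
#' indistinguishable from a condyle/coronoid fusion, which is why the
#' phantom keeps a sigmoid-notch gap between the two.
#'
#' @param mask_above_cpoint binary [vol3d()] of the foreground strictly above
#'   the C-point plane (one side only).
#' @param condylion length-3 Condylion position (mm); should lie inside or
#'   within ~2 voxels of a foreground component.
#' @return `list(condyle = , coronoid = )` of binary [vol3d()] volumes; warns
#'   and returns empty volumes if there is no foreground above the plane.
#' @export
split_coronoid <- function(mask_above_cpoint, condylion) {
  stopifnot(inherits(mask_above_cpoint, "vol3d"),
            is.logical(mask_above_cpoint$values))
  m <- mask_above_cpoint$values
  d <- dim(m)
  mk <- function(v) vol3d(v, mask_above_cpoint$spacing,
                          mask_above_cpoint$origin,
                          mask_above_cpoint$direction)
  if (!any(m)) {
    warning("no foreground above the C-point plane")
    return(list(condyle = mk(array(FALSE, d)), coronoid = mk(array(FALSE, d))))
  }
  labels <- array(cc_label_3d(as.vector(m), d, 26L), dim = d)
  ijk <- world_to_index(mask_above_cpoint, condylion)
  lab_co <- 0L
  if (all(ijk >= 1L) && all(ijk <= d)) lab_co <- labels[ijk[1], ijk[2], ijk[3]]
  if (lab_co == 0L) {
    # nearest labelled voxel to Condylion
    idx <- which(m)
    pts <- voxel_centers(mask_above_cpoint, idx)
    d2 <- rowSums(sweep(pts, 2, as.numeric(condylion), "-")^2)
    lab_co <- labels[idx[which.min(d2)]]
  }
  list(condyle = mk(labels == lab_co),
       coronoid = mk(labels != 0L & labels != lab_co))
}

#' Partition a mandible mask into labelled segments
#'
#' Classifies every foreground voxel at its centre point with
#' [classify_point()] and refines the supra-notch condyle candidates with
#' [split_coronoid()] per side. The mask should already be cavity-filled and
#' crown-clipped. Label counts conserve the input foreground count exactly.
#'
#' @param mask a binary [vol3d()].
#' @param planes_L,planes_R [build_mandibular_planes()] results.
#' @param landmarks the [landmark_set()] (Condylion positions seed the
#'   condyle/coronoid split).
#' @return A [label_map()].
#' @export
partition_mandible <- function(mask, planes_L, planes_R, landmarks) {
  stopifnot(inherits(mask, "vol3d"), is.logical(mask$values))
  d <- dim(mask$values)
  idx <- which(mask$values)
  codes <- segment_labels()
  out <- array(0L, d)
  if (!length(idx)) {
    return(label_map(out, mask$spacing, mask$origin, mask$direction))
  }
  pts <- voxel_centers(mask, idx)
  lab <- classify_point(pts, planes_L, planes_R)
  for (s in c("L", "R")) {
    for (seg in c("ramus", "hemibody")) {
      key <- paste0(seg, "_", s)
      out[idx[lab == key]] <- codes[[key]]
    }
    cand <- idx[lab == paste0("condyle_candidate_", s)]
    if (!length(cand)) next
    sub <- array(FALSE, d)
    sub[cand] <- TRUE
    parts <- split_coronoid(
      vol3d(sub, mask$spacing, mask$origin, mask$direction),
      lm_pos(landmarks, paste0("Co_", s)))
    out[which(parts$condyle$values)] <- codes[[paste0("condyle_", s)]]
    out[which(parts$coronoid$values)] <- codes[[paste0("coronoid_", s)]]
  }
  label_map(out, mask$spacing, mask$origin, mask$direction)
}
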