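# 3D image grids with world-coordinate metadata (mm, LPS), NIfTI I/O,
# label maps and per-segment volume accounting.
#
# Grid convention: 0-based voxel indices; world = origin + direction %*%
# (index * spacing). Direction is a 3x3 orthonormal matrix (identity for all
# volumes this package creates).

#' 3D volume with grid metadata
#'
#' @param values 3D array (numeric or logical).
#' @param spacing length-3 voxel spacing in mm (strictly positive), or a
#'   scalar for isotropic grids.
#' @param origin length-3 world position (mm) of the centre of voxel
#'   `(0, 0, 0)`.
#' @param direction 3 x 3 orthonormal direction matrix (columns are the world
#'   directions of the voxel axes).
#' @return An object of class `vol3d` (also `binvol` if `values` is logical).
#' @export
vol3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                  direction = diag(3)) {
  stopifnot(length(dim(values)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)),
            all(dim(direction) == c(3L, 3L)))
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction matrix must be orthonormal", call. = FALSE)
  }
  cls <- c(if (is.logical(values)) "binvol", "vol3d")
  structure(list(values = values, spacing = spacing, origin = origin,
                 direction = direction),
            class = cls)
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  if (is.logical(x$values)) {
    cat(sprintf("  foreground voxels: %d (%.1f mm^3)\n", sum(x$values),
                sum(x$values) * prod(x$spacing)))
  }
  invisible(x)
}

#' Voxel volume of a grid, mm^3
#' @param vol a [vol3d()].
#' @return Scalar voxel volume (product of spacings).
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

# world coordinates (n x 3) of voxel centres for 1-based linear indices
voxel_centers <- function(vol, linear_idx) {
  d <- dim(vol$values)
  i0 <- linear_idx - 1L
  x <- i0 %% d[1]
  rest <- i0 %/% d[1]
  y <- rest %% d[2]
  z <- rest %/% d[2]
  ijk <- cbind(x, y, z)
  sweep(ijk %*% (t(vol$direction) * vol$spacing), 2, vol$origin, "+")
}

# nearest voxel (1-based i,j,k) for a world point; NULL metadata checks kept
# minimal because phantom and pipeline grids are axis-aligned
world_to_index <- function(vol, point) {
  rel <- drop(t(vol$direction) %*% (as.numeric(point) - vol$origin)) / vol$spacing
  as.integer(round(rel)) + 1L
}

#' Read a NIfTI volume
#'
#' Reads `.nii`/`.nii.gz` via RNifti and converts the stored RAS affine to
#' the package's LPS world convention (x and y negated).
#'
#' @param path path to a NIfTI file.
#' @param binary logical; coerce values to a binary mask (`values != 0`).
#' @return A [vol3d()].
#' @export
read_volume <- function(path, binary = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)      # voxel (0-based) -> RAS world
  aff[1:2, ] <- -aff[1:2, ]      # RAS -> LPS
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  direction <- sweep(aff[1:3, 1:3], 2, spacing, "/")
  vals <- array(as.vector(img), dim = dim(img))
  if (binary) vals <- vals != 0
  vol3d(vals, spacing = spacing, origin = aff[1:3, 4], direction = direction)
}

#' Write a volume to NIfTI
#'
#' Writes through RNifti, converting the package's LPS metadata to the RAS
#' affine NIfTI stores. Logical masks and label arrays are written as uint8.
#'
#' @param vol a [vol3d()] or [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  datatype <- "auto"
  if (is.logical(vals)) {
    vals <- array(as.integer(vals), dim = dim(vals))
    datatype <- "uint8"
  } else if (is.integer(vals) && max(abs(range(vals))) < 256) {
    datatype <- "uint8"
  }
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  aff[1:2, ] <- -aff[1:2, ]      # LPS -> RAS
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Segment label vocabulary
#'
#' Integer codes of the label map: 0 background, then condyle, coronoid,
#' ramus and hemibody per side.
#'
#' @return Named integer vector of label codes.
#' @export
segment_labels <- function() {
  c(background = 0L,
    condyle_L = 1L, condyle_R = 2L,
    coronoid_L = 3L, coronoid_R = 4L,
    ramus_L = 5L, ramus_R = 6L,
    hemibody_L = 7L, hemibody_R = 8L)
}

#' Label map
#'
#' A 3D integer grid assigning each foreground voxel exactly one segment
#' label from [segment_labels()].
#'
#' @param values 3D integer array of label codes.
#' @inheritParams vol3d
#' @return An object of class `label_map` (a [vol3d()] subclass).
#' @export
label_map <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(as.vector(values)), unname(segment_labels()))
  if (length(bad)) {
    stop("unknown label code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- vol3d(values, spacing, origin, direction)
  class(out) <- c("label_map", class(out))
  out
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<label_map> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- tabulate(x$values + 1L, nbins = 9L)
  lbl <- names(segment_labels())
  for (i in seq_along(lbl)) {
    if (tab[i] > 0) cat(sprintf("  %-10s %d voxels\n", lbl[i], tab[i]))
  }
  invisible(x)
}

#' Write a label map with a JSON sidecar naming the labels
#'
#' @param labels a [label_map()].
#' @param path output NIfTI path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  write_volume(labels, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(as.list(segment_labels()), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' Per-segment volumes from a label map
#'
#' Volume per label is the voxel count times the voxel volume. The
#' hemimandible of a side is defined as all foreground on that side of the
#' median plane, i.e. condyle + coronoid + ramus + hemibody (an exact
#' voxel-count identity), and the total mandible is the sum of the two
#' hemimandibles.
#'
#' @param labels a [label_map()].
#' @return An object of class `segment_volumes`: named volumes (mm^3), voxel
#'   counts and spacing.
#' @export
compute_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  counts <- tabulate(labels$values, nbins = 8L)
  names(counts) <- names(segment_labels())[-1]
  segment_volumes_from_counts(counts, voxel_volume(labels))
}

segment_volumes_from_counts <- function(counts, vox_mm3) {
  sides <- c("L", "R")
  segs <- c("condyle", "coronoid", "ramus", "hemibody")
  hemi <- vapply(sides, function(s) {
    sum(counts[paste0(segs, "_", s)])
  }, numeric(1))
  counts_all <- c(counts,
                  stats::setNames(hemi, paste0("hemimandible_", sides)))
  volumes <- counts_all * vox_mm3
  structure(list(volumes = volumes,
                 total_mandible = sum(hemi) * vox_mm3,
                 voxel_counts = counts_all,
                 voxel_volume = vox_mm3),
            class = "segment_volumes")
}

#' @export
print.segment_volumes <- function(x, ...) {
  cat("<segment_volumes> (mm^3)\n")
  segs <- c("condyle", "coronoid", "ramus", "hemibody", "hemimandible")
  m <- sapply(c("L", "R"), function(s) x$volumes[paste0(segs, "_", s)])
  rownames(m) <- segs
  print(round(m, 2))
  cat(sprintf("  total mandible: %.2f mm^3\n", x$total_mandible))
  invisible(x)
}

#' @export
as.data.frame.segment_volumes <- function(x, ...) {
  nm <- names(x$volumes)
  side <- sub("^.*_", "", nm)
  segment <- sub("_[LR]$", "", nm)
  rbind(
    data.frame(side = side, segment = segment,
               volume_mm3 = unname(x$volumes),
               voxel_count = unname(x$voxel_counts)),
    data.frame(side = "both", segment = "total_mandible",
               volume_mm3 = x$total_mandible,
               voxel_count = sum(x$voxel_counts[paste0("hemimandible_",
                                                       c("L", "R"))]))
  )
}

#' Write segment volumes as CSV and/or JSON
#'
#' @param x a `segment_volumes` object.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return Invisibly, the data frame written.
#' @export
write_segment_volumes <- function(x, csv = NULL, json = NULL) {
  df <- as.data.frame(x)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(volumes_mm3 = as.list(x$volumes),
                              total_mandible_mm3 = x$total_mandible,
                              voxel_volume_mm3 = x$voxel_volume),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
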