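# Named anatomical landmarks, mm, LPS world coordinates.

#' Landmark vocabulary
#'
#' The twelve landmark names used by the partition: six midline/skull-base
#' points (Sella `S`, Nasion `N`, Basion `Ba`, Menton `Me`, Down's B point
#' `Bpt`, mental-spine point `MSp`) and three per side (Condylion `Co`,
#' Gonion `Go`, sigmoid-notch C-point `Cp`, suffixed `_L`/`_R`).
#'
#' @return Character vector of the 12 landmark names.
#' @export
landmark_names <- function() {
  c("S", "N", "Ba", "Me", "Bpt", "MSp",
    "Co_L", "Co_R", "Go_L", "Go_R", "Cp_L", "Cp_R")
}

#' Landmark set
#'
#' A complete set of the twelve named 3D landmarks, stored as a 12 x 3 matrix
#' (rows named by landmark, columns x/y/z in mm, LPS world coordinates).
#' Validation enforces: all names present and finite, no two landmarks
#' coincident, S/N/Ba non-collinear (they define the mid-sagittal plane) and
#' Go_L/Go_R/Me non-collinear (they define the mandibular-base plane).
#'
#' @param positions named list of length-3 numeric vectors, or a 12 x 3
#'   matrix with rownames, covering [landmark_names()].
#' @return An object of class `landmark_set` (a 12 x 3 numeric matrix).
#' @export
landmark_set <- function(positions) {
  nm <- landmark_names()
  if (is.list(positions)) {
    missing <- setdiff(nm, names(positions))
    if (length(missing)) {
      stop("missing landmark(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- do.call(rbind, lapply(positions[nm], as.numeric))
  } else {
    m <- as.matrix(positions)
    missing <- setdiff(nm, rownames(m))
    if (length(missing)) {
      stop("missing landmark(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[nm, , drop = FALSE]
  }
  if (ncol(m) != 3L || !all(is.finite(m))) {
    stop("landmark positions must be finite 3-vectors", call. = FALSE)
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(nm, c("x", "y", "z"))
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  if (any(d < 1e-6)) {
    pair <- which(d < 1e-6, arr.ind = TRUE)[1, ]
    stop("coincident landmarks: ", nm[pair[1]], " and ", nm[pair[2]],
         call. = FALSE)
  }
  chk_collinear <- function(a, b, c, what) {
    v <- cross3(m[b, ] - m[a, ], m[c, ] - m[a, ])
    if (sqrt(sum(v^2)) <
        1e-9 * max(1, sqrt(sum((m[b, ] - m[a, ])^2)) *
                      sqrt(sum((m[c, ] - m[a, ])^2)))) {
      stop("degenerate geometry: ", what, " are collinear", call. = FALSE)
    }
  }
  chk_collinear("S", "N", "Ba", "S, N, Ba")
  chk_collinear("Go_L", "Go_R", "Me", "Go_L, Go_R, Me")
  structure(m, class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> 12 landmarks (mm, LPS)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

lm_pos <- function(landmarks, name) as.numeric(unclass(landmarks)[name, ])

#' Apply a rigid (or affine) transform to a landmark set
#'
#' @param landmarks a [landmark_set()].
#' @param R 3 x 3 rotation (or orthogonal) matrix.
#' @param t length-3 translation vector (mm).
#' @return Transformed [landmark_set()] (positions mapped `p -> R p + t`).
#' @export
transform_landmarks <- function(landmarks, R = diag(3), t = c(0, 0, 0)) {
  m <- unclass(landmarks)[, , drop = FALSE]
  m2 <- t(R %*% t(m)) + matrix(t, nrow(m), 3, byrow = TRUE)
  rownames(m2) <- rownames(m)
  landmark_set(m2)
}

#' Swap left and right landmark names
#'
#' Used when reflecting a subject across the mid-sagittal plane: positions
#' are reflected by the caller; this renames `*_L` to `*_R` and vice versa.
#'
#' @param landmarks a [landmark_set()].
#' @return A [landmark_set()] with sided names exchanged.
#' @export
swap_landmark_sides <- function(landmarks) {
  m <- unclass(landmarks)
  nm <- rownames(m)
  swapped <- sub("_L$", "_XX", nm)
  swapped <- sub("_R$", "_L", swapped)
  swapped <- sub("_XX$", "_R", swapped)
  rownames(m) <- swapped
  landmark_set(m)
}

#' Jitter landmarks with isotropic Gaussian noise
#'
#' Emulates re-digitisation of the landmark set by a (second) observer, for
#' intra-/inter-observer reliability simulation: each coordinate of each
#' landmark receives independent N(0, sigma^2) noise.
#'
#' @param landmarks a [landmark_set()].
#' @param sigma_mm standard deviation of the jitter per axis (mm, >= 0);
#'   `0` returns the input unchanged.
#' @param seed integer seed; the jitter is deterministic given the seed.
#' @return A perturbed [landmark_set()].
#' @export
perturb_landmarks <- function(landmarks, sigma_mm, seed = NULL) {
  stopifnot(sigma_mm >= 0)
  m <- unclass(landmarks)
  if (sigma_mm == 0) return(landmark_set(m))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  landmark_set(m + matrix(stats::rnorm(length(m), 0, sigma_mm), nrow(m), 3))
}

#' Read landmarks from JSON
#'
#' Expects `{"landmarks": [{"name": "...", "position_mm": [x, y, z]}, ...]}`.
#' Coordinates are LPS millimetres; set `ras = TRUE` if the file stores RAS
#' coordinates (x and y are negated on read).
#'
#' @param path path to a JSON landmark file.
#' @param ras logical; convert RAS input to LPS.
#' @return A [landmark_set()].
#' @export
read_landmarks_json <- function(path, ras = FALSE) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$landmarks)) stop("no 'landmarks' field in ", path, call. = FALSE)
  lm <- j$landmarks
  pos <- do.call(rbind, lapply(lm$position_mm, as.numeric))
  rownames(pos) <- lm$name
  if (ras) pos[, 1:2] <- -pos[, 1:2]
  landmark_set(pos)
}

#' Write landmarks to JSON
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(landmarks, path) {
  m <- unclass(landmarks)
  obj <- list(landmarks = data.frame(name = rownames(m)))
  obj$landmarks$position_mm <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from a Slicer markup fiducial file (.fcsv)
#'
#' Parses the comma-separated Slicer fiducial dialect (comment lines starting
#' with `#`, columns `id,x,y,z,...,label`). Slicer stores RAS coordinates by
#' default; they are converted to LPS unless `ras = FALSE`-style input is
#' declared via `coordinate_system = "LPS"` (also auto-detected from the
#' `# CoordinateSystem` header when present).
#'
#' @param path path to a `.fcsv` file.
#' @param name_map optional named character vector mapping fiducial labels in
#'   the file to [landmark_names()] tokens (e.g. `c(Condylion_left = "Co_L")`).
#' @param coordinate_system `"auto"` (default, from header, falling back to
#'   RAS as Slicer writes), `"RAS"` or `"LPS"`.
#' @return A [landmark_set()].
#' @export
read_landmarks_fcsv <- function(path, name_map = NULL,
                                coordinate_system = c("auto", "RAS", "LPS")) {
  coordinate_system <- match.arg(coordinate_system)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  if (!length(body)) stop("no fiducial rows in ", path, call. = FALSE)
  if (coordinate_system == "auto") {
    cs <- grep("CoordinateSystem", header, value = TRUE)
    coordinate_system <-
      if (length(cs) && grepl("LPS|0\\s*$", cs[1])) "LPS" else "RAS"
  }
  rows <- utils::read.csv(text = body, header = FALSE,
                          stringsAsFactors = FALSE)
  # Slicer fcsv: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,assoc
  if (ncol(rows) < 12L) stop("unexpected .fcsv column count", call. = FALSE)
  pos <- as.matrix(rows[, 2:4])
  storage.mode(pos) <- "double"
  labels <- trimws(as.character(rows[[12]]))
  if (!is.null(name_map)) {
    mapped <- name_map[labels]
    labels[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  rownames(pos) <- labels
  if (coordinate_system == "RAS") pos[, 1:2] <- -pos[, 1:2]
  landmark_set(pos)
}
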