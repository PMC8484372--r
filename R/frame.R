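# Cephalometric reference frame (Swennen-style) and the five mandibular
# cutting planes.

#' Build the 3D cephalometric reference frame
#'
#' The frame is anchored at Sella. The mid-sagittal plane passes through
#' Sella, Nasion and Basion, its normal oriented toward the subject's left.
#' The horizontal (x) plane passes through Sella and is obtained by tilting
#' the plane through Sella and Nasion (normal to the mid-sagittal plane) six
#' degrees downward at its anterior (Nasion) end. The vertical (y) plane
#' passes through Sella normal to the horizontal plane (a coronal plane), and
#' the sagittal (z) plane through Sella normal to both, which coincides with
#' the mid-sagittal plane.
#'
#' @param landmarks a [landmark_set()].
#' @param tilt_deg tilt of the horizontal plane below the Sella-Nasion plane,
#'   degrees (default 6, the standard clinical correction that brings S-N
#'   close to a true horizontal).
#' @return An object of class `reference_frame`: origin (Sella), orthonormal
#'   right-handed axes `axis_anterior`, `axis_left`, `axis_superior`, and the
#'   three reference planes `horizontal`, `vertical`, `sagittal`.
#' @export
build_reference_frame <- function(landmarks, tilt_deg = 6) {
  S <- lm_pos(landmarks, "S")
  N <- lm_pos(landmarks, "N")
  Ba <- lm_pos(landmarks, "Ba")
  sag <- midsagittal_plane(S, N, Ba)
  axis_left <- sag$normal
  # plane through S and N, normal to the mid-sagittal plane: its normal is
  # perpendicular to both S->N and the left axis, pointing superior-ish
  n0 <- unit3(cross3(N - S, axis_left), "S-N plane normal")
  # tilt: anterior (Nasion) end rotates inferiorly, i.e. the normal rotates
  # by +tilt about the left axis (right-hand rule: posterior -> superior)
  axis_superior <- rotate_about_axis(n0, axis_left, tilt_deg * pi / 180)
  axis_anterior <- cross3(axis_left, axis_superior)
  structure(list(
    origin = S,
    axis_anterior = axis_anterior,
    axis_left = axis_left,
    axis_superior = axis_superior,
    horizontal = plane3(axis_superior, S, label = "horizontal"),
    vertical = plane3(axis_anterior, S, label = "vertical"),
    sagittal = plane3(axis_left, S, label = "sagittal"),
    tilt_deg = tilt_deg
  ), class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame> origin (Sella):",
      sprintf("(%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (a in c("axis_anterior", "axis_left", "axis_superior")) {
    cat(sprintf("  %-14s (%.6f, %.6f, %.6f)\n", a,
                x[[a]][1], x[[a]][2], x[[a]][3]))
  }
  cat(sprintf("  horizontal tilt below S-N: %g deg\n", x$tilt_deg))
  invisible(x)
}

#' Build the five mandibular cutting planes for one side
#'
#' Constructs, from the landmark set and reference frame:
#' \describe{
#'   \item{condylion_gonion}{through Condylion and Gonion of `side`,
#'     perpendicular to the mid-sagittal plane (the 2D ramus line swept
#'     laterally); normal oriented anterior-superior.}
#'   \item{c_point}{through the C-point of `side`, parallel to the horizontal
#'     reference plane; normal is the superior axis. Everything strictly
#'     above it is condyle or coronoid.}
#'   \item{gonion_menton}{through both Gonions and Menton (the mandibular
#'     base); normal oriented superior. Shared across sides.}
#'   \item{median}{through Menton, Down's B point and the mental-spine point;
#'     normal oriented toward the left. Shared across sides; splits the
#'     mandible into hemimandibles.}
#'   \item{mandibular_angle}{bisector of the condylion_gonion and
#'     gonion_menton planes through the Gonion of `side`; normal oriented so
#'     Condylion has positive signed distance. Splits ramus from hemibody.}
#' }
#'
#' @param landmarks a [landmark_set()].
#' @param frame a [build_reference_frame()] result.
#' @param side `"L"` or `"R"`.
#' @param bisector_parents which pair of planes the mandibular-angle plane
#'   bisects: `"ramus_base"` (default; Condylion-Gonion and Gonion-Menton) or
#'   `"ramus_cpoint"` (Condylion-Gonion and C-point, the literal reading of
#'   "planes 1 and 2").
#' @return An object of class `segment_planes`.
#' @export
build_mandibular_planes <- function(landmarks, frame, side = c("L", "R"),
                                    bisector_parents = c("ramus_base",
                                                         "ramus_cpoint")) {
  side <- match.arg(side)
  bisector_parents <- match.arg(bisector_parents)
  stopifnot(inherits(frame, "reference_frame"))
  Co <- lm_pos(landmarks, paste0("Co_", side))
  Go <- lm_pos(landmarks, paste0("Go_", side))
  Cp <- lm_pos(landmarks, paste0("Cp_", side))
  Me <- lm_pos(landmarks, "Me")
  Bpt <- lm_pos(landmarks, "Bpt")
  MSp <- lm_pos(landmarks, "MSp")

  cg <- plane_through_two_points_normal_to(
    Co, Go, frame$sagittal,
    orient = frame$axis_anterior + frame$axis_superior,
    label = paste0("condylion_gonion_", side))
  cp <- plane_through_point_parallel_to(Cp, frame$horizontal,
                                        label = paste0("c_point_", side))
  gm <- plane_through_three_points(lm_pos(landmarks, "Go_L"),
                                   lm_pos(landmarks, "Go_R"), Me,
                                   orient = frame$axis_superior,
                                   label = "gonion_menton")
  md <- plane_through_three_points(Me, Bpt, MSp,
                                   orient = frame$axis_left,
                                   label = "median")
  # the bisector is anchored at the Gonion; for the literal "planes 1 and 2"
  # reading the C-point plane is first translated there (only its direction
  # enters the bisection)
  parent2 <- switch(bisector_parents,
                    ramus_base = gm,
                    ramus_cpoint = plane_through_point_parallel_to(Go, cp))
  ma <- bisecting_plane(cg, parent2, Go, orient_point = Co,
                        separate_point = Me,
                        label = paste0("mandibular_angle_", side))
  structure(list(side = side,
                 condylion_gonion = cg,
                 c_point = cp,
                 gonion_menton = gm,
                 median = md,
                 mandibular_angle = ma,
                 bisector_parents = bisector_parents),
            class = "segment_planes")
}

#' @export
print.segment_planes <- function(x, ...) {
  cat("<segment_planes> side", x$side, "\n")
  for (p in c("condylion_gonion", "c_point", "gonion_menton", "median",
              "mandibular_angle")) {
    cat("  "); print(x[[p]])
  }
  invisible(x)
}
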