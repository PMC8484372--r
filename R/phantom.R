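# Parametric mandible phantom: a constructive solid (U-shaped body, sheared
# rami, half-ellipsoid condyles sitting on the sigmoid-notch plane, coronoid
# blocks, tooth bumps, an internal canal void) rasterised on a regular grid,
# with analytically known landmarks and brute-force ground-truth segment
# volumes. Unilateral juvenile-arthritis-like damage is emulated by per-side
# condylar and ramal scale factors.
#
# Ground truth is computed by an independent per-voxel classifier written in
# this file (inline signed-distance arithmetic plus constructive-solid
# membership for the condyle/coronoid distinction); it never calls the
# segmentation module, so segmentation tests against it are not
# self-referential.

#' Phantom specification
#'
#' All lengths in mm. The defaults describe a juvenile-sized mandible whose
#' plane-defined segment volumes fall in the range reported for children and
#' adolescents (condyle-above-notch around 1.4 cm^3 per side). Default
#' boundary positions are chosen off the voxel lattice at the spacings used
#' in practice (0.8/0.4/0.2 mm) so that no voxel centre falls exactly on a
#' primitive boundary.
#'
#' @param spacing isotropic voxel spacing (mm); 0.4 matches typical CBCT.
#' @param intergonial_halfwidth half the distance between the gonia (mm).
#' @param body_length anteroposterior length of each lateral body bar (mm).
#' @param body_width width of the body band (mm).
#' @param body_height height of the body (inferior border to alveolar
#'   crest, mm); also the crown-clip level.
#' @param body_front_y anteroposterior position of the symphysis centreline.
#' @param ramus_height height of the sigmoid notch above the inferior
#'   border (mm); the C-point plane sits here (scaled by `s_ramus`).
#' @param ramus_width anteroposterior width of the ramus (mm).
#' @param ramus_thickness mediolateral thickness of the ramus (mm).
#' @param gonial_angle_deg gonial angle between the mandibular base and the
#'   ramus line, degrees, in (90, 180).
#' @param condyle_radii length-3 ellipsoid radii (x, y, z) of the condylar
#'   head-plus-neck unit (mm); the ellipsoid is centred on the notch plane so
#'   the condyle segment is exactly its upper half.
#' @param coronoid_thickness,coronoid_ap,coronoid_height coronoid block
#'   dimensions (mm).
#' @param notch_drop depth of the sigmoid-notch slot (mm): the ramus top
#'   (and the coronoid base) sit this far below the C-point plane, which
#'   keeps the condyle/coronoid component split stable when the plane is
#'   digitised slightly too low.
#' @param s_condyle,s_ramus named per-side scale factors in (0, 1]
#'   (`c(L = , R = )`); the condylar ellipsoid scales isotropically about its
#'   centre, the supra-body ramus height scales linearly.
#' @param n_teeth,tooth_radius,tooth_height clinical-crown pegs protruding
#'   anteriorly from the symphyseal face (count must be even; 0 disables).
#'   The crown-clip plane is the anterior alveolar face, so clipping removes
#'   exactly the protruding crown voxels and nothing else -- the phantom's
#'   abstraction of the per-tooth tailored cutting surfaces used clinically.
#' @param canal_radius radius of the internal canal void (mm; 0 disables).
#'   The void is fully enclosed, emulating the flood-filled mandibular canal.
#' @param intensity_fg,intensity_bg,noise_sd grayscale levels and Gaussian
#'   noise SD for the simulated image.
#' @param seed integer seed for the image noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 0.4,
                         intergonial_halfwidth = 40.1,
                         body_length = 40,
                         body_width = 10.3,
                         body_height = 18.3,
                         body_front_y = 20.15,
                         ramus_height = 42.35,
                         ramus_width = 27.2,
                         ramus_thickness = 10.3,
                         gonial_angle_deg = 120,
                         condyle_radii = c(6.45, 5.95, 18),
                         coronoid_thickness = 8.1,
                         coronoid_ap = 10,
                         coronoid_height = 12.4,
                         notch_drop = 2.05,
                         s_condyle = c(L = 1, R = 1),
                         s_ramus = c(L = 1, R = 1),
                         n_teeth = 8,
                         tooth_radius = 2.55,
                         tooth_height = 6.2,
                         canal_radius = 2.05,
                         intensity_fg = 1000,
                         intensity_bg = 0,
                         noise_sd = 50,
                         seed = 1) {
  s_condyle <- resolve_sides(s_condyle)
  s_ramus <- resolve_sides(s_ramus)
  spec <- list(spacing = spacing,
               intergonial_halfwidth = intergonial_halfwidth,
               body_length = body_length, body_width = body_width,
               body_height = body_height, body_front_y = body_front_y,
               ramus_height = ramus_height, ramus_width = ramus_width,
               ramus_thickness = ramus_thickness,
               gonial_angle_deg = gonial_angle_deg,
               condyle_radii = as.numeric(condyle_radii),
               coronoid_thickness = coronoid_thickness,
               coronoid_ap = coronoid_ap, coronoid_height = coronoid_height,
               notch_drop = notch_drop,
               s_condyle = s_condyle, s_ramus = s_ramus,
               n_teeth = as.integer(n_teeth), tooth_radius = tooth_radius,
               tooth_height = tooth_height, canal_radius = canal_radius,
               intensity_fg = intensity_fg, intensity_bg = intensity_bg,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

resolve_sides <- function(x) {
  if (length(x) == 1L) x <- c(L = unname(x), R = unname(x))
  stopifnot(all(c("L", "R") %in% names(x)))
  c(L = unname(x[["L"]]), R = unname(x[["R"]]))
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    lens <- c(spacing, intergonial_halfwidth, body_length, body_width,
              body_height, ramus_height, ramus_width, ramus_thickness,
              condyle_radii, coronoid_thickness, coronoid_ap, coronoid_height)
    if (!all(lens > 0)) stop("phantom lengths must be positive", call. = FALSE)
    if (gonial_angle_deg <= 90 || gonial_angle_deg >= 180) {
      stop("gonial angle must lie in (90, 180) degrees", call. = FALSE)
    }
    if (!all(c(s_condyle, s_ramus) > 0 & c(s_condyle, s_ramus) <= 1)) {
      stop("scale factors must lie in (0, 1]", call. = FALSE)
    }
    if (ramus_height <= body_height + 8) {
      stop("sigmoid notch must lie well above the body", call. = FALSE)
    }
    if (notch_drop <= 0 || notch_drop >= coronoid_height) {
      stop("notch_drop must lie in (0, coronoid_height)", call. = FALSE)
    }
    if (n_teeth %% 2L != 0L) stop("n_teeth must be even (symmetric rows)",
                                  call. = FALSE)
    if (n_teeth > 0L) {
      if (11.05 + tooth_radius >= body_height || 11.05 - tooth_radius <= 0) {
        stop("tooth pegs do not fit within the body height", call. = FALSE)
      }
      if (6.07 + 8 * (n_teeth / 2 - 1) + tooth_radius >= intergonial_halfwidth) {
        stop("tooth row too wide for the symphyseal face", call. = FALSE)
      }
    }
    # sigmoid-notch gap between coronoid and condylar ellipsoid
    gap <- ramus_width - 2 * condyle_radii[2] - coronoid_ap - 2.05
    if (gap < 1.7) {
      stop("sigmoid-notch gap too small (", round(gap, 2),
           " mm); enlarge ramus_width or shrink coronoid/condyle", call. = FALSE)
    }
  })
  invisible(spec)
}

# derived geometry: per-side notch heights, ramus borders, ellipsoid and
# coronoid placement, landmark positions, grid
phantom_geometry <- function(spec) {
  h <- spec$spacing
  xg <- spec$intergonial_halfwidth
  halfband <- spec$body_width / 2
  y_go <- spec$body_front_y + spec$body_length + halfband
  y_front_face <- spec$body_front_y - halfband
  tanp <- tan((spec$gonial_angle_deg - 90) * pi / 180)
  r <- spec$condyle_radii

  side <- function(s) {
    sc <- spec$s_condyle[[s]]
    sr <- spec$s_ramus[[s]]
    zn <- spec$body_height + (spec$ramus_height - spec$body_height) * sr
    yp <- y_go + tanp * zn          # posterior ramus border at the notch
    ya <- yp - spec$ramus_width     # anterior ramus border at the notch
    ye <- yp - (r[2] + 1)           # ellipsoid centre, anteroposterior
    cor_y0 <- ya + 1.05
    cor_y1 <- cor_y0 + spec$coronoid_ap
    # the sigmoid notch is a slot: the ramus top sits notch_drop below the
    # C-point plane, so a slightly mis-digitised (lower) plane still leaves
    # the condylar and coronoid components disconnected
    list(sx = if (s == "L") 1 else -1, sc = sc, sr = sr, zn = zn,
         z_ramus_top = zn - spec$notch_drop,
         yp = yp, ya = ya, ye = ye, cor_y0 = cor_y0, cor_y1 = cor_y1,
         cp_y = ye - r[2] * sc,
         co = c(if (s == "L") xg else -xg, ye, zn + r[3] * sc))
  }
  g <- list(h = h, xg = xg, halfband = halfband, y_go = y_go,
            y_front_face = y_front_face, tanp = tanp, r = r,
            L = side("L"), R = side("R"))

  zmax <- max(g$L$zn + max(r[3] * g$L$sc, spec$coronoid_height),
              g$R$zn + max(r[3] * g$R$sc, spec$coronoid_height)) + 2.5
  ymax <- max(g$L$yp, g$R$yp, g$L$ye + r[2], g$R$ye + r[2]) + 2.5
  xmax <- max(xg + spec$ramus_thickness / 2, xg + r[1]) + 2.5
  nx <- 2L * as.integer(ceiling(xmax / h))     # even: symmetric, no x = 0 centre
  g$nx <- nx
  g$xs <- h * (seq_len(nx) - 1 - (nx - 1) / 2) # exactly sign-symmetric centres
  ymin <- y_front_face - 2.0371 -
    (if (spec$n_teeth > 0L) spec$tooth_height else 0)
  g$origin <- c(g$xs[1], ymin, -2.0123)
  g$ys <- g$origin[2] + h * (seq_len(as.integer(ceiling((ymax - g$origin[2]) / h)) + 1L) - 1)
  g$zs <- g$origin[3] + h * (seq_len(as.integer(ceiling((zmax - g$origin[3]) / h)) + 1L) - 1)
  g$dim <- c(nx, length(g$ys), length(g$zs))

  # landmarks: skull-base triple placed so the frame's horizontal plane is a
  # true horizontal (S -> N elevated exactly 6 degrees), mandibular points on
  # the constructive solid
  S <- c(0, y_go - 15, zmax + 18)
  N <- S + 80 * c(0, -cos(6 * pi / 180), sin(6 * pi / 180))
  Ba <- S + c(0, 18, -32)
  g$landmarks <- landmark_set(list(
    S = S, N = N, Ba = Ba,
    Me = c(0, y_front_face, 0),
    Bpt = c(0, y_front_face, 8.3),
    MSp = c(0, spec$body_front_y + halfband, 6.2),
    Go_L = c(xg, y_go, 0), Go_R = c(-xg, y_go, 0),
    Cp_L = c(xg, g$L$cp_y, g$L$zn), Cp_R = c(-xg, g$R$cp_y, g$R$zn),
    Co_L = g$L$co, Co_R = g$R$co))
  g
}

# squared 2D distance to the U-shaped centreline (front bar + two side bars)
dist2_centerline <- function(X, Y, xg, yf, bar_len) {
  tx <- pmin(pmax(X, -xg), xg)
  d2 <- (X - tx)^2 + (Y - yf)^2
  cy <- pmin(pmax(Y, yf), yf + bar_len)
  d2 <- pmin(d2, (X - xg)^2 + (Y - cy)^2)
  pmin(d2, (X + xg)^2 + (Y - cy)^2)
}

# the two bisecting planes of the ramus line and the mandibular base through
# the Gonion; returns the one separating Condylion from Menton, oriented so
# Condylion is positive. Independent of the geometry module on purpose.
oracle_angle_plane <- function(Go, Co, Me, GoL, GoR) {
  u <- Co - Go
  n1 <- c(0, u[3], -u[2])                       # cross(u, (1,0,0))
  n1 <- n1 / sqrt(sum(n1^2))
  n3 <- cross3(GoR - GoL, Me - GoL)
  n3 <- n3 / sqrt(sum(n3^2))
  if (n3[3] < 0) n3 <- -n3
  if (sum(n1 * n3) < 0) n3 <- -n3
  for (cand in list(n1 + n3, n1 - n3)) {
    nc <- sqrt(sum(cand^2))
    if (nc < 1e-9) next
    n <- cand / nc
    off <- sum(n * Go)
    dc <- sum(n * Co) - off
    dm <- sum(n * Me) - off
    if (dc * dm < 0) {
      if (dc < 0) { n <- -n; off <- -off }
      return(list(normal = n, offset = off))
    }
  }
  stop("internal: no separating bisector found")
}

#' Generate a mandible phantom
#'
#' Rasterises the constructive solid at the spec's spacing, derives the
#' landmark set analytically from the construction, and computes ground-truth
#' segment volumes with the independent brute-force voxel classifier. The
#' output is deterministic given the spec (image noise uses the spec's seed).
#'
#' @param spec a [phantom_spec()].
#' @param image logical; also produce a noisy grayscale image (two-level
#'   foreground/background plus Gaussian noise). Disable for large grids
#'   when only the mask is needed.
#' @return An object of class `mandible_phantom` with elements `image`
#'   (or `NULL`), `mask` (binary volume including tooth crowns and the canal
#'   void), `solid` (the cavity-filled, crown-clipped reference solid),
#'   `landmarks`, `crown_clip` (a [plane3()]), `truth` (a `segment_volumes`),
#'   `truth_counts` and `spec`.
#' @export
generate_phantom <- function(spec, image = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  d <- g$dim
  h <- g$h
  r <- g$r

  X <- rep(g$xs, times = d[2])
  Y <- rep(g$ys, each = d[1])

  band2 <- g$halfband^2
  d2body <- dist2_centerline(X, Y, g$xg, spec$body_front_y, spec$body_length)
  in_body_xy <- d2body <= band2
  if (spec$canal_radius > 0) {
    d2canal <- dist2_centerline(X, Y, g$xg, spec$body_front_y,
                                spec$body_length - 4)
  }
  tooth_zc <- 11.05
  if (spec$n_teeth > 0L) {
    k <- spec$n_teeth / 2L
    xt <- 6.07 + 8 * (seq_len(k) - 1)
    xt <- c(-rev(xt), xt)
    # pegs run along -y from the symphyseal face; circular cross-section in
    # (x, z), so only the x-part is an xy-grid quantity
    d2teeth_x <- rep(Inf, length(X))
    for (x0 in xt) d2teeth_x <- pmin(d2teeth_x, (X - x0)^2)
    teeth_y <- Y >= g$y_front_face - spec$tooth_height &
      Y <= g$y_front_face + 0.55
  }

  sides <- list(L = g$L, R = g$R)
  per_side <- lapply(sides, function(sd) {
    sx <- sd$sx
    list(
      ramus_x = (sx * X) >= (g$xg - spec$ramus_thickness / 2) &
                (sx * X) <= (g$xg + spec$ramus_thickness / 2),
      cor_xy = (sx * X) >= (g$xg - spec$coronoid_thickness / 2) &
               (sx * X) <= (g$xg + spec$coronoid_thickness / 2) &
               Y >= sd$cor_y0 & Y <= sd$cor_y1,
      ell_xy = ((X - sx * g$xg) / (r[1] * sd$sc))^2 +
               ((Y - sd$ye) / (r[2] * sd$sc))^2,
      angle = oracle_angle_plane(
        Go = c(sx * g$xg, g$y_go, 0), Co = sd$co,
        Me = c(0, g$y_front_face, 0),
        GoL = c(g$xg, g$y_go, 0), GoR = c(-g$xg, g$y_go, 0))
    )
  })
  isL <- X >= 0
  codes <- segment_labels()

  mask <- array(FALSE, d)
  solid <- array(FALSE, d)
  counts <- stats::setNames(numeric(8), names(codes)[-1])
  nslice <- d[1] * d[2]
  canal_zc <- spec$body_height / 2

  for (k in seq_len(d[3])) {
    z <- g$zs[k]
    sl <- rep(FALSE, nslice)
    if (z >= 0 && z <= spec$body_height) sl <- sl | in_body_xy
    for (s in c("L", "R")) {
      sd <- sides[[s]]; ps <- per_side[[s]]
      if (z >= 0 && z <= sd$z_ramus_top) {
        yp <- g$y_go + g$tanp * z
        sl <- sl | (ps$ramus_x & Y <= yp & Y >= yp - spec$ramus_width)
      }
      ez <- ((z - sd$zn) / (r[3] * sd$sc))^2
      if (ez <= 1) sl <- sl | (ps$ell_xy + ez <= 1)
      if (z > sd$z_ramus_top &&
          z <= sd$z_ramus_top + spec$coronoid_height) sl <- sl | ps$cor_xy
    }
    solid_sl <- sl
    msk_sl <- sl
    if (spec$n_teeth > 0L) {
      rad2 <- spec$tooth_radius^2 - (z - tooth_zc)^2
      if (rad2 > 0) msk_sl <- msk_sl | (d2teeth_x <= rad2 & teeth_y)
    }
    if (spec$canal_radius > 0 && abs(z - canal_zc) < spec$canal_radius) {
      msk_sl <- msk_sl & !(d2canal <= spec$canal_radius^2 - (z - canal_zc)^2)
    }
    mask[, , k] <- msk_sl
    solid[, , k] <- solid_sl

    # ---- independent brute-force ground-truth classification -------------
    sel <- which(solid_sl)
    if (length(sel)) {
      left <- isL[sel]
      lab <- integer(length(sel))
      for (s in c("L", "R")) {
        sd <- sides[[s]]; ps <- per_side[[s]]
        on_side <- if (s == "L") left else !left
        if (!any(on_side)) next
        i <- sel[on_side]
        if (z > sd$zn) {
          in_ell <- ps$ell_xy[i] + ((z - sd$zn) / (r[3] * sd$sc))^2 <= 1
          lab[on_side] <- ifelse(in_ell, codes[[paste0("condyle_", s)]],
                                 codes[[paste0("coronoid_", s)]])
        } else {
          da <- ps$angle$normal[2] * Y[i] + ps$angle$normal[3] * z -
            ps$angle$offset
          lab[on_side] <- ifelse(da > 0, codes[[paste0("ramus_", s)]],
                                 codes[[paste0("hemibody_", s)]])
        }
      }
      tb <- tabulate(lab, nbins = 8L)
      counts <- counts + tb
    }
  }

  img <- NULL
  if (image) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    vals <- array(spec$intensity_bg + (spec$intensity_fg - spec$intensity_bg) *
                    mask, d)
    if (spec$noise_sd > 0) {
      vals <- vals + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    img <- vol3d(vals, h, g$origin)
  }

  structure(list(
    image = img,
    mask = vol3d(mask, h, g$origin),
    solid = vol3d(solid, h, g$origin),
    landmarks = g$landmarks,
    crown_clip = plane3(c(0, -1, 0), c(0, g$y_front_face, 0),
                        label = "crown_clip"),
    truth = segment_volumes_from_counts(counts, h^3),
    truth_counts = counts,
    spec = spec
  ), class = "mandible_phantom")
}

#' @export
print.mandible_phantom <- function(x, ...) {
  d <- dim(x$mask$values)
  cat(sprintf("<mandible_phantom> %d x %d x %d voxels at %g mm\n",
              d[1], d[2], d[3], x$spec$spacing))
  cat(sprintf("  scale factors: condyle L %.2f R %.2f, ramus L %.2f R %.2f\n",
              x$spec$s_condyle[["L"]], x$spec$s_condyle[["R"]],
              x$spec$s_ramus[["L"]], x$spec$s_ramus[["R"]]))
  cat("  ground-truth volumes:\n")
  print(x$truth)
  invisible(x)
}

#' Mirror a phantom across the mid-sagittal plane
#'
#' Reflects the volumes through x = 0 (which must be a lattice symmetry
#' plane, as generated), reflects the landmarks and swaps their sides, and
#' swaps the ground-truth sides.
#'
#' @param out a [generate_phantom()] result.
#' @return A `mandible_phantom` with left and right exchanged.
#' @export
mirror_phantom <- function(out) {
  stopifnot(inherits(out, "mandible_phantom"))
  nx <- dim(out$mask$values)[1]
  if (abs(out$mask$origin[1] + (nx - 1) * out$mask$spacing[1] / 2) > 1e-6) {
    stop("grid is not symmetric about x = 0; reflection is off-lattice",
         call. = FALSE)
  }
  flip <- function(v) {
    if (is.null(v)) return(NULL)
    vol3d(v$values[nx:1, , , drop = FALSE], v$spacing, v$origin, v$direction)
  }
  m <- unclass(out$landmarks)
  m[, 1] <- -m[, 1]
  swap <- function(x) {
    nm <- names(x)
    nm2 <- sub("_L$", "_XX", nm); nm2 <- sub("_R$", "_L", nm2)
    names(x) <- sub("_XX$", "_R", nm2)
    x[nm]
  }
  counts <- swap(out$truth_counts)
  spec <- out$spec
  spec$s_condyle <- rev_sides(spec$s_condyle)
  spec$s_ramus <- rev_sides(spec$s_ramus)
  structure(list(
    image = flip(out$image),
    mask = flip(out$mask),
    solid = flip(out$solid),
    landmarks = swap_landmark_sides(landmark_set(m)),
    crown_clip = out$crown_clip,
    truth = segment_volumes_from_counts(counts, prod(out$mask$spacing)),
    truth_counts = counts,
    spec = spec
  ), class = "mandible_phantom")
}

rev_sides <- function(x) c(L = unname(x[["R"]]), R = unname(x[["L"]]))

#' Random phantom specification
#'
#' Draws a valid spec uniformly from ranges that exercise asymmetric
#' shrinkage, varying gonial angles and proportions, for property-based
#' testing of the partition against the brute-force oracle.
#'
#' @param seed integer seed.
#' @param spacing voxel spacing (mm).
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, spacing = 0.8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rw <- stats::runif(1, 27, 34)
  ry <- stats::runif(1, 5, 6.5)
  cap_max <- rw - 2 * ry - 2.05 - 1.8
  phantom_spec(
    spacing = spacing,
    intergonial_halfwidth = stats::runif(1, 36, 44),
    body_length = stats::runif(1, 38, 50),
    body_width = stats::runif(1, 10.5, 14),
    body_height = stats::runif(1, 18, 24),
    ramus_height = stats::runif(1, 37, 48),
    ramus_width = rw,
    ramus_thickness = stats::runif(1, 10.5, 14),
    gonial_angle_deg = stats::runif(1, 110, 135),
    condyle_radii = c(stats::runif(1, 5.5, 7.5), ry, stats::runif(1, 12, 20)),
    coronoid_thickness = stats::runif(1, 8, 12),
    coronoid_ap = stats::runif(1, 7, min(11, cap_max)),
    coronoid_height = stats::runif(1, 9, 14),
    s_condyle = c(L = stats::runif(1, 0.6, 1), R = stats::runif(1, 0.6, 1)),
    s_ramus = c(L = stats::runif(1, 0.75, 1), R = stats::runif(1, 0.75, 1)),
    n_teeth = sample(c(0L, 6L, 8L), 1),
    canal_radius = sample(c(0, 2.05), 1),
    seed = seed
  )
}
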