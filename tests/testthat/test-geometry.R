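# Reference frame and cutting-plane construction

test_that("midsagittal plane contains its defining points and matches the cross-product oracle", {
  p <- midsagittal_plane(c(0, 0, 0), c(100, 0, 0), c(-30, -40, 0))
  for (pt in list(c(0, 0, 0), c(100, 0, 0), c(-30, -40, 0))) {
    expect_lt(abs(signed_distance(p, pt)), 1e-9)
  }
  expect_equal(abs(p$normal), c(0, 0, 1), tolerance = 1e-12)

  expect_error(midsagittal_plane(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3)),
               "collinear")

  set.seed(11)
  for (i in 1:25) {
    S <- rnorm(3, sd = 20); N <- rnorm(3, sd = 20); Ba <- rnorm(3, sd = 20)
    v <- c((N - S)[2] * (Ba - S)[3] - (N - S)[3] * (Ba - S)[2],
           (N - S)[3] * (Ba - S)[1] - (N - S)[1] * (Ba - S)[3],
           (N - S)[1] * (Ba - S)[2] - (N - S)[2] * (Ba - S)[1])
    p <- midsagittal_plane(S, N, Ba)
    expect_equal(p$normal, v / sqrt(sum(v^2)), tolerance = 1e-12)
    expect_lt(abs(signed_distance(p, Ba)), 1e-9)
  }
})

test_that("reference frame tilts the horizontal plane exactly 6 degrees below S-N", {
  lm <- simple_landmarks()
  fr <- build_reference_frame(lm)
  S <- lm["S", ]; N <- lm["N", ]
  n0 <- xprod(N - S, fr$axis_left)
  n0 <- n0 / sqrt(sum(n0^2))
  ang <- acos(sum(n0 * fr$axis_superior))
  expect_equal(ang, 6 * pi / 180, tolerance = 1e-9)
  # by construction of the fixture the tilted horizontal is a true horizontal
  expect_equal(fr$axis_superior, c(0, 0, 1), tolerance = 1e-12)
  # tilt sign: the plane's anterior end dips, so Nasion ends up exactly
  # |S-N| * sin(6 deg) above the horizontal plane
  expect_equal(signed_distance(fr$horizontal, N),
               sqrt(sum((N - S)^2)) * sin(6 * pi / 180), tolerance = 1e-9)
})

test_that("frame axes are orthonormal, right-handed, and all planes pass through Sella", {
  set.seed(5)
  for (i in 1:20) {
    R <- random_rotation(); t <- rnorm(3, sd = 40)
    lm <- transform_landmarks(simple_landmarks(), R, t)
    fr <- build_reference_frame(lm)
    A <- cbind(fr$axis_anterior, fr$axis_left, fr$axis_superior)
    expect_lt(max(abs(crossprod(A) - diag(3))), 1e-9)
    expect_equal(det(A), 1, tolerance = 1e-9)
    for (pl in list(fr$horizontal, fr$vertical, fr$sagittal)) {
      expect_lt(abs(signed_distance(pl, lm["S", ])), 1e-6)
      expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)
    }
  }
})

test_that("frame construction is equivariant under rigid motion", {
  lm <- simple_landmarks()
  fr <- build_reference_frame(lm)
  set.seed(7)
  for (i in 1:10) {
    R <- random_rotation(); t <- rnorm(3, sd = 50)
    fr2 <- build_reference_frame(transform_landmarks(lm, R, t))
    expect_equal(fr2$origin, drop(R %*% lm["S", ]) + t, tolerance = 1e-9)
    for (ax in c("axis_anterior", "axis_left", "axis_superior")) {
      expect_equal(fr2[[ax]], drop(R %*% fr[[ax]]), tolerance = 1e-9)
    }
  }
})

test_that("plane through two points normal to a reference plane follows the cross-product oracle", {
  ref <- plane3(c(0, 0, 1), 0)
  p <- plane_through_two_points_normal_to(c(0, 0, 0), c(1, 0, 0), ref)
  expect_equal(abs(p$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(p$offset), 1e-12)

  expect_error(plane_through_two_points_normal_to(c(1, 2, 3), c(1, 2, 3), ref),
               "coincident")
  expect_error(plane_through_two_points_normal_to(c(0, 0, 0), c(0, 0, 5), ref),
               "parallel")

  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    ref <- plane3(rnorm(3), rnorm(1))
    pl <- plane_through_two_points_normal_to(a, b, ref)
    d <- (b - a) / sqrt(sum((b - a)^2))
    v <- xprod(d, ref$normal)
    v <- v / sqrt(sum(v^2))
    expect_equal(abs(sum(pl$normal * v)), 1, tolerance = 1e-9)
    expect_lt(abs(signed_distance(pl, a)), 1e-9)
    expect_lt(abs(signed_distance(pl, b)), 1e-9)
    expect_lt(abs(sum(pl$normal * ref$normal)), 1e-9)  # perpendicular planes
  }
})

test_that("plane through three points is permutation-invariant and interpolating", {
  p <- plane_through_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_lt(abs(p$offset), 1e-12)
  expect_error(plane_through_three_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")

  set.seed(9)
  for (i in 1:15) {
    pts <- matrix(rnorm(9, sd = 15), 3)
    base <- plane_through_three_points(pts[1, ], pts[2, ], pts[3, ])
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      q <- plane_through_three_points(pts[perm[1], ], pts[perm[2], ],
                                      pts[perm[3], ])
      expect_equal(q$normal, base$normal, tolerance = 1e-12)
      expect_equal(q$offset, base$offset, tolerance = 1e-9)
    }
    for (j in 1:3) expect_lt(abs(signed_distance(base, pts[j, ])), 1e-9)
  }
})

test_that("parallel plane through a point shifts the offset by the normal displacement", {
  ref <- plane3(c(1, 2, 2), 5)
  same <- plane_through_point_parallel_to(ref$normal * ref$offset, ref)
  expect_equal(same$offset, ref$offset, tolerance = 1e-12)
  p0 <- ref$normal * ref$offset
  shifted <- plane_through_point_parallel_to(p0 + 3.5 * ref$normal, ref)
  expect_equal(shifted$offset, ref$offset + 3.5, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    p <- rnorm(3, sd = 30)
    pl <- plane_through_point_parallel_to(p, ref)
    expect_equal(pl$normal, ref$normal)
    expect_lt(abs(signed_distance(pl, p)), 1e-9)
  }
})

test_that("bisecting plane makes equal dihedral angles with its parents", {
  b <- bisecting_plane(plane3(c(1, 0, 0), 0), plane3(c(0, 1, 0), 0),
                       c(0, 0, 0))
  expect_equal(b$normal, c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_lt(abs(b$offset), 1e-12)

  p <- plane3(c(1, 2, -1), c(3, 1, 5))
  expect_equal(bisecting_plane(p, p, c(3, 1, 5))$normal, p$normal,
               tolerance = 1e-12)

  expect_error(bisecting_plane(plane3(c(1, 0, 0), 0), plane3(c(0, 1, 0), 0),
                               c(5, 5, 5)), "anchor")

  set.seed(21)
  for (i in 1:20) {
    anchor <- rnorm(3, sd = 10)
    p1 <- plane3(rnorm(3), anchor)
    p2 <- plane3(rnorm(3), anchor)
    b <- bisecting_plane(p1, p2, anchor)
    a1 <- acos(min(1, abs(sum(b$normal * p1$normal))))
    a2 <- acos(min(1, abs(sum(b$normal * p2$normal))))
    expect_lt(abs(a1 - a2), 1e-9)
  }
})

test_that("mandibular planes: C-point parallelism, symmetry, and the gonial-angle split", {
  lm <- simple_landmarks()
  fr <- build_reference_frame(lm)
  pl <- build_mandibular_planes(lm, fr, "L")
  pr <- build_mandibular_planes(lm, fr, "R")

  expect_equal(abs(sum(pl$c_point$normal * fr$axis_superior)), 1,
               tolerance = 1e-12)
  expect_equal(abs(sum(pr$c_point$normal * fr$axis_superior)), 1,
               tolerance = 1e-12)
  # shared planes are identical across sides
  expect_equal(pl$median, pr$median)
  expect_equal(pl$gonion_menton, pr$gonion_menton)

  # symmetric fixture: left and right planes are mirror images across x = 0
  reflect <- function(p) plane3(p$normal * c(-1, 1, 1), p$offset)
  for (nm in c("condylion_gonion", "c_point", "mandibular_angle")) {
    expect_plane_equal(pl[[nm]], reflect(pr[[nm]]))
  }

  # angle plane passes through the Gonion and keeps Condylion positive,
  # Menton negative
  for (ps in list(pl, pr)) {
    go <- lm[paste0("Go_", ps$side), ]
    expect_lt(abs(signed_distance(ps$mandibular_angle, go)), 1e-6)
    expect_gt(signed_distance(ps$mandibular_angle,
                              lm[paste0("Co_", ps$side), ]), 0)
    expect_lt(signed_distance(ps$mandibular_angle, lm["Me", ]), 0)
  }

  # with Condylion placed on a known gonial-angle ray the mandibular-angle
  # plane halves that angle against both parents
  for (gonial in c(110, 120, 132.5)) {
    lma <- angled_landmarks(gonial)
    fra <- build_reference_frame(lma)
    psa <- build_mandibular_planes(lma, fra, "L")
    half <- gonial / 2 * pi / 180
    expect_equal(plane_angle(psa$mandibular_angle, psa$condylion_gonion),
                 half, tolerance = 1e-9)
    expect_equal(plane_angle(psa$mandibular_angle, psa$gonion_menton),
                 half, tolerance = 1e-9)
  }
})

test_that("mandibular planes are equivariant under rigid motion and swap under reflection", {
  lm <- simple_landmarks()
  fr <- build_reference_frame(lm)
  planes <- list(L = build_mandibular_planes(lm, fr, "L"),
                 R = build_mandibular_planes(lm, fr, "R"))
  nms <- c("condylion_gonion", "c_point", "gonion_menton", "median",
           "mandibular_angle")
  set.seed(13)
  for (i in 1:8) {
    R <- random_rotation(); t <- rnorm(3, sd = 30)
    lm2 <- transform_landmarks(lm, R, t)
    fr2 <- build_reference_frame(lm2)
    for (s in c("L", "R")) {
      p2 <- build_mandibular_planes(lm2, fr2, s)
      for (nm in nms) {
        expected <- mandivol:::transform_plane(planes[[s]][[nm]], R, t)
        expect_equal(p2[[nm]]$normal, expected$normal, tolerance = 1e-9)
        expect_equal(p2[[nm]]$offset, expected$offset, tolerance = 1e-6)
      }
    }
  }

  # reflection across the mid-sagittal plane swaps L and R exactly
  m <- unclass(lm); m[, 1] <- -m[, 1]
  lmr <- swap_landmark_sides(landmark_set(m))
  frr <- build_reference_frame(lmr)
  reflect <- function(p) plane3(p$normal * c(-1, 1, 1), p$offset)
  for (s in c("L", "R")) {
    other <- if (s == "L") "R" else "L"
    pref <- build_mandibular_planes(lmr, frr, s)
    for (nm in nms) {
      expect_plane_equal(pref[[nm]], reflect(planes[[other]][[nm]]),
                         tol_n = 1e-9, tol_o = 1e-9)
    }
  }
})
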