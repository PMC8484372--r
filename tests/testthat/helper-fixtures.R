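# shared fixtures: a hand-written landmark set matching the canonical
# phantom layout, random rigid transforms, and small synthetic volumes

simple_landmarks <- function() {
  landmark_set(list(
    S = c(0, 40, 70),
    N = c(0, 40, 70) + 80 * c(0, -cos(6 * pi / 180), sin(6 * pi / 180)),
    Ba = c(0, 60, 40),
    Me = c(0, 14, 0), Bpt = c(0, 14, 8), MSp = c(0, 26, 6),
    Go_L = c(40, 70, 0), Go_R = c(-40, 70, 0),
    Cp_L = c(40, 78, 42), Cp_R = c(-40, 78, 42),
    Co_L = c(40, 88, 55), Co_R = c(-40, 88, 55)))
}

# landmark set with Condylion exactly on the gonial-angle ray from Gonion
angled_landmarks <- function(gonial_deg, ramus_len = 55) {
  lm <- unclass(simple_landmarks())
  g <- gonial_deg * pi / 180
  dir <- c(0, -cos(g), sin(g))
  lm["Co_L", ] <- lm["Go_L", ] + ramus_len * dir
  lm["Co_R", ] <- lm["Go_R", ] + ramus_len * dir
  landmark_set(lm)
}

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# plain-R flood fill oracle (6-connectivity) marking background reachable
# from the grid boundary; intentionally independent of the compiled kernel
r_flood_oracle <- function(mask) {
  d <- dim(mask)
  reach <- array(FALSE, d)
  idx <- which(!mask, arr.ind = TRUE)
  boundary <- idx[idx[, 1] %in% c(1, d[1]) | idx[, 2] %in% c(1, d[2]) |
                    idx[, 3] %in% c(1, d[3]), , drop = FALSE]
  queue <- boundary
  reach[boundary] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue)) {
    nxt <- list()
    for (k in seq_len(nrow(offs))) {
      cand <- sweep(queue, 2, offs[k, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      new <- !mask[cand] & !reach[cand]
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand)) {
        reach[cand] <- TRUE
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    queue <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(0L, 0, 3)
  }
  reach
}

# handmade segment_planes for axis-aligned partition tests
axis_planes <- function(side, x_median = 0, z_cpoint, y_angle) {
  structure(list(
    side = side,
    condylion_gonion = plane3(c(0, 1, 0), y_angle, label = "cg"),
    c_point = plane3(c(0, 0, 1), z_cpoint, label = "cp"),
    gonion_menton = plane3(c(0, 0, 1), 0, label = "gm"),
    median = plane3(c(1, 0, 0), x_median, label = "median"),
    mandibular_angle = plane3(c(0, 1, 0), y_angle, label = "ma")
  ), class = "segment_planes")
}

expect_plane_equal <- function(p, q, tol_n = 1e-9, tol_o = 1e-6) {
  sgn <- if (sum(p$normal * q$normal) < 0) -1 else 1
  expect_lt(max(abs(p$normal - sgn * q$normal)), tol_n)
  expect_lt(abs(p$offset - sgn * q$offset), tol_o)
}
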