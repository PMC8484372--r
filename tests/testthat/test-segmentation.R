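# Thresholding, cavity filling, crown removal, classification and partition

test_that("thresholding matches a per-voxel comparison sweep", {
  v <- array(0, c(6, 6, 6))
  v[2:5, 2:5, 2:5] <- 1000
  vol <- vol3d(v, spacing = 1)
  m <- threshold_mask(vol, 500)
  expect_identical(sum(m$values), 64L)
  expect_true(all(m$values[2:5, 2:5, 2:5]))

  expect_warning(threshold_mask(vol, 5000), "empty")

  set.seed(42)
  noisy <- v + array(rnorm(length(v), 0, 50), dim(v))
  m2 <- threshold_mask(vol3d(noisy, spacing = 1), 500, 1500)
  expect_identical(which(m2$values), which(noisy >= 500 & noisy <= 1500))
})

test_that("internal cavities fill; open tunnels need a closing; oracle agrees", {
  # hollow cube: 20^3 shell with a 10^3 internal cavity
  shell <- array(FALSE, c(24, 24, 24))
  shell[3:22, 3:22, 3:22] <- TRUE
  shell[8:17, 8:17, 8:17] <- FALSE
  filled <- fill_internal_cavities(vol3d(shell, spacing = 1), 0)
  expect_identical(sum(filled$values), 8000L)

  solid <- array(FALSE, c(10, 10, 10)); solid[3:8, 3:8, 3:8] <- TRUE
  expect_identical(fill_internal_cavities(vol3d(solid, spacing = 1), 0)$values,
                   solid)

  # cube pierced by an open 1-voxel-radius tunnel along x
  tun <- array(FALSE, c(20, 16, 16))
  tun[2:19, 3:14, 3:14] <- TRUE
  tun[, 8:9, 8:9] <- FALSE
  vol <- vol3d(tun, spacing = 1)
  keep <- fill_internal_cavities(vol, 0)
  expect_identical(keep$values, tun)  # tunnel open at both ends: no cavity
  closed <- fill_internal_cavities(vol, 2.5)
  expect_gt(sum(closed$values), sum(tun))
  expect_true(all(closed$values[tun]))
  # interior of the tunnel (away from the sealed mouths) is filled
  expect_true(all(closed$values[8:13, 8:9, 8:9]))

  # oracle: cavities are exactly the background not reachable from the
  # boundary (plain-R flood fill)
  for (mask in list(shell, tun)) {
    reach <- r_flood_oracle(mask)
    expect_identical(fill_internal_cavities(vol3d(mask, spacing = 1), 0)$values,
                     mask | !reach)
  }
})

test_that("crown removal clips exactly the strictly-positive half-space", {
  m <- array(FALSE, c(8, 8, 10))
  m[2:7, 2:7, 2:7] <- TRUE            # body: z centres 1..6 (0-based)
  m[4:5, 4:5, 8:9] <- TRUE            # bumps above: z centres 7..8
  vol <- vol3d(m, spacing = 1)

  clip <- plane3(c(0, 0, 1), 6.5)
  out <- remove_crowns(vol, clip)
  expect_identical(sum(out$values), sum(m) - 8L)
  expect_false(any(out$values[, , 8:10]))

  # plane above everything: identity
  expect_identical(remove_crowns(vol, plane3(c(0, 0, 1), 50))$values, m)

  # plane exactly through the top body layer: distance-zero voxels retained
  out2 <- remove_crowns(vol, plane3(c(0, 0, 1), 6))
  expect_true(all(out2$values[2:7, 2:7, 7]))
  expect_false(any(out2$values[, , 8:10]))

  expect_warning(remove_crowns(vol, plane3(c(0, 0, 1), 0.5)), "half")

  # per-side pair needs the median plane and clips each side with its plane
  med <- plane3(c(1, 0, 0), 3.5)
  pair <- list(L = plane3(c(0, 0, 1), 5.5), R = plane3(c(0, 0, 1), 50))
  expect_error(remove_crowns(vol, pair), "median")
  out3 <- remove_crowns(vol, pair, median = med)
  expect_false(any(out3$values[5:7, , 7:10]))   # left of median, clipped
  expect_true(all(out3$values[2:3, 2:7, 7]))    # right side untouched
})

test_that("point classification reproduces independent signed-distance comparisons", {
  lm <- simple_landmarks()
  fr <- build_reference_frame(lm)
  pl <- build_mandibular_planes(lm, fr, "L")
  pr <- build_mandibular_planes(lm, fr, "R")

  expect_identical(classify_point(c(40, 88, 50), pl, pr),
                   "condyle_candidate_L")
  # median-plane tie goes Left
  expect_identical(classify_point(c(0, 30, 5), pl, pr), "hemibody_L")

  set.seed(31)
  pts <- cbind(runif(1e5, -60, 60), runif(1e5, 0, 110), runif(1e5, -10, 70))
  got <- classify_point(pts, pl, pr)
  # independent re-implementation of the decision rule
  sd_to <- function(p, x) drop(x %*% p$normal) - p$offset
  expected <- character(nrow(pts))
  left <- sd_to(pl$median, pts) >= 0
  for (s in c("L", "R")) {
    ps <- if (s == "L") pl else pr
    sel <- if (s == "L") left else !left
    lab <- rep(paste0("hemibody_", s), sum(sel))
    above <- sd_to(ps$c_point, pts[sel, , drop = FALSE]) > 0
    ram <- !above & sd_to(ps$mandibular_angle, pts[sel, , drop = FALSE]) > 0
    lab[above] <- paste0("condyle_candidate_", s)
    lab[ram] <- paste0("ramus_", s)
    expected[sel] <- lab
  }
  expect_identical(got, expected)
})

test_that("coronoid split assigns components by Condylion membership", {
  m <- array(FALSE, c(20, 20, 10))
  m[3:7, 3:7, 3:7] <- TRUE     # blob A
  m[12:16, 12:16, 3:7] <- TRUE # blob B
  vol <- vol3d(m, spacing = 1)
  sp <- split_coronoid(vol, condylion = c(4, 4, 4))
  blobA <- array(FALSE, dim(m)); blobA[3:7, 3:7, 3:7] <- TRUE
  expect_identical(sp$condyle$values, blobA)
  expect_identical(sum(sp$condyle$values), 125L)
  expect_identical(sum(sp$coronoid$values), 125L)
  expect_false(any(sp$condyle$values & sp$coronoid$values))

  # single component: everything condyle
  m2 <- array(FALSE, c(10, 10, 10)); m2[3:7, 3:7, 3:7] <- TRUE
  sp2 <- split_coronoid(vol3d(m2, spacing = 1), c(5, 5, 5))
  expect_identical(sp2$condyle$values, m2)
  expect_identical(sum(sp2$coronoid$values), 0L)

  # Condylion off-grid: nearest component wins
  sp3 <- split_coronoid(vol, condylion = c(-3, 2, 4))
  expect_identical(sum(sp3$condyle$values), 125L)
  expect_true(sp3$condyle$values[4, 4, 4])

  expect_warning(split_coronoid(vol3d(array(FALSE, c(4, 4, 4)), spacing = 1),
                                c(1, 1, 1)), "no foreground")
})

test_that("box partition matches closed-form slab counts and conserves voxels", {
  # 20^3 box at unit spacing, centres 0..19 in each axis; cutting planes
  # between voxel centres
  m <- array(TRUE, c(20, 20, 20))
  vol <- vol3d(m, spacing = 1, origin = c(-9.5, 0, 0))  # x centres -9.5..9.5
  lm <- unclass(simple_landmarks())
  lm["Co_L", ] <- c(5, 10, 18); lm["Co_R", ] <- c(-5, 10, 18)
  lmk <- landmark_set(lm)
  pl <- axis_planes("L", x_median = 0, z_cpoint = 13.5, y_angle = 11.5)
  pr <- axis_planes("R", x_median = 0, z_cpoint = 13.5, y_angle = 11.5)
  labs <- partition_mandible(vol, pl, pr, lmk)
  v <- compute_volumes(labs)
  cnt <- v$voxel_counts
  # per side: 10 x 20 x 20 voxels; above z = 13.5: 6 layers, one component
  # (all condyle); below: ramus has y > 11.5 (8 rows) x 14 layers
  expect_identical(unname(cnt["condyle_L"]), 10 * 20 * 6)
  expect_identical(unname(cnt["coronoid_L"]), 0)
  expect_identical(unname(cnt["ramus_L"]), 10 * 8 * 14)
  expect_identical(unname(cnt["hemibody_L"]), 10 * 12 * 14)
  expect_identical(unname(cnt["hemimandible_L"]), 10 * 20 * 20)
  expect_identical(cnt[c("condyle_R", "ramus_R", "hemibody_R")],
                   cnt[c("condyle_L", "ramus_L", "hemibody_L")],
                   ignore_attr = TRUE)
  expect_identical(sum(cnt[c("hemimandible_L", "hemimandible_R")]),
                   as.numeric(sum(m)))
})

test_that("volume computation is count times voxel volume with exact identities", {
  m <- array(0L, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- 1L   # 1000 voxels condyle_L
  lm <- label_map(m, spacing = 0.4)
  v <- compute_volumes(lm)
  expect_equal(unname(v$volumes["condyle_L"]), 64.000)
  expect_equal(unname(v$volumes["coronoid_L"]), 0)
  expect_equal(unname(v$volumes["hemimandible_L"]),
               unname(sum(v$volumes[c("condyle_L", "coronoid_L",
                                      "ramus_L", "hemibody_L")])))

  m2 <- array(0L, c(10, 10, 10)); m2[1:4, 1:5, 1:5] <- 5L
  v2 <- compute_volumes(label_map(m2, spacing = c(0.5, 0.5, 1)))
  expect_equal(unname(v2$volumes["ramus_L"]), 25.0)
})

test_that("partition equals the brute-force oracle exactly on asymmetric phantoms", {
  for (seed in c(101, 202)) {
    ph <- generate_phantom(random_phantom_spec(seed), image = FALSE)
    res <- segment_phantom(ph)
    expect_identical(res$measured$voxel_counts, res$truth$voxel_counts)
    # conservation: every clipped foreground voxel got exactly one label
    expect_identical(sum(res$labels$values > 0L), sum(ph$solid$values))
  }
})

test_that("one-sided condylar shrinkage decreases only that condyle", {
  base <- generate_phantom(phantom_spec(spacing = 0.8), image = FALSE)
  shr <- generate_phantom(phantom_spec(spacing = 0.8,
                                       s_condyle = c(L = 0.8, R = 1)),
                          image = FALSE)
  expect_lt(shr$truth_counts[["condyle_L"]], base$truth_counts[["condyle_L"]])
  expect_identical(shr$truth_counts[["condyle_R"]],
                   base$truth_counts[["condyle_R"]])
})

test_that("halving the voxel size changes reported segment volumes by < 2%", {
  p4 <- generate_phantom(phantom_spec(spacing = 0.4), image = FALSE)
  p2 <- generate_phantom(phantom_spec(spacing = 0.2), image = FALSE)
  segs <- c("condyle_L", "condyle_R", "ramus_L", "ramus_R",
            "hemibody_L", "hemibody_R", "hemimandible_L", "hemimandible_R")
  rel <- abs(p2$truth$volumes[segs] / p4$truth$volumes[segs] - 1)
  expect_lt(max(rel), 0.02)
  expect_lt(abs(p2$truth$total_mandible / p4$truth$total_mandible - 1), 0.02)
})
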