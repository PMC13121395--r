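test_that("SUVpeak of a large uniform region equals the uniform value", {
  v <- array(10, c(15, 15, 15))
  vol <- suv_volume(v, c(2, 2, 2))
  m <- array(TRUE, dim(v))
  expect_equal(suv_peak(vol, m), 10)
})

test_that("SUVpeak of a single hot voxel matches the sphere-voxelisation count", {
  v <- array(0, c(15, 15, 15)); v[8, 8, 8] <- 20
  vol <- suv_volume(v, c(2, 2, 2))
  m <- v > 0
  # oracle: enumerate voxel centres within the 1 mL sphere radius
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)
  cnt <- 0L
  for (di in -4:4) for (dj in -4:4) for (dk in -4:4)
    if ((2 * di)^2 + (2 * dj)^2 + (2 * dk)^2 <= r_mm^2) cnt <- cnt + 1L
  expect_equal(suv_peak(vol, m), 20 / cnt)
  # and numerically about 20 * voxel/sphere volume
  expect_equal(suv_peak(vol, m), 20 * 8 / 1000, tolerance = 0.15)
})

test_that("SUVpeak never exceeds SUVmax, is translation-invariant and scales linearly", {
  for (s in 1:20) {
    ph <- random_phantom(400 + s)
    m <- fixed_threshold_mask(ph$vol, ph$seed, 2.0)
    if (!any(m)) next
    pk <- suv_peak(ph$vol, m)
    expect_lte(pk, max(ph$vol$values[m]))
    # uniform intensity scaling scales SUVpeak linearly
    vol2 <- suv_volume(ph$vol$values * 3, ph$vol$spacing)
    expect_equal(suv_peak(vol2, m), 3 * pk, tolerance = 1e-12)
  }
  # whole-voxel translation leaves SUVpeak unchanged (away from edges)
  v <- array(0, c(20, 20, 20)); v[6:9, 6:9, 6:9] <- 7
  vol <- suv_volume(v, c(2, 2, 2))
  vt <- array(0, c(20, 20, 20)); vt[9:12, 10:13, 8:11] <- 7
  volt <- suv_volume(vt, c(2, 2, 2))
  expect_equal(suv_peak(vol, v > 0), suv_peak(volt, vt > 0))
})

test_that("background shell in a uniform background returns the background exactly", {
  ph <- random_phantom(11, grid = 20L)
  vol0 <- suv_volume(array(1.0, c(20, 20, 20)) , c(2, 2, 2))
  m <- array(FALSE, c(20, 20, 20)); m[9:12, 9:12, 9:12] <- TRUE
  bg <- suvbg_shell(vol0, m)
  expect_identical(bg$suvbg, 1.0)
  expect_gt(bg$n_voxels, 0)
})

test_that("shell distances agree with a brute-force all-pairs oracle", {
  set.seed(9)
  m <- array(FALSE, c(14, 14, 14))
  m[6:9, 5:8, 6:10] <- TRUE
  m[7, 4, 7] <- TRUE   # small protrusion for a non-convex surface
  sp <- c(2, 2.5, 3)
  vol <- suv_volume(array(runif(14^3), c(14, 14, 14)), sp)
  sh <- suvbg_shell(vol, m, shell_mm = c(5, 9))
  # oracle: distance of every voxel to the nearest mask voxel, full pairwise
  mc <- which(m, arr.ind = TRUE)
  ok <- matrix(FALSE, 0, 3)
  sel <- array(FALSE, dim(m))
  for (i in 1:14) for (j in 1:14) for (k in 1:14) {
    if (m[i, j, k]) next
    d2 <- (mc[, 1] - i)^2 * sp[1]^2 + (mc[, 2] - j)^2 * sp[2]^2 + (mc[, 3] - k)^2 * sp[3]^2
    dmin <- sqrt(min(d2))
    if (dmin >= 5 && dmin <= 9) sel[i, j, k] <- TRUE
  }
  got <- array(FALSE, dim(m))
  got[sh$voxels] <- TRUE
  expect_identical(got, sel)
  expect_equal(sh$suvbg, mean(vol$values[sel]))
})

test_that("a split background averages to the midpoint within voxelisation error", {
  v <- array(0.5, c(24, 24, 24)); v[13:24, , ] <- 1.5
  v[11:14, 11:14, 11:14] <- 8          # lesion straddling the interface
  vol <- suv_volume(v, c(2, 2, 2))
  m <- array(FALSE, dim(v)); m[11:14, 11:14, 11:14] <- TRUE
  bg <- suvbg_shell(vol, m)
  expect_equal(bg$suvbg, 1.0, tolerance = 0.02)
})

test_that("exclusion masks remove their voxels from the shell", {
  vol <- suv_volume(array(1, c(20, 20, 20)), c(2, 2, 2))
  m <- array(FALSE, c(20, 20, 20)); m[9:11, 9:11, 9:11] <- TRUE
  excl <- array(FALSE, c(20, 20, 20)); excl[15:17, 9:11, 9:11] <- TRUE  # ~12 mm away
  sh_plain <- suvbg_shell(vol, m)
  sh_excl <- suvbg_shell(vol, m, exclusions = list(excl))
  plain_set <- paste(sh_plain$voxels[, 1], sh_plain$voxels[, 2], sh_plain$voxels[, 3])
  excl_set <- paste(sh_excl$voxels[, 1], sh_excl$voxels[, 2], sh_excl$voxels[, 3])
  excl_coords <- which(excl, arr.ind = TRUE)
  excl_ids <- paste(excl_coords[, 1], excl_coords[, 2], excl_coords[, 3])
  expect_true(any(plain_set %in% excl_ids))      # the exclusion overlapped the shell
  expect_false(any(excl_set %in% excl_ids))      # and is gone after exclusion
  # shell never intersects the lesion itself
  mc <- which(m, arr.ind = TRUE)
  expect_false(any(excl_set %in% paste(mc[, 1], mc[, 2], mc[, 3])))
})

test_that("degenerate shells raise distinguishable errors", {
  vol <- suv_volume(array(1, c(6, 6, 6)), c(8, 8, 8))  # tiny grid, huge spacing
  m <- array(FALSE, c(6, 6, 6)); m[3:4, 3:4, 3:4] <- TRUE
  expect_error(suvbg_shell(vol, m, shell_mm = c(100, 110)), "out of bounds")
  vol2 <- suv_volume(array(1, c(20, 20, 20)), c(2, 2, 2))
  m2 <- array(FALSE, c(20, 20, 20)); m2[10, 10, 10] <- TRUE
  everything <- array(TRUE, c(20, 20, 20))
  expect_error(suvbg_shell(vol2, m2, exclusions = list(everything)), "fully excluded")
  expect_error(suvbg_shell(vol2, array(FALSE, c(20, 20, 20))), "empty mask")
})

test_that("TBRpeak is the plain ratio with a guarded denominator", {
  expect_equal(tbr_peak(6.0, 1.2), 5.0)
  expect_equal(tbr_peak(3.7, 3.7), 1.0)
  # typical preferred SUV4.0 lesion: SUVpeak 7.6 over SUVbg 1.3 gives TBR near 6
  expect_equal(tbr_peak(7.6, 1.3), 5.846154, tolerance = 1e-6)
  expect_lt(abs(tbr_peak(7.6, 1.3) - 6), 0.2)
  expect_error(tbr_peak(5, 0), "SUVbg")
})

test_that("MTV is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- TRUE
  expect_equal(mtv(m, c(2, 2, 2)), 100 * 8 / 1000)
  expect_identical(mtv(array(FALSE, c(5, 5, 5)), c(2, 2, 2)), 0)
  for (s in 1:10) {
    set.seed(500 + s)
    mm <- array(runif(512) < 0.3, c(8, 8, 8))
    sp <- runif(3, 1, 4)
    cnt <- 0L
    for (i in 1:8) for (j in 1:8) for (k in 1:8) if (mm[i, j, k]) cnt <- cnt + 1L
    expect_equal(mtv(mm, sp), cnt * prod(sp) / 1000)
  }
})
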