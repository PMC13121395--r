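test_that("fixed threshold on a uniform block behaves exactly", {
  vol <- block_volume(block_suv = 5)
  m <- fixed_threshold_mask(vol, c(5, 5, 5), 4.0)
  expect_identical(sum(m), 27L)
  expect_true(all(which(m, arr.ind = TRUE) >= 4) && all(which(m, arr.ind = TRUE) <= 6))
  expect_identical(sum(fixed_threshold_mask(vol, c(5, 5, 5), 6.0)), 0L)
  expect_error(fixed_threshold_mask(vol, c(0, 5, 5), 4), "outside")
})

test_that("a low bridge between two lesions floods into one merged component", {
  v <- array(0, c(15, 9, 9))
  v[3:5, 4:6, 4:6] <- 8
  v[11:13, 4:6, 4:6] <- 8
  v[6:10, 5, 5] <- 3          # bridge
  vol <- suv_volume(v, c(2, 2, 2))
  merged <- fixed_threshold_mask(vol, c(4, 5, 5), 2.5)   # below bridge intensity
  expect_identical(unname(merged), unname(flood_fill_oracle(v >= 2.5, c(4, 5, 5))))
  expect_true(merged[12, 5, 5])                           # reached the far lesion
  split <- fixed_threshold_mask(vol, c(4, 5, 5), 4)       # above bridge intensity
  expect_false(any(split[11:13, , ]))
})

test_that("41%max uses the scouted SUVmax and reduces to 0.41 * max at the lesion max", {
  vol <- block_volume(block_suv = 10)
  m <- relative41_mask(vol, c(5, 5, 5))
  expect_equal(attr(m, "threshold"), 4.1)
  expect_identical(sum(m), 27L)
  # seed away from the max voxel still scouts the same SUVmax
  v <- vol$values; v[5, 5, 5] <- 12
  vol2 <- suv_volume(v, vol$spacing)
  m_corner <- relative41_mask(vol2, c(4, 4, 4))
  m_max <- relative41_mask(vol2, c(5, 5, 5))
  expect_equal(attr(m_corner, "threshold"), 0.41 * 12)
  expect_equal(attr(m_max, "threshold"), 0.41 * 12)
  expect_identical(unname(m_corner), unname(m_max))
})

test_that("41%max can dip into a warm background only when contiguously above threshold", {
  v <- array(1.0, c(11, 11, 11))
  v[5:7, 5:7, 5:7] <- 4
  vol <- suv_volume(v, c(2, 2, 2))
  m <- relative41_mask(vol, c(6, 6, 6))
  expect_equal(attr(m, "threshold"), 1.64)
  expect_identical(bare(m), flood_fill_oracle(v >= 1.64, c(6, 6, 6)))
  expect_identical(sum(m), 27L)   # background 1.0 < 1.64 stays out
})

test_that("A50peak reaches the closed-form threshold on uniform contrast", {
  # sphere SUV 10 (radius 10 mm) in uniform background 2
  ls1 <- lesion_spec(center = c(40, 40, 40), radius = 10, peak_suv = 10)
  g <- generate_volume(phantom_spec(40, 2, background_suv = 2, lesions = list(ls1)))
  seed <- as.integer(g$seeds[1, c("i", "j", "k")])
  m <- a50peak_mask(g$volume, seed)
  expect_true(attr(m, "converged"))
  expect_equal(attr(m, "threshold"), 2 + 0.5 * (10 - 2), tolerance = 1e-6)
  # zero background: pure 50% of SUVpeak
  g0 <- generate_volume(phantom_spec(40, 2, background_suv = 0, lesions = list(
    lesion_spec(center = c(40, 40, 40), radius = 10, peak_suv = 10))))
  m0 <- a50peak_mask(g0$volume, as.integer(g0$seeds[1, c("i", "j", "k")]))
  pk0 <- suv_peak(g0$volume, m0)
  expect_equal(attr(m0, "threshold"), 0.5 * pk0, tolerance = 1e-6)
})

test_that("A50peak returns a self-consistent fixed point on blurred phantoms", {
  for (s in 1:5) {
    ph <- random_phantom(100 + s)
    m <- a50peak_mask(ph$vol, ph$seed)
    if (!any(m) || !attr(m, "converged")) next
    pk <- suv_peak(ph$vol, m)
    bg <- tryCatch(suvbg_shell(ph$vol, m)$suvbg, error = function(e) 0)
    expect_lt(abs((bg + 0.5 * (pk - bg)) - attr(m, "threshold")), 0.01)
  }
})

test_that("majority vote follows the per-voxel definition and unanimity", {
  d <- c(5, 5, 5)
  base <- array(FALSE, d); base[2:4, 2:4, 2:4] <- TRUE
  m2 <- base; m2[1, 1, 1] <- TRUE
  masks <- list(base, m2, array(FALSE, d), array(FALSE, d))
  mv2 <- majority_vote(masks, 2, c(3, 3, 3))
  mv3 <- majority_vote(masks, 3, c(3, 3, 3))
  expect_identical(unname(mv2), unname(base))  # isolated (1,1,1) voxel is not connected
  expect_identical(sum(mv3), 0L)
  same <- list(base, base, base, base)
  expect_identical(majority_vote(same, 2, c(3, 3, 3)),
                   majority_vote(same, 3, c(3, 3, 3)))
  expect_error(majority_vote(list(base, array(FALSE, c(4, 4, 4))), 2, c(3, 3, 3)),
               "same dimensions")
})

test_that("random mask quadruples match the brute-force voting tally", {
  d <- c(8, 8, 8)
  for (s in 1:30) {
    set.seed(200 + s)
    masks <- lapply(1:4, function(i) array(runif(prod(d)) < 0.4, d))
    votes_or <- mv_count_oracle(masks, 2)
    votes_or3 <- mv_count_oracle(masks, 3)
    seedv <- c(4, 4, 4)
    got2 <- majority_vote(masks, 2, seedv)
    got3 <- majority_vote(masks, 3, seedv)
    expect_identical(unname(got2), unname(flood_fill_oracle(votes_or, seedv)))
    expect_identical(unname(got3), unname(flood_fill_oracle(votes_or3, seedv)))
  }
})

test_that("segment_all returns six records with threshold monotonicity and fusion nesting", {
  ph <- random_phantom(7)
  sa <- segment_all(ph$vol, ph$seed)
  expect_identical(nrow(sa$results), 6L)
  expect_identical(sa$results$method, pet_methods())
  m <- sa$masks
  expect_true(all(!m[["SUV4.0"]] | m[["SUV2.5"]]))   # SUV4.0 within SUV2.5
  expect_true(all(!m[["MV3"]] | m[["MV2"]]))         # MV3 within MV2
  four <- m[c("SUV2.5", "SUV4.0", "41max", "A50peak")]
  union4 <- Reduce(`|`, four)
  inter4 <- Reduce(`&`, four)
  expect_true(all(!m[["MV2"]] | union4))
  seeded_inter <- flood_fill_oracle(inter4, ph$seed)
  expect_true(all(!seeded_inter | m[["MV3"]]))
  expect_equal(sa$results$mtv_ml, sa$results$n_voxels * prod(ph$vol$spacing) / 1000)
})

test_that("threshold monotonicity holds across random phantoms", {
  for (s in 1:10) {
    ph <- random_phantom(300 + s)
    t1 <- runif(1, 1, 3); t2 <- t1 + runif(1, 0.5, 3)
    lo <- fixed_threshold_mask(ph$vol, ph$seed, t1)
    hi <- fixed_threshold_mask(ph$vol, ph$seed, t2)
    expect_true(all(!hi | lo))
  }
})
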