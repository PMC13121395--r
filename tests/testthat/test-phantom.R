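test_that("an unblurred noiseless sphere is exact: max SUV and voxel set", {
  ls1 <- lesion_spec(center = c(39, 39, 39), radius = 8, peak_suv = 10)
  ps <- phantom_spec(40, 2, background_suv = 0.5, noise_sd = 0, psf_fwhm = 0,
                     lesions = list(ls1))
  g <- generate_volume(ps)
  expect_identical(max(g$volume$values), 10)
  # voxels at SUV 10 are exactly those whose centres lie inside the sphere
  ax <- (0:39) * 2
  inside <- outer(outer((ax - 39)^2, (ax - 39)^2, "+"), (ax - 39)^2, "+") <= 64
  expect_identical(unname(g$volume$values == 10), unname(inside))
  # everything else is background
  expect_true(all(g$volume$values[!inside] == 0.5))
})

test_that("PSF blur matches a direct dense convolution at sampled voxels and conserves activity", {
  ls1 <- lesion_spec(center = c(39, 39, 39), radius = 8, peak_suv = 10)
  mk <- function(fwhm) generate_volume(
    phantom_spec(40, 2, background_suv = 0.5, psf_fwhm = fwhm,
                 lesions = list(ls1)))
  g0 <- mk(0); g6 <- mk(6)
  expect_gt(max(g6$volume$values), 0.5)
  expect_lte(max(g6$volume$values), 10)
  # peak attenuation by the blur stays small for a radius comfortably above
  # the PSF width (see also the 2% check at radius 10 below)
  expect_lt(abs(max(g6$volume$values) - 10) / 10, 0.035)
  # total lesion activity conserved within 1% versus the unblurred volume
  act <- function(g) sum(g$volume$values - 0.5) * prod(g$volume$spacing)
  expect_lt(abs(act(g6) - act(g0)) / act(g0), 0.01)
  # oracle: direct dense 3-D convolution of the excess field at sampled voxels
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2      # in voxels (2 mm spacing)
  r <- ceiling(4 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  kern <- outer(outer(k1, k1), k1)
  delta0 <- g0$volume$values - 0.5
  set.seed(42)
  probes <- cbind(sample(5:36, 12, TRUE), sample(5:36, 12, TRUE), sample(5:36, 12, TRUE))
  probes <- rbind(probes, c(20, 20, 20), c(1, 1, 1), c(40, 20, 20))
  for (p in seq_len(nrow(probes))) {
    v <- probes[p, ]
    tot <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      i <- v[1] - di; j <- v[2] - dj; kk <- v[3] - dk
      if (i >= 1 && i <= 40 && j >= 1 && j <= 40 && kk >= 1 && kk <= 40)
        tot <- tot + kern[di + r + 1, dj + r + 1, dk + r + 1] * delta0[i, j, kk]
    }
    expect_equal(g6$volume$values[v[1], v[2], v[3]] - 0.5, tot, tolerance = 1e-10)
  }
})

test_that("the blurred peak matches peak_suv within 2% when the lesion dwarfs the PSF", {
  g <- generate_volume(phantom_spec(
    40, 2, background_suv = 0.5, psf_fwhm = 6,
    lesions = list(lesion_spec(center = c(40, 40, 40), radius = 10, peak_suv = 10))))
  expect_lt(abs(max(g$volume$values) - 10) / 10, 0.02)
})

test_that("volume generation is deterministic under a fixed seed", {
  ls1 <- lesion_spec(center = c(20, 20, 20), radius = 6, peak_suv = 8)
  ps <- phantom_spec(20, 2, background_suv = 0.4, noise_sd = 0.2, psf_fwhm = 4,
                     lesions = list(ls1), rng_seed = 11)
  g1 <- generate_volume(ps); g2 <- generate_volume(ps)
  expect_identical(g1$volume$values, g2$volume$values)
  expect_identical(g1$seeds, g2$seeds)
})

test_that("overlapping lesions are rejected with the colliding indices", {
  l1 <- lesion_spec(center = c(20, 20, 20), radius = 6, peak_suv = 8)
  l2 <- lesion_spec(center = c(24, 20, 20), radius = 6, peak_suv = 8)
  ps <- phantom_spec(24, 2, lesions = list(l1, l2))
  expect_error(generate_volume(ps), "lesions 1 and 2 overlap")
})

test_that("lesions must fit inside the volume bounds", {
  expect_error(
    phantom_spec(16, 2, lesions = list(
      lesion_spec(center = c(2, 15, 15), radius = 6, peak_suv = 8))),
    "does not fit")
})

test_that("a noiseless planted-rule table gives the planted rule accuracy exactly 1", {
  spec <- rating_sim_spec(n_lesions_per_timepoint = c(120, 40, 40),
                          rating_noise = 0, co_acceptability = 0, rng_seed = 3)
  tab <- simulate_rating_table(spec)
  expect_identical(rule_accuracy(default_decision_rule(), tab), 1)
})

test_that("rating noise moves planted-rule accuracy to 1 - noise within binomial error", {
  spec <- rating_sim_spec(n_lesions_per_timepoint = c(1400, 300, 300),
                          rating_noise = 0.1, rng_seed = 17)
  tab <- simulate_rating_table(spec)
  expect_equal(rule_accuracy(default_decision_rule(), tab), 0.90, tolerance = 0.025)
})

test_that("the default cohort split yields 598 lesions and features stay in range", {
  spec <- rating_sim_spec(rng_seed = 2)
  tab <- simulate_rating_table(spec)
  expect_identical(nrow(tab), 598L)
  expect_identical(as.integer(table(factor(tab$timepoint,
                                           c("baseline", "interim", "eot")))),
                   c(409L, 67L, 122L))
  expect_true(all(tab$suvpeak >= 2 & tab$suvpeak <= 20))
  expect_true(all(tab$suvbg >= 0.3 & tab$suvbg <= 2.5))
  expect_equal(tab$tbrpeak, tab$suvpeak / tab$suvbg)
  expect_true(all(as.matrix(tab[paste0("rating_", pet_methods())]) %in% 1:5))
  # deterministic
  expect_identical(tab, simulate_rating_table(spec))
})

test_that("an empty simulated cohort is rejected", {
  expect_error(rating_sim_spec(n_lesions_per_timepoint = c(0, 0, 0)),
               "must contain lesions")
})
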