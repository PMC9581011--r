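test_that("uniform placement is Poisson-concentrated and deterministic", {
  e1 <- place_uniform(10, 16, seed = 5)
  expect_true(abs(nrow(e1) - 2560) < 4 * sqrt(2560))
  expect_true(all(e1$x >= 0 & e1$x <= 16 & e1$y >= 0 & e1$y <= 16))
  e2 <- place_uniform(10, 16, seed = 5)
  expect_identical(e1, e2)
  tiny <- place_uniform(0.01, 10, seed = 6)
  expect_gte(nrow(tiny), 1)
})

test_that("dimer placement gives exact separations on a well-spaced grid", {
  seps <- seq(0.1, 1, length.out = 20)
  em <- place_dimers(seps, roi_size = 50, spacing = 10)
  expect_identical(nrow(em), 40L)
  for (k in seq_along(seps)) {
    pair <- em[em$pair == k, ]
    expect_equal(sqrt(diff(pair$x)^2 + diff(pair$y)^2), seps[k],
                 tolerance = 1e-12)
  }
  # emitters of different pairs stay at least spacing - 1 apart
  d <- as.matrix(dist(cbind(em$x, em$y)))
  cross <- d[outer(em$pair, em$pair, "!=")]
  expect_gte(min(cross), 9)
  expect_error(place_dimers(seps, roi_size = 5, spacing = 10), "ROI")
})

test_that("blinking respects the kinetic chain structure", {
  em <- place_uniform(2, 5, seed = 7)
  dark <- simulate_blinking(em, kinetic_model(0, 0.5, 0.2), 1000, seed = 7)
  expect_identical(nrow(dark), 0L)
  tr <- simulate_blinking(em, kinetic_model(0.01, 0.5, 0.2), 5000,
                          mode = "gillespie", seed = 8)
  for (e in unique(tr$emitter_id)) {
    iv <- tr[tr$emitter_id == e, ]
    expect_true(all(iv$t_end > iv$t_start))
    if (nrow(iv) > 1) expect_true(all(diff(iv$t_start) > 0) &&
                                    all(iv$t_start[-1] >= iv$t_end[-nrow(iv)]))
    expect_true(all(iv$t_end <= 5000))
  }
})

test_that("discrete-mode blink statistics match the geometric closed forms", {
  em <- place_uniform(8, 16, seed = 9) # ~2000 emitters
  tr <- simulate_blinking(em, kinetic_model(0.01, 0.5, 0.2), 20000,
                          mode = "discrete", seed = 9)
  # mean blinks per activated emitter: (k_off + k_bleach) / k_bleach
  blinks <- table(tr$emitter_id)
  expect_equal(mean(blinks), 3.5, tolerance = 0.15)
  # durations geometric with p = 1 - exp(-0.7): mean within 3 standard errors
  N <- round(tr$t_end - tr$t_start)
  N <- N[tr$t_end < 20000]
  p <- 1 - exp(-0.7)
  se <- sqrt((1 - p) / p^2) / sqrt(length(N))
  expect_lt(abs(mean(N) - 1 / p), 3 * se)
})

test_that("photon counts distinguish full and boundary frames", {
  em <- tibble::tibble(emitter_id = 1L, x = 2, y = 2)
  tr <- tibble::tibble(emitter_id = 1L, t_start = 0.4, t_end = 3.6)
  set.seed(10)
  locs <- intervals_to_localizations(tr, em, 10, photons_per_frame = 1000)
  expect_identical(nrow(locs), 4L)
  full <- locs$frame %in% 2:3
  expect_true(all(locs$photons[full] == 1000))
  expect_true(all(locs$photons[!full] > 0 & locs$photons[!full] < 1000))
  # boundary frames are noisier and say so in their reported error
  expect_true(all(locs$sigma_x[!full] > min(locs$sigma_x[full])))
})

test_that("reported sigma calibrates the CRLB component of the noise", {
  # with no extra noise the reported error is the whole error budget
  sim <- simulate_smlm(rho0 = 10, roi_size = 8, n_frames = 2500,
                       kinetics_mode = "gillespie", extra_noise_sigma = 0,
                       seed = 11)
  locs <- sim$localizations
  truth_x <- sim$emitters$x[match(locs$emitter_id, sim$emitters$emitter_id)]
  z <- (locs$x - truth_x) / locs$sigma_x
  expect_gt(length(z), 3000)
  expect_equal(sd(z), 1, tolerance = 0.05)
  # with extra noise the total scatter follows the quadrature sum
  sim2 <- simulate_smlm(rho0 = 10, roi_size = 8, n_frames = 2500,
                        kinetics_mode = "discrete", seed = 12)
  l2 <- sim2$localizations
  err <- l2$x - sim2$emitters$x[match(l2$emitter_id, sim2$emitters$emitter_id)]
  expect_equal(sd(err), sqrt(mean(l2$sigma_x^2) + 0.05^2), tolerance = 0.05)
})

test_that("miss thinning removes round(p_miss * n) records", {
  locs <- as_localizations(random_locs(100, seed = 13))
  expect_identical(nrow(apply_miss_probability(locs, 0)), 100L)
  expect_identical(nrow(apply_miss_probability(locs, 0.01, seed = 1)), 99L)
  l149 <- as_localizations(random_locs(149, seed = 14))
  expect_identical(nrow(apply_miss_probability(l149, 0.01, seed = 1)), 148L)
})

test_that("full simulations are reproducible under a fixed seed", {
  s1 <- simulate_smlm(rho0 = 5, roi_size = 4, n_frames = 800, seed = 15)
  s2 <- simulate_smlm(rho0 = 5, roi_size = 4, n_frames = 800, seed = 15)
  expect_identical(s1$localizations, s2$localizations)
  expect_identical(s1$emitters, s2$emitters)
})
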