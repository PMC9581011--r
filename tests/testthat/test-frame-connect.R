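test_that("cluster extraction follows chains from births to deaths", {
  # n_c = 3, links 1 -> 2 -> 3 (rows select UL columns)
  a <- c(2L, 3L, 6L, 1L, 4L, 5L)
  cl <- assignments_to_clusters(a, 3)
  expect_identical(cl, list(1:3))
  # no UL selections: all singletons
  b <- c(4L, 5L, 6L, 1L, 2L, 3L)
  expect_identical(assignments_to_clusters(b, 3), list(1L, 2L, 3L))
})

test_that("random LAP solutions on real cost matrices partition the members", {
  m <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  for (seed in 1:10) {
    members <- as_localizations(random_locs(8, n_frames = 8, roi = 0.4,
                                            seed = 900 + seed))
    cm <- build_cost_matrix(members, m, 10)
    cl <- assignments_to_clusters(solve_lap(cm), cm$n_c)
    expect_setequal(unlist(cl), seq_len(cm$n_c))
    expect_identical(sum(lengths(cl)), cm$n_c)
  }
})

test_that("maximum-likelihood combination matches the closed forms", {
  one <- as_localizations(make_locs(5, 1.5, 2.5, sigma = 0.07))
  c1 <- combine_cluster(one)
  expect_equal(c1$x, 1.5)
  expect_equal(c1$sigma_x, 0.07)
  expect_identical(c1$n_members, 1L)
  # equal errors: midpoint, error / sqrt(2)
  two <- as_localizations(make_locs(1:2, c(0, 1), c(0, 0), sigma = 0.1))
  c2 <- combine_cluster(two)
  expect_equal(c2$x, 0.5)
  expect_equal(c2$sigma_x, 0.1 / sqrt(2), tolerance = 1e-12)
  # unequal errors: inverse-variance weights
  uneq <- as_localizations(make_locs(1:2, c(0, 1), c(0, 0), sigma = c(0.1, 0.2)))
  c3 <- combine_cluster(uneq)
  expect_equal(c3$x, 0.2, tolerance = 1e-3)
  expect_equal(c3$sigma_x, 1 / sqrt(125), tolerance = 1e-3)
  expect_equal(c3$sigma_x, 0.0894, tolerance = 1e-3)
  # photons sum, background averages, frame = first member frame
  expect_equal(c3$photons, 2000)
  expect_equal(c3$frame, 1L)
  # precision never degrades below the best member
  expect_lte(c3$sigma_x, min(uneq$sigma_x))
})

test_that("combination keeps emitter identity only when unanimous", {
  same <- as_localizations(make_locs(1:2, c(0, 0.01), c(0, 0), emitter_id = 4L))
  expect_identical(combine_cluster(same)$emitter_id, 4L)
  mixed <- as_localizations(make_locs(1:2, c(0, 0.01), c(0, 0),
                                      emitter_id = c(4L, 5L)))
  expect_identical(combine_cluster(mixed)$emitter_id, -1L)
})

test_that("LAP frame connection handles edge cases and preserves membership", {
  expect_identical(nrow(frame_connect_lap(lapfc:::empty_localizations())), 0L)
  # an isolated blink equals the ground-truth ideal connection
  fix <- single_blink_fixture()
  got <- frame_connect_lap(fix)
  ideal <- ideal_frame_connection(fix)
  expect_identical(nrow(got), 1L)
  expect_equal(got$x, ideal$x)
  expect_equal(got$sigma_x, ideal$sigma_x)
  # bright same-frame localizations are never combined with each other
  # (all-singleton input legitimately clamps the duration-based rate)
  pair <- make_locs(c(10, 10), c(3, 3.2), c(3, 3), emitter_id = c(1L, 2L))
  out <- suppressWarnings(frame_connect_lap(pair))
  expect_identical(nrow(out), 2L)
})

test_that("the output member ids partition the input ids", {
  sim <- simulate_smlm(rho0 = 5, roi_size = 4, n_frames = 1500,
                       kinetics_mode = "discrete", seed = 31)
  out <- frame_connect_lap(sim$localizations)
  expect_setequal(unlist(out$member_ids), sim$localizations$id)
  expect_identical(sum(out$n_members), nrow(sim$localizations))
  expect_lte(nrow(out), nrow(sim$localizations))
  # diagnostics carry the calibrated model and per-precluster counts
  d <- attr(out, "diagnostics")
  expect_s3_class(d$model, "kinetic_model")
  expect_identical(sum(d$clusters_per_precluster), nrow(out))
})

test_that("the halving convention conserves the full connection cost", {
  m <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  members <- as_localizations(make_locs(1:2, c(0, 0.02), c(0, 0.01)))
  cm <- build_cost_matrix(members, m, 10)
  full <- connection_cost(0.02, 0.01, 2 * 0.05^2, 2 * 0.05^2, 1, m)
  expect_equal(cm$values[1, 2] + cm$values[4, 3], full, tolerance = 1e-12)
})

test_that("LAP-FC merges distinct emitters less than the hypothesis test", {
  # dense data: over-clustering pressure; count combined records whose
  # members disagree on the generating emitter
  wrong_rate <- function(out) {
    sum(out$n_members > 1 & out$emitter_id == -1L) / max(nrow(out), 1)
  }
  sims <- lapply(1:2, function(s) {
    simulate_smlm(rho0 = 20, roi_size = 4, n_frames = 4000,
                  kinetics_mode = "discrete", seed = 40 + s)
  })
  w_lap <- mean(vapply(sims, function(s)
    wrong_rate(frame_connect_lap(s$localizations)), numeric(1)))
  w_hyp <- mean(vapply(sims, function(s)
    wrong_rate(frame_connect_hypothesis_test(s$localizations)), numeric(1)))
  expect_lte(w_lap, w_hyp)
})

test_that("externally prescribed rates override the self-calibration", {
  sim <- simulate_smlm(rho0 = 5, roi_size = 4, n_frames = 1500,
                       kinetics_mode = "discrete", seed = 33)
  ext <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  out <- frame_connect_lap(sim$localizations, model = ext)
  expect_identical(attr(out, "diagnostics")$model, ext)
  expect_setequal(unlist(out$member_ids), sim$localizations$id)
})
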