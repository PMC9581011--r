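test_that("off+bleach rate follows the geometric-duration closed form", {
  expect_equal(estimate_off_plus_bleach(rep(2, 10)), log(2), tolerance = 1e-6)
  expect_equal(estimate_off_plus_bleach(c(1, 2, 3)), log(2), tolerance = 1e-6)
  expect_warning(r <- estimate_off_plus_bleach(rep(1, 5)), "clamped")
  expect_equal(r, 5) # upper rate bound
})

test_that("p_miss is one minus the mean cluster fill fraction", {
  fill <- function(ncs, Ns) {
    parts <- purrr::map2(ncs, Ns, function(nc, N) {
      frames <- c(1L, N, if (nc > 2) seq_len(nc - 2) + 1L)
      make_locs(frames[seq_len(nc)], runif(nc, 0, 0.01), runif(nc, 0, 0.01))
    })
    locs <- dplyr::bind_rows(parts, .id = "grp")
    locs$x <- locs$x + 10 * as.numeric(locs$grp) # separate clusters
    locs$grp <- NULL
    locs$id <- seq_len(nrow(locs))
    locs$precluster <- rep(seq_along(ncs), ncs)
    locs
  }
  expect_equal(estimate_p_miss(fill(5, 5)), 0)
  expect_equal(estimate_p_miss(fill(4, 5)), 0.2)
  expect_equal(estimate_p_miss(fill(c(3, 5), c(4, 5))), 0.125)
})

test_that("k_off is the cluster/localization count ratio", {
  expect_equal(estimate_k_off(100, 400), 0.25)
  expect_equal(estimate_k_off(7, 7), 1)
  expect_error(estimate_k_off(1, 0), "n = 0")
})

test_that("the cumulative localization model matches an independent evaluation", {
  model <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  expect_equal(cumulative_localization_model(1, 1000, model), 0)
  # independent evaluation of the expected-count expression
  direct <- function(f, N, k_on, k_off, k_bleach, p_miss) {
    tau <- k_on / (k_on + k_off + k_bleach)
    l1 <- k_bleach * tau
    l2 <- k_on + k_off + k_bleach - l1
    N * (1 - p_miss) * tau *
      ((1 - exp(-l1 * (f - 1))) / l1 - (1 - exp(-l2 * (f - 1))) / l2)
  }
  expect_equal(cumulative_localization_model(1001, 1000, model),
               direct(1001, 1000, 0.005, 0.5, 0.2, 0.01), tolerance = 1e-12)
  # asymptote: N (1 - p_miss) (1/k_bleach - tau/lambda2)
  lim <- 1000 * 0.99 * (1 / 0.2 - model$tau / model$lambda2)
  expect_equal(cumulative_localization_model(1e7, 1000, model), lim,
               tolerance = 1e-6)
  # non-decreasing in f, linear in N_emitters
  f <- c(1, 2, 5, 10, 100, 1000)
  v <- cumulative_localization_model(f, 1000, model)
  expect_true(all(diff(v) > 0))
  expect_equal(cumulative_localization_model(f, 2000, model), 2 * v)
  # k_bleach = 0 gives lambda1 = 0; analytic limit applies
  m0 <- kinetic_model(0.005, 0.5, 0, 0)
  expect_true(is.finite(cumulative_localization_model(100, 10, m0)))
})

test_that("the on-rate fit recovers exact and Poisson-noised curves", {
  model <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  f <- 1:4000
  exact <- cumulative_localization_model(f, 1500, model)
  fit <- fit_kon_nemitters(exact, 0.5, 0.2, 0.01)
  expect_equal(fit$k_on, 0.005, tolerance = 1e-3)
  expect_equal(fit$N_emitters, 1500, tolerance = 1e-3)
  expect_error(fit_kon_nemitters(rep(0, 100), 0.5, 0.2, 0.01), "all-zero")
  # Poissonized per-frame increments
  set.seed(4)
  noisy <- cumsum(rpois(length(f), diff(c(0, exact))))
  fitn <- fit_kon_nemitters(noisy, 0.5, 0.2, 0.01)
  expect_equal(fitn$k_on, 0.005, tolerance = 0.1)
})

test_that("local cluster density matches the k-NN formula and its fallbacks", {
  # equilateral triangle, pairwise distance 1: rho_c = 3 / pi
  tri <- tibble::tibble(precluster = 1:3, n_c = 1L, frame_start = 1L,
                        frame_end = 1L, N = 1L,
                        cx = c(0, 1, 0.5), cy = c(0, 0, sqrt(3) / 2))
  out <- estimate_local_cluster_density(tri, 2, roi_area = 100)
  expect_equal(out$rho_c, rep(3 / pi, 3), tolerance = 1e-12)
  # two preclusters only: global fallback
  two <- tri[1:2, ]
  out2 <- estimate_local_cluster_density(two, 2, roi_area = 10)
  expect_equal(out2$rho_c, rep(2 / 10, 2))
  # random configuration vs a brute-force k-NN recomputation
  set.seed(9)
  m <- 40
  pts <- tibble::tibble(precluster = 1:m, n_c = 1L, frame_start = 1L,
                        frame_end = 1L, N = 1L,
                        cx = runif(m, 0, 5), cy = runif(m, 0, 5))
  got <- estimate_local_cluster_density(pts, 2, roi_area = 25)$rho_c
  d <- as.matrix(dist(cbind(pts$cx, pts$cy)))
  diag(d) <- Inf
  rk <- unname(apply(d, 1, function(r) sort(r)[2]))
  expect_equal(got, 3 / (pi * rk^2), tolerance = 1e-12)
  # k-NN density estimator is biased high for Poisson points
  expect_gt(mean(got), m / 25)
})

test_that("initial density estimation inverts the forward cluster-density model", {
  model <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  f_end <- 10000
  g <- function(l, f) (1 - exp(-l * (f - 1))) / l
  forward <- function(rho0) {
    rho0 * model$k_off * (1 - model$p_miss) * model$tau *
      (g(model$lambda1, f_end) - g(model$lambda2, f_end))
  }
  expect_equal(estimate_rho0_local(forward(10), model, f_end), 10,
               tolerance = 1e-12)
  expect_equal(estimate_rho0_local(forward(0.3), model, f_end), 0.3,
               tolerance = 1e-12)
  # vanishing duty cycle makes the inversion undefined
  expect_error(estimate_rho0_local(1, kinetic_model(0, 0.5, 0.2, 0), 100),
               "tau")
})

test_that("on/off densities start at zero and keep the rate ratio", {
  model <- kinetic_model(0.005, 0.5, 0.2, 0.01)
  d1 <- rho_on_off(10, model, 1)
  expect_equal(d1$rho_on, 0)
  expect_equal(d1$rho_off, 0)
  d <- rho_on_off(10, model, c(2, 10, 1000))
  expect_equal(d$rho_off / d$rho_on, rep(0.5 / 0.005, 3), tolerance = 1e-12)
  # independent evaluation at f = 1000
  expected <- 10 * model$tau *
    (exp(-model$lambda1 * 999) - exp(-model$lambda2 * 999))
  expect_equal(rho_on_off(10, model, 1000)$rho_on, expected, tolerance = 1e-12)
  expect_warning(z <- rho_on_off(10, kinetic_model(0, 0.5, 0.2, 0), 5),
                 "k_on = 0")
  expect_equal(z$rho_off, 0)
})

test_that("the full estimation cascade runs on minimal input", {
  locs <- make_locs(1:3, c(0, 0.01, 0.02), c(0, 0, 0))
  kin <- estimate_kinetics(locs)
  expect_s3_class(kin, "kinetic_fit")
  expect_true(all(tidy(kin)$estimate >= 0))
  expect_identical(kin$n_clusters, 1L)
  expect_true(is.finite(kin$densities$rho0_local))
  expect_identical(nrow(glance(kin)), 1L)
})
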