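# Rate bounds: outside these a per-frame rate is physically meaningless at
# 1-frame time resolution.
RATE_MIN <- 1e-5
RATE_MAX <- 5
P_MISS_MAX <- 0.5

#' Three-state blinking kinetic model
#'
#' Emitters switch from a dark state to the visible on state at rate `k_on`,
#' back to the (reversible) off state at `k_off`, and to the irreversible
#' bleached state at `k_bleach`, all in units of frame^-1.  A visible emitter
#' fails to be localized with probability `p_miss` per frame.  The derived
#' quantities are the approximate duty cycle
#' `tau = k_on / (k_on + k_off + k_bleach)` and the decay constants of the
#' on-state density, `lambda1 = k_bleach * tau` and
#' `lambda2 = k_on + k_off + k_bleach - lambda1`.
#'
#' @param k_on,k_off,k_bleach Transition rates, frame^-1 (>= 0).
#' @param p_miss Per-frame miss probability in `[0, 1)`.
#' @return An object of class `kinetic_model`: a list with the four
#'   parameters plus `tau`, `lambda1`, `lambda2`.
#' @export
kinetic_model <- function(k_on, k_off, k_bleach, p_miss = 0) {
  stopifnot(k_on >= 0, k_off >= 0, k_bleach >= 0, p_miss >= 0, p_miss < 1)
  ksum <- k_on + k_off + k_bleach
  tau <- if (ksum > 0) k_on / ksum else 0
  lambda1 <- k_bleach * tau
  structure(
    list(k_on = k_on, k_off = k_off, k_bleach = k_bleach, p_miss = p_miss,
         tau = tau, lambda1 = lambda1, lambda2 = ksum - lambda1),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Blinking kinetic model (rates in frame^-1):\n")
  cat(sprintf("  k_on = %.5g  k_off = %.5g  k_bleach = %.5g  p_miss = %.4g\n",
              x$k_on, x$k_off, x$k_bleach, x$p_miss))
  cat(sprintf("  duty cycle tau = %.5g  lambda1 = %.5g  lambda2 = %.5g\n",
              x$tau, x$lambda1, x$lambda2))
  invisible(x)
}

#' Estimate the summed off + bleach rate from cluster durations
#'
#' Blinking-event durations (in frames) are geometric with per-frame
#' off-switching probability `1 - exp(-(k_off + k_bleach))`, so the summed
#' rate is recovered from the mean duration as `-log(1 - 1/mean(N))`,
#' clamped to `[1e-5, 5]` frame^-1.
#'
#' @param durations Integer vector of cluster durations, each >= 1 frame.
#' @return The estimated `k_off + k_bleach`, frame^-1.
#' @export
estimate_off_plus_bleach <- function(durations) {
  stopifnot(length(durations) > 0, all(durations >= 1))
  nbar <- mean(durations)
  if (nbar <= 1) {
    warn("all clusters are single-frame; off+bleach rate clamped at upper bound")
    return(RATE_MAX)
  }
  min(max(-log(1 - 1 / nbar), RATE_MIN), RATE_MAX)
}

#' Estimate the per-frame miss probability
#'
#' A miss leaves a frame gap inside a cluster, so the fill fraction
#' `n_c / N` (localizations per spanned frame) falls below 1; `p_miss` is
#' estimated as one minus the mean fill fraction over preclusters, clamped
#' to `[0, 0.5]`.
#'
#' @param locs A preclustered localization tibble (see [precluster()]).
#' @return Estimated miss probability.
#' @export
estimate_p_miss <- function(locs) {
  pc <- precluster_summary(locs)
  min(max(1 - mean(pc$n_c / pc$N), 0), P_MISS_MAX)
}

#' Estimate the off rate from cluster counts
#'
#' The cumulative number of preclusters grows as `k_off` times the cumulative
#' number of localizations, so `k_off` is estimated as the ratio of total
#' precluster count to total localization count.
#'
#' @param n_clusters Number of preclusters.
#' @param n Number of localizations.
#' @return Estimated `k_off`, frame^-1.
#' @export
estimate_k_off <- function(n_clusters, n) {
  if (n == 0) abort("k_off estimate undefined for n = 0 localizations")
  stopifnot(n >= n_clusters, n_clusters >= 1)
  min(n_clusters / n, RATE_MAX)
}

# (1 - exp(-lam * (f - 1))) / lam with the analytic lam -> 0 limit (f - 1)
.decay_bracket <- function(lam, f) {
  if (lam < 1e-12) return(f - 1)
  -expm1(-lam * (f - 1)) / lam
}

#' Expected cumulative localization count
#'
#' The expected number of localizations observed by frame `f` from
#' `N_emitters` emitters all starting dark, under the three-state model with
#' misses:
#' `N_emitters * (1 - p_miss) * tau * [(1 - exp(-lambda1 (f-1)))/lambda1 -
#'  (1 - exp(-lambda2 (f-1)))/lambda2]`.
#' Non-negative and non-decreasing in `f`; the `lambda1 = 0` case uses the
#' analytic limit `(f - 1)`.
#'
#' @param f Frame number(s), >= 1.
#' @param N_emitters Number of emitters at the start of the acquisition.
#' @param model A [kinetic_model()].
#' @return Expected cumulative count(s), same length as `f`.
#' @export
cumulative_localization_model <- function(f, N_emitters, model) {
  stopifnot(all(f >= 1))
  g1 <- vapply(f, function(fi) .decay_bracket(model$lambda1, fi), numeric(1))
  g2 <- vapply(f, function(fi) .decay_bracket(model$lambda2, fi), numeric(1))
  N_emitters * (1 - model$p_miss) * model$tau * (g1 - g2)
}

#' Per-frame cumulative localization counts
#'
#' @param locs A localization tibble.
#' @param n_frames Total frames; defaults to the last frame with data.
#' @return Integer vector of length `n_frames`: localizations observed by
#'   each frame.
#' @export
cumulative_counts <- function(locs, n_frames = max(locs$frame)) {
  cumsum(tabulate(locs$frame, nbins = n_frames))
}

#' Fit the on rate and emitter count to a cumulative count curve
#'
#' Least-squares fit of [cumulative_localization_model()] to an observed
#' cumulative localization count curve, with `k_off`, `k_bleach` and
#' `p_miss` held fixed.  The model is linear in `N_emitters`, so for each
#' candidate `k_on` the optimal emitter count has a closed form; `k_on` is
#' found by a log-spaced grid search over `[1e-4, 1]` frame^-1 followed by
#' local refinement.
#'
#' @param counts Non-decreasing per-frame cumulative counts (frame 1..F).
#' @param k_off,k_bleach Fixed rates, frame^-1.
#' @param p_miss Fixed miss probability.
#' @return A list with `k_on` (frame^-1) and `N_emitters`.
#' @export
fit_kon_nemitters <- function(counts, k_off, k_bleach, p_miss) {
  stopifnot(length(counts) >= 2, all(diff(counts) >= 0))
  if (max(counts) <= 0) abort("cannot fit an all-zero cumulative count curve")
  f <- seq_along(counts)
  shape <- function(k_on) {
    cumulative_localization_model(f, 1, kinetic_model(k_on, k_off, k_bleach, p_miss))
  }
  sse <- function(log_kon) {
    g <- shape(exp(log_kon))
    nem <- max(sum(counts * g) / sum(g^2), 1e-12)
    sum((counts - nem * g)^2)
  }
  grid <- log(exp(seq(log(1e-4), log(1), length.out = 40)))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  k_on <- min(max(exp(opt$minimum), RATE_MIN), RATE_MAX)
  g <- shape(k_on)
  list(k_on = k_on, N_emitters = max(sum(counts * g) / sum(g^2), 1e-12))
}

# chunked k-nearest-neighbor distances among points (cx, cy)
.knn_dist <- function(cx, cy, k) {
  m <- length(cx)
  out <- numeric(m)
  chunk <- max(1L, as.integer(2e6 / m))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    d2 <- outer(cx[idx], cx, "-")^2 + outer(cy[idx], cy, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf # self
    out[idx] <- sqrt(apply(d2, 1, function(r) sort(r, partial = k)[k]))
  }
  out
}

#' Local precluster density via k-nearest-neighbor distances
#'
#' For each precluster centroid, `rho_c = (k + 1) / (pi * r_k^2)` with `r_k`
#' the distance to the k-th nearest other precluster (default k = 2).  With
#' fewer than `k + 1` preclusters, or for a centroid whose k-th neighbor is
#' coincident with it, the global density `n_preclusters / roi_area` is used
#' (coincident centroids fall back to the nearest strictly positive
#' neighbor distance first).
#'
#' @param pc A precluster summary tibble ([precluster_summary()]).
#' @param k_neighbors Neighbor rank used (default 2).
#' @param roi_area ROI area in pixels^2 (for the global fallback).
#' @return `pc` with an added `rho_c` column, clusters/pixel^2.
#' @export
estimate_local_cluster_density <- function(pc, k_neighbors = 2, roi_area) {
  m <- nrow(pc)
  global <- m / roi_area
  if (m < k_neighbors + 1) {
    pc$rho_c <- rep(global, m)
    return(pc)
  }
  rk <- .knn_dist(pc$cx, pc$cy, k_neighbors)
  if (any(rk == 0)) {
    # coincident kth neighbor: use nearest strictly positive neighbor if any
    for (i in which(rk == 0)) {
      d <- sqrt((pc$cx - pc$cx[i])^2 + (pc$cy - pc$cy[i])^2)
      d <- d[d > 0]
      rk[i] <- if (length(d) > 0) min(d) else NA_real_
    }
  }
  rho <- (k_neighbors + 1) / (pi * rk^2)
  rho[!is.finite(rho)] <- global
  pc$rho_c <- rho
  pc
}

#' Initial local emitter density from precluster density
#'
#' Inverts the forward relation between the initial emitter density and the
#' density of preclusters accumulated by the last frame:
#' `rho_c = rho0 * k_off * (1 - p_miss) * tau * [(1 - exp(-lambda1 (f_end-1)))/
#'  lambda1 - (1 - exp(-lambda2 (f_end-1)))/lambda2]`.
#'
#' @param rho_c Precluster density, clusters/pixel^2.
#' @param model A [kinetic_model()] with `k_off > 0`.
#' @param f_end Last frame containing localizations (> 1).
#' @return Estimated initial emitter density `rho0_local`, emitters/pixel^2.
#' @export
estimate_rho0_local <- function(rho_c, model, f_end) {
  stopifnot(model$k_off > 0, f_end > 1)
  bracket <- .decay_bracket(model$lambda1, f_end) -
    .decay_bracket(model$lambda2, f_end)
  denom <- model$k_off * (1 - model$p_miss) * model$tau * bracket
  if (denom == 0) {
    part <- if (model$tau == 0) "duty cycle tau" else "decay bracket"
    abort(paste0("rho0 estimate undefined: ", part, " is zero"))
  }
  rho_c / denom
}

#' On- and off-state emitter densities at a frame
#'
#' `rho_on(f) = rho0_local * tau * (exp(-lambda1 (f-1)) - exp(-lambda2 (f-1)))`
#' and `rho_off(f) = rho_on(f) * k_off / k_on`.  Both vanish at `f = 1`
#' (all emitters start dark).
#'
#' @param rho0_local Initial emitter density, emitters/pixel^2.
#' @param model A [kinetic_model()].
#' @param f Frame number(s), >= 1.
#' @return A list with numeric vectors `rho_on` and `rho_off`.
#' @export
rho_on_off <- function(rho0_local, model, f) {
  stopifnot(all(f >= 1))
  rho_on <- rho0_local * model$tau *
    (exp(-model$lambda1 * (f - 1)) - exp(-model$lambda2 * (f - 1)))
  if (model$k_on == 0) {
    warn("k_on = 0: rho_off defined as 0")
    rho_off <- rep(0, length(f))
  } else {
    rho_off <- rho_on * model$k_off / model$k_on
  }
  list(rho_on = rho_on, rho_off = rho_off)
}

#' Self-calibrate blinking kinetics and local densities
#'
#' Runs the full estimation cascade on preclustered data: the summed
#' off+bleach rate from cluster durations, `p_miss` from cluster fill
#' fractions, `k_off` from the cluster/localization count ratio, `k_bleach`
#' by subtraction (floored at the rate lower bound), `k_on` and the emitter
#' count by fitting the cumulative-count model, and per-precluster local
#' densities.
#'
#' @param locs A localization tibble; preclustered first (with the given
#'   `max_frame_gap` and `n_sigma`) if no `precluster` column is present.
#' @param max_frame_gap,n_sigma Preclustering parameters (see [precluster()]).
#' @param k_neighbors Neighbor rank for local density (default 2).
#' @param roi ROI rectangle `c(x_min, x_max, y_min, y_max)`; defaults to the
#'   whole-pixel bounding box of the data (coordinates are pixel units, so a
#'   sub-pixel box would be degenerate).  Used for the global density
#'   fallback.
#' @return An object of class `kinetic_fit`: a list with the fitted
#'   `model` ([kinetic_model()]), `N_emitters`, counts `n` and `n_clusters`,
#'   `f_end`, and `densities` (a tibble with per-precluster `rho_c` and
#'   `rho0_local`).
#' @export
estimate_kinetics <- function(locs, max_frame_gap = 5, n_sigma = 5,
                              k_neighbors = 2, roi = NULL) {
  if (!"precluster" %in% names(locs)) {
    locs <- precluster(locs, max_frame_gap = max_frame_gap, n_sigma = n_sigma)
  }
  stopifnot(nrow(locs) > 0)
  if (is.null(roi)) {
    roi <- c(floor(min(locs$x)), ceiling(max(locs$x)),
             floor(min(locs$y)), ceiling(max(locs$y)))
  }
  roi_area <- max((roi[2] - roi[1]) * (roi[4] - roi[3]), .Machine$double.eps)
  pc <- precluster_summary(locs)
  n <- nrow(locs)
  n_clusters <- nrow(pc)
  f_end <- max(locs$frame)

  k_total <- estimate_off_plus_bleach(pc$N)
  p_miss <- estimate_p_miss(locs)
  k_off <- estimate_k_off(n_clusters, n)
  k_bleach <- k_total - k_off
  if (k_bleach < RATE_MIN) {
    warn("off-rate estimate exceeds the total off+bleach estimate; k_bleach floored")
    k_bleach <- RATE_MIN
  }
  counts <- cumulative_counts(locs, n_frames = f_end)
  fit <- fit_kon_nemitters(counts, k_off, k_bleach, p_miss)
  model <- kinetic_model(fit$k_on, k_off, k_bleach, p_miss)

  pc <- estimate_local_cluster_density(pc, k_neighbors, roi_area)
  if (f_end > 1) {
    pc$rho0_local <- estimate_rho0_local(pc$rho_c, model, f_end)
  } else {
    pc$rho0_local <- pc$rho_c # degenerate single-frame data
  }
  structure(
    list(model = model, N_emitters = fit$N_emitters, n = n,
         n_clusters = n_clusters, f_end = f_end, densities = pc),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic self-calibration from %d localizations in %d preclusters\n",
              x$n, x$n_clusters))
  print(x$model)
  cat(sprintf("  N_emitters = %.1f, f_end = %d\n", x$N_emitters, x$f_end))
  invisible(x)
}

#' @rdname estimate_kinetics
#' @param x A `kinetic_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_on", "k_off", "k_bleach", "p_miss", "tau",
             "lambda1", "lambda2", "N_emitters"),
    estimate = c(x$model$k_on, x$model$k_off, x$model$k_bleach,
                 x$model$p_miss, x$model$tau, x$model$lambda1,
                 x$model$lambda2, x$N_emitters)
  )
}

#' @rdname estimate_kinetics
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_clusters = x$n_clusters, f_end = x$f_end,
    N_emitters = x$N_emitters,
    median_rho0_local = stats::median(x$densities$rho0_local)
  )
}
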