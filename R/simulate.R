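#' Place emitters uniformly in a square ROI
#'
#' The emitter count is Poisson with mean `rho0 * roi_size^2` (at least 1),
#' positions i.i.d. uniform.
#'
#' @param rho0 Initial emitter density, emitters/pixel^2.
#' @param roi_size Side of the square ROI, pixels.
#' @param seed Optional RNG seed.
#' @return A tibble with `emitter_id`, `x`, `y`.
#' @export
place_uniform <- function(rho0, roi_size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rho0 * roi_size^2 >= 1)
  n <- max(1L, rpois(1, rho0 * roi_size^2))
  tibble::tibble(
    emitter_id = seq_len(n),
    x = runif(n, 0, roi_size),
    y = runif(n, 0, roi_size)
  )
}

#' Place dimerized emitter pairs on a grid
#'
#' One pair per requested separation, centered on a square grid with
#' `spacing` pixels between pair centers, so localizations from distinct
#' dimers are never candidates for connection.  Pair members are offset by
#' half the separation along x on either side of the grid point.
#'
#' @param separations Intra-pair separations, pixels (default 20 values
#'   uniformly spaced on 0.1..1).
#' @param roi_size Side of the square ROI, pixels.
#' @param spacing Grid spacing between pair centers, pixels (default 10).
#' @param seed Optional RNG seed (placement is deterministic; kept for
#'   interface symmetry).
#' @return A tibble with `emitter_id`, `x`, `y`, and `pair` index.
#' @export
place_dimers <- function(separations = seq(0.1, 1, length.out = 20),
                         roi_size = 50, spacing = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(separations > 0), spacing > max(separations))
  npair <- length(separations)
  ncol_grid <- max(1L, floor(roi_size / spacing))
  nrow_grid <- ceiling(npair / ncol_grid)
  if (nrow_grid * spacing > roi_size) {
    abort(sprintf(
      "dimer grid (%d x %d at spacing %g) does not fit a %g px ROI; increase roi_size",
      nrow_grid, ncol_grid, spacing, roi_size))
  }
  k <- seq_len(npair)
  gx <- ((k - 1) %% ncol_grid) * spacing + spacing / 2
  gy <- ((k - 1) %/% ncol_grid) * spacing + spacing / 2
  tibble::tibble(
    emitter_id = seq_len(2L * npair),
    x = as.vector(rbind(gx - separations / 2, gx + separations / 2)),
    y = as.vector(rbind(gy, gy)),
    pair = rep(k, each = 2)
  )
}

#' Simulate three-state blinking
#'
#' Each emitter starts in the dark (off) state at time 0 and follows the
#' off -> on (`k_on`), on -> off (`k_off`), on -> bleached (`k_bleach`)
#' chain.  In `"gillespie"` mode the chain is simulated exactly in
#' continuous time; in `"discrete"` mode a per-frame Markov chain is used
#' (leave-on probability `1 - exp(-(k_off + k_bleach))` per frame, branching
#' to bleaching with probability `k_bleach / (k_off + k_bleach)`), so on
#' intervals align with frame boundaries and blink durations are exactly
#' geometric.
#'
#' @param emitters Emitter tibble ([place_uniform()] / [place_dimers()]).
#' @param model Generative [kinetic_model()].
#' @param n_frames Number of frames (frame `f` spans time `(f-1, f]`).
#' @param mode `"gillespie"` (continuous, default) or `"discrete"`.
#' @param seed Optional RNG seed.
#' @return A tibble of on intervals: `emitter_id`, `t_start`, `t_end`
#'   (frame-unit times in `[0, n_frames]`, disjoint per emitter).
#' @export
simulate_blinking <- function(emitters, model, n_frames,
                              mode = c("gillespie", "discrete"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k_on <- model$k_on; k_off <- model$k_off; k_bleach <- model$k_bleach
  per_emitter <- vector("list", nrow(emitters))
  if (k_on > 0) {
    for (e_idx in seq_len(nrow(emitters))) {
      t <- 0
      t0 <- numeric(0); t1 <- numeric(0)
      repeat {
        if (mode == "gillespie") {
          t <- t + rexp(1, k_on)
          if (t >= n_frames) break
          dur <- rexp(1, k_off + k_bleach)
          t0 <- c(t0, t)
          t <- min(t + dur, n_frames)
          t1 <- c(t1, t)
        } else {
          # first on frame after a geometric number of dark frames
          f_on <- floor(t) + 1L + rgeom(1, 1 - exp(-k_on))
          if (f_on > n_frames) break
          dur <- 1L + rgeom(1, 1 - exp(-(k_off + k_bleach)))
          f_off <- min(f_on + dur - 1L, n_frames)
          t0 <- c(t0, f_on - 1)
          t1 <- c(t1, f_off)
          t <- f_off
        }
        if (t >= n_frames) break
        if (runif(1) < k_bleach / (k_off + k_bleach)) break # bleached
      }
      if (length(t0) > 0) {
        per_emitter[[e_idx]] <- list(e = emitters$emitter_id[e_idx],
                                     t0 = t0, t1 = t1)
      }
    }
  }
  per_emitter <- per_emitter[!vapply(per_emitter, is.null, logical(1))]
  tibble::tibble(
    emitter_id = unlist(lapply(per_emitter, function(p) rep(p$e, length(p$t0)))) %||% integer(0),
    t_start = unlist(lapply(per_emitter, `[[`, "t0")) %||% numeric(0),
    t_end = unlist(lapply(per_emitter, `[[`, "t1")) %||% numeric(0)
  )
}

# Localization precision: CRLB of fitting a pixel-integrated symmetric
# Gaussian PSF with uniform background over a finite window.  Vectorized
# over photon counts.
crlb_sigma <- function(photons, background, psf_sigma, window = 7) {
  half <- window / 2
  edges <- seq(-half, half, by = 1)
  E <- diff(pnorm(edges, 0, psf_sigma))
  dE <- -diff(dnorm(edges, 0, psf_sigma))
  info <- numeric(length(photons))
  for (k in seq_len(window)) {
    for (l in seq_len(window)) {
      mu <- photons * E[k] * E[l] + background
      info <- info + (photons * dE[k] * E[l])^2 / mu
    }
  }
  ifelse(photons > 0, 1 / sqrt(info), Inf)
}

#' Convert blinking intervals to noisy localizations
#'
#' Every (on interval, frame) overlap yields one localization.  Frames fully
#' covered by the interval carry the nominal photon count `I`; frames where
#' the emitter turned on, off, or bleached carry `I * (1 - u)` with
#' `u ~ Uniform(0, 1)`.  Per-axis Gaussian noise is added with standard
#' deviation `sqrt(crlb^2 + extra_noise_sigma^2)` where the CRLB term is the
#' precision of fitting a pixel-integrated Gaussian PSF at that photon count
#' and background.  The *reported* `sigma_x` / `sigma_y` is the CRLB alone:
#' the extra term emulates noise sources (such as residual uncorrected
#' drift) that a localization fitter cannot account for, so it is
#' deliberately absent from the reported precision.
#'
#' @param truth On-interval tibble from [simulate_blinking()].
#' @param emitters Emitter position tibble.
#' @param n_frames Number of frames.
#' @param photons_per_frame Nominal photons per fully-on frame.
#' @param background Background, photons/pixel/frame.
#' @param psf_sigma PSF width, pixels.
#' @param extra_noise_sigma Residual noise (e.g. uncorrected drift), pixels.
#' @param seed Optional RNG seed.
#' @return A localization tibble with ground-truth `emitter_id`.
#' @export
intervals_to_localizations <- function(truth, emitters, n_frames,
                                       photons_per_frame = 1000,
                                       background = 5, psf_sigma = 1,
                                       extra_noise_sigma = 0.05,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(truth) == 0) return(empty_localizations())
  # expand each interval to the frames it touches
  f_first <- pmax(floor(truth$t_start) + 1L, 1L)
  f_last <- pmin(ceiling(truth$t_end), n_frames)
  reps <- pmax(f_last - f_first + 1L, 0L)
  keep <- reps > 0
  idx <- rep(which(keep), reps[keep])
  frame <- unlist(lapply(which(keep), function(i) f_first[i]:f_last[i]),
                  use.names = FALSE)
  partial <- truth$t_start[idx] > frame - 1 | truth$t_end[idx] < frame
  photons <- rep(photons_per_frame, length(idx))
  photons[partial] <- photons_per_frame * (1 - runif(sum(partial)))
  drop <- photons <= 0
  if (any(drop)) {
    idx <- idx[!drop]; frame <- frame[!drop]; photons <- photons[!drop]
  }
  crlb <- crlb_sigma(photons, background, psf_sigma)
  noise_sd <- sqrt(crlb^2 + extra_noise_sigma^2)
  pos <- emitters[match(truth$emitter_id[idx], emitters$emitter_id), ]
  as_localizations(tibble::tibble(
    frame = frame,
    x = pos$x + rnorm(length(idx), 0, noise_sd),
    y = pos$y + rnorm(length(idx), 0, noise_sd),
    sigma_x = crlb,
    sigma_y = crlb,
    photons = photons,
    background = background,
    emitter_id = truth$emitter_id[idx]
  ))
}

#' Randomly drop a fraction of localizations
#'
#' Removes `round(p_miss * n)` uniformly chosen records, emulating
#' localizations missed in processing.
#'
#' @param locs A localization tibble.
#' @param p_miss Miss probability in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return The thinned localization tibble (ids renumbered).
#' @export
apply_miss_probability <- function(locs, p_miss, seed = NULL) {
  stopifnot(p_miss >= 0, p_miss < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(locs)
  n_drop <- round(p_miss * n)
  if (n_drop > 0) {
    locs <- locs[-sample.int(n, n_drop), ]
    locs$id <- seq_len(nrow(locs))
  }
  locs
}

#' Simulate an SMLM acquisition with ground truth
#'
#' End-to-end generator: place emitters (uniform density or dimer pairs),
#' simulate three-state blinking, convert on intervals to CRLB-calibrated
#' noisy localizations, and thin by the miss probability.  Defaults are the
#' study conditions used throughout the package's validation: `k_on` =
#' 0.005, `k_off` = 0.5, `k_bleach` = 0.2 frame^-1, `p_miss` = 0.01,
#' 1000 photons/frame, 0.05 px residual noise, 10,000 frames.
#'
#' @param geometry `"uniform"` or `"dimer"`.
#' @param rho0 Initial emitter density, emitters/pixel^2 (uniform geometry).
#' @param dimer_separations Pair separations, pixels (dimer geometry).
#' @param dimer_spacing Grid spacing between pairs, pixels.
#' @param roi_size Side of the square ROI, pixels.
#' @param n_frames Number of frames.
#' @param k_on,k_off,k_bleach Generative rates, frame^-1.
#' @param p_miss Miss probability.
#' @param photons_per_frame Photons per fully-on frame.
#' @param background Background, photons/pixel/frame.
#' @param psf_sigma PSF width, pixels.
#' @param extra_noise_sigma Residual localization noise, pixels.
#' @param kinetics_mode `"gillespie"` (continuous-time, default) or
#'   `"discrete"` (frame-aligned; blink durations exactly geometric).
#' @param seed Optional RNG seed for the whole simulation.
#' @return An object of class `smlm_sim`: list with `localizations` (a
#'   localization tibble), `emitters` (ground-truth positions), `truth`
#'   (on intervals), and `config`.
#' @export
simulate_smlm <- function(geometry = c("uniform", "dimer"), rho0 = 10,
                          dimer_separations = seq(0.1, 1, length.out = 20),
                          dimer_spacing = 10, roi_size = 16,
                          n_frames = 10000, k_on = 0.005, k_off = 0.5,
                          k_bleach = 0.2, p_miss = 0.01,
                          photons_per_frame = 1000, background = 5,
                          psf_sigma = 1, extra_noise_sigma = 0.05,
                          kinetics_mode = c("gillespie", "discrete"),
                          seed = NULL) {
  geometry <- match.arg(geometry)
  kinetics_mode <- match.arg(kinetics_mode)
  if (!is.null(seed)) set.seed(seed)
  model <- kinetic_model(k_on, k_off, k_bleach, p_miss)
  emitters <- if (geometry == "uniform") {
    place_uniform(rho0, roi_size)
  } else {
    place_dimers(dimer_separations, roi_size, dimer_spacing)
  }
  truth <- simulate_blinking(emitters, model, n_frames, mode = kinetics_mode)
  locs <- intervals_to_localizations(
    truth, emitters, n_frames, photons_per_frame = photons_per_frame,
    background = background, psf_sigma = psf_sigma,
    extra_noise_sigma = extra_noise_sigma
  )
  locs <- apply_miss_probability(locs, p_miss)
  structure(
    list(localizations = locs, emitters = emitters, truth = truth,
         config = list(geometry = geometry, rho0 = rho0,
                       roi_size = roi_size, n_frames = n_frames,
                       model = model, photons_per_frame = photons_per_frame,
                       background = background, psf_sigma = psf_sigma,
                       extra_noise_sigma = extra_noise_sigma,
                       kinetics_mode = kinetics_mode, seed = seed)),
    class = "smlm_sim"
  )
}

#' @export
print.smlm_sim <- function(x, ...) {
  cat(sprintf("SMLM simulation (%s, %s kinetics): %d emitters, %d frames, %d localizations\n",
              x$config$geometry, x$config$kinetics_mode, nrow(x$emitters),
              x$config$n_frames, nrow(x$localizations)))
  invisible(x)
}
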