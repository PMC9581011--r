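# Greedy chaining engine shared by the three baseline connectors.
# Localizations are visited in (frame, id) order; each may join an open
# chain whose last member lies 1..max_frame_gap frames in the past (so a
# chain never holds two same-frame localizations) and which passes the
# method's distance rule against the chain's inverse-variance running
# centroid.  Ties between eligible chains go to the smallest rule score.
.greedy_chain <- function(locs, max_frame_gap, accept) {
  locs <- as_localizations(locs)
  n <- nrow(locs)
  if (n == 0) return(.bind_combined(list()))
  ord <- order(locs$frame, locs$id)
  frame <- locs$frame[ord]
  x <- locs$x[ord]; y <- locs$y[ord]
  wx <- 1 / locs$sigma_x[ord]^2; wy <- 1 / locs$sigma_y[ord]^2

  # open chain state (parallel vectors)
  cSx <- numeric(0); cWx <- numeric(0)
  cSy <- numeric(0); cWy <- numeric(0)
  cLast <- integer(0); cId <- integer(0)
  n_chain <- 0L
  member_of <- integer(n)

  for (i in seq_len(n)) {
    pick <- NA_integer_
    if (n_chain > 0) {
      gap_ok <- which(frame[i] - cLast >= 1L & frame[i] - cLast <= max_frame_gap)
      if (length(gap_ok) > 0) {
        score <- accept(
          dx = x[i] - cSx[gap_ok] / cWx[gap_ok],
          dy = y[i] - cSy[gap_ok] / cWy[gap_ok],
          var_cx = 1 / cWx[gap_ok], var_cy = 1 / cWy[gap_ok],
          var_lx = 1 / wx[i], var_ly = 1 / wy[i]
        )
        ok <- which(is.finite(score))
        if (length(ok) > 0) pick <- gap_ok[ok[which.min(score[ok])]]
      }
    }
    if (is.na(pick)) {
      n_chain <- n_chain + 1L
      cSx <- c(cSx, x[i] * wx[i]); cWx <- c(cWx, wx[i])
      cSy <- c(cSy, y[i] * wy[i]); cWy <- c(cWy, wy[i])
      cLast <- c(cLast, frame[i]); cId <- c(cId, n_chain)
      member_of[i] <- n_chain
    } else {
      cSx[pick] <- cSx[pick] + x[i] * wx[i]; cWx[pick] <- cWx[pick] + wx[i]
      cSy[pick] <- cSy[pick] + y[i] * wy[i]; cWy[pick] <- cWy[pick] + wy[i]
      cLast[pick] <- frame[i]
      member_of[i] <- cId[pick]
    }
    # retire chains that can no longer accept members (all future frames
    # are >= frame[i], so a gap already exceeding the limit never shrinks)
    live <- frame[i] - cLast <= max_frame_gap
    if (!all(live)) {
      cSx <- cSx[live]; cWx <- cWx[live]; cSy <- cSy[live]; cWy <- cWy[live]
      cLast <- cLast[live]; cId <- cId[live]
    }
  }
  rows_by_chain <- split(ord, member_of)
  .bind_combined(lapply(rows_by_chain, function(r) .combine_rows(locs, r)))
}

#' Classical frame connection
#'
#' The hard-threshold connector: a localization joins an open chain when it
#' lies within `max_distance` pixels of the chain's running inverse-variance
#' centroid and within `max_frame_gap` frames of the chain's last member
#' (defaults 0.2 px / 1 frame).  Chains are combined with the same
#' maximum-likelihood operator as LAP-FC ([combine_cluster()]).
#'
#' @param locs A localization tibble.
#' @param max_frame_gap Maximum frame gap, frames.
#' @param max_distance Maximum separation, pixels.
#' @return A combined localization tibble.
#' @export
frame_connect_classical <- function(locs, max_frame_gap = 1,
                                    max_distance = 0.2) {
  stopifnot(max_frame_gap >= 1, max_distance > 0)
  .greedy_chain(locs, max_frame_gap, function(dx, dy, ...) {
    d <- sqrt(dx^2 + dy^2)
    ifelse(d <= max_distance, d, Inf)
  })
}

#' Revised classical frame connection
#'
#' As [frame_connect_classical()] but with a precision-scaled threshold:
#' the separation must not exceed `n_sigma` times the symmetric combined
#' error `sqrt(sbar_loc^2 + sbar_chain^2)` with
#' `sbar^2 = (sigma_x^2 + sigma_y^2)/2` (defaults 2 sigma / 5 frames).
#'
#' @inheritParams frame_connect_classical
#' @param n_sigma Threshold multiplier of the combined localization error.
#' @return A combined localization tibble.
#' @export
frame_connect_revised_classical <- function(locs, max_frame_gap = 5,
                                            n_sigma = 2) {
  stopifnot(max_frame_gap >= 1, n_sigma > 0)
  .greedy_chain(locs, max_frame_gap,
                function(dx, dy, var_cx, var_cy, var_lx, var_ly) {
    d <- sqrt(dx^2 + dy^2)
    s_pair <- sqrt((var_lx + var_ly) / 2 + (var_cx + var_cy) / 2)
    r <- d / (n_sigma * s_pair)
    ifelse(r <= 1, r, Inf)
  })
}

#' Hypothesis-test frame connection
#'
#' Prefiltered like the classical connector (`max_distance`,
#' `max_frame_gap`; defaults 1 px / 5 frames), but the accept rule tests the
#' null hypothesis that candidate and chain observe the same emitter under
#' Gaussian localization noise: the statistic
#' `s = dx^2 / (var_x) + dy^2 / (var_y)` (per-axis summed variances of
#' candidate and chain centroid) is chi-square with 2 degrees of freedom
#' under the null, and the candidate connects iff the p-value is `>= alpha`.
#'
#' @inheritParams frame_connect_classical
#' @param alpha Level of significance.
#' @return A combined localization tibble.
#' @export
frame_connect_hypothesis_test <- function(locs, max_frame_gap = 5,
                                          max_distance = 1, alpha = 0.05) {
  stopifnot(max_frame_gap >= 1, max_distance > 0, alpha > 0, alpha < 1)
  .greedy_chain(locs, max_frame_gap,
                function(dx, dy, var_cx, var_cy, var_lx, var_ly) {
    d <- sqrt(dx^2 + dy^2)
    s <- dx^2 / (var_lx + var_cx) + dy^2 / (var_ly + var_cy)
    p <- pchisq(s, df = 2, lower.tail = FALSE)
    ifelse(d <= max_distance & p >= alpha, s, Inf)
  })
}
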