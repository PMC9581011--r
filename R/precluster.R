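#' Group localizations into spatiotemporal preclusters
#'
#' Preclusters are the candidate sets inside which the assignment problem is
#' solved: each localization, visited in (frame, id) order, looks for its
#' spatial nearest neighbor among localizations in earlier frames within
#' `max_frame_gap` frames and within `n_sigma` combined localization errors,
#' and joins that neighbor's cluster (or founds a new one when no eligible
#' neighbor exists).  Localizations in the same frame can end up in the same
#' precluster only through chains via other frames.
#'
#' The distance threshold is `n_sigma` times the *query's own* localization
#' error `sbar = sqrt((sigma_x^2 + sigma_y^2) / 2)` — each localization
#' searches within a multiplier of its error.  Ties between equidistant
#' neighbors go to the smaller id.
#'
#' @param locs A localization tibble (see [localizations]).
#' @param max_frame_gap Maximum frame gap to an eligible neighbor (default 5).
#' @param n_sigma Distance threshold in combined-error units (default 5).
#' @return `locs` with an added integer `precluster` column labelling the
#'   partition (labels are 1..n_preclusters in order of founding).
#' @export
precluster <- function(locs, max_frame_gap = 5, n_sigma = 5) {
  stopifnot(max_frame_gap >= 1, n_sigma > 0)
  locs <- as_localizations(locs)
  n <- nrow(locs)
  if (n == 0) {
    locs$precluster <- integer(0)
    return(locs)
  }
  ord <- order(locs$frame, locs$id)
  x <- locs$x[ord]; y <- locs$y[ord]
  frame <- locs$frame[ord]; id <- locs$id[ord]
  sbar2 <- (locs$sigma_x[ord]^2 + locs$sigma_y[ord]^2) / 2

  # row indices (in processing order) per frame, for candidate lookup
  frames_seen <- split(seq_len(n), frame)
  fkeys <- as.integer(names(frames_seen))

  cluster <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    f <- frame[i]
    sel <- fkeys >= f - max_frame_gap & fkeys <= f - 1L
    j <- NA_integer_
    if (any(sel)) {
      cand <- unlist(frames_seen[sel], use.names = FALSE)
      d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      ok <- d2 <= n_sigma^2 * sbar2[i]
      if (any(ok)) {
        cand <- cand[ok]; d2 <- d2[ok]
        best <- d2 == min(d2)
        j <- cand[best][which.min(id[cand[best]])]
      }
    }
    if (is.na(j)) {
      next_label <- next_label + 1L
      cluster[i] <- next_label
    } else {
      cluster[i] <- cluster[j]
    }
  }
  locs$precluster <- integer(n)
  locs$precluster[ord] <- cluster
  locs
}

#' Summarize preclusters
#'
#' @param locs A preclustered localization tibble (output of [precluster()]).
#' @return One row per precluster: `precluster`, member count `n_c`,
#'   `frame_start`, `frame_end`, duration `N = frame_end - frame_start + 1`,
#'   and the centroid (`cx`, `cy`, unweighted mean position).
#' @export
precluster_summary <- function(locs) {
  stopifnot("precluster" %in% names(locs))
  locs |>
    dplyr::group_by(.data$precluster) |>
    dplyr::summarise(
      n_c = dplyr::n(),
      frame_start = min(.data$frame),
      frame_end = max(.data$frame),
      N = max(.data$frame) - min(.data$frame) + 1L,
      cx = mean(.data$x),
      cy = mean(.data$y),
      .groups = "drop"
    )
}

#' Precluster durations in frames
#'
#' The duration of a precluster is the span of its member frames,
#' `frame_end - frame_start + 1`; these durations drive the off+bleach rate
#' estimator (see [estimate_off_plus_bleach()]).
#'
#' @inheritParams precluster_summary
#' @return An integer vector of durations, one per precluster.
#' @export
precluster_durations <- function(locs) {
  stopifnot(nrow(locs) > 0)
  precluster_summary(locs)$N
}
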