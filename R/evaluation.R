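#' Ground-truth ideal frame connection
#'
#' The scoring reference: localizations of the same ground-truth emitter are
#' chained transitively whenever consecutive localizations (in frame order)
#' are at most `max_frame_gap` frames apart, and each chain is combined with
#' the maximum-likelihood operator ([combine_cluster()]).
#'
#' @param locs A localization tibble with every `emitter_id >= 0`.
#' @param max_frame_gap Chaining gap, frames (default 5).
#' @return A combined localization tibble.
#' @export
ideal_frame_connection <- function(locs, max_frame_gap = 5) {
  locs <- as_localizations(locs)
  if (any(locs$emitter_id < 0)) {
    abort("ideal frame connection requires ground-truth emitter_id for every localization")
  }
  if (nrow(locs) == 0) return(.bind_combined(list()))
  parts <- list()
  np <- 0L
  for (rows in split(seq_len(nrow(locs)), locs$emitter_id)) {
    rows <- rows[order(locs$frame[rows], locs$id[rows])]
    gaps <- diff(locs$frame[rows])
    chain_id <- cumsum(c(1L, as.integer(gaps > max_frame_gap)))
    for (ch in split(rows, chain_id)) {
      np <- np + 1L
      parts[[np]] <- .combine_rows(locs, ch)
    }
  }
  .bind_combined(parts)
}

#' Nearest-neighbor distances within a frame window
#'
#' For each localization, the distance to its spatially nearest neighbor
#' among localizations `1..max_frame_gap` frames away in either direction
#' (same-frame neighbors excluded).  Localizations with no such neighbor
#' contribute nothing.
#'
#' @param locs A localization tibble.
#' @param max_frame_gap Temporal window, frames (default 5).
#' @return A numeric vector of distances, pixels (one per localization that
#'   has an eligible neighbor).
#' @export
nn_distances <- function(locs, max_frame_gap = 5) {
  n <- nrow(locs)
  if (n < 2) return(numeric(0))
  frames_seen <- split(seq_len(n), locs$frame)
  fkeys <- as.integer(names(frames_seen))
  x <- locs$x; y <- locs$y; frame <- locs$frame
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- fkeys >= frame[i] - max_frame_gap & fkeys <= frame[i] + max_frame_gap &
      fkeys != frame[i]
    if (!any(sel)) next
    cand <- unlist(frames_seen[sel], use.names = FALSE)
    out[i] <- sqrt(min((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
  }
  out[!is.na(out)]
}

#' Binned empirical CDF of nearest-neighbor distances
#'
#' @param distances Distance sample, pixels (non-empty).
#' @param bin_width Bin width, pixels (default 0.01).
#' @param max_r Largest binned distance, pixels (default 2).
#' @return A tibble with bin upper edges `r` and CDF values `F`
#'   (`F[b]` = fraction of distances `<= r[b]`).
#' @export
binned_cdf <- function(distances, bin_width = 0.01, max_r = 2) {
  if (length(distances) == 0) abort("cannot bin an empty distance sample")
  edges <- seq(bin_width, max_r, by = bin_width)
  tibble::tibble(
    r = edges,
    F = vapply(edges, function(e) mean(distances <= e), numeric(1))
  )
}

#' Deviation of a CDF from the ideal CDF
#'
#' `delta = F - F_ideal` per bin.  `delta < 0` suggests over-connection
#' (merging localizations of distinct emitters inflates nearest-neighbor
#' distances), `delta > 0` under-connection.
#'
#' @param curve,ideal Tibbles from [binned_cdf()] on identical bin grids.
#' @return `curve` with an added `delta` column.
#' @export
cdf_deviation <- function(curve, ideal) {
  if (nrow(curve) != nrow(ideal) || any(abs(curve$r - ideal$r) > 1e-12)) {
    abort("CDF deviation requires identical bin grids")
  }
  curve$delta <- curve$F - ideal$F
  curve
}

#' Histogram of frame-connected durations
#'
#' @param connected A combined localization tibble (with `frame_first`,
#'   `frame_last`).
#' @return A tibble with duration `N` (frames) and `count`.
#' @export
duration_histogram <- function(connected) {
  stopifnot(nrow(connected) > 0)
  N <- connected$frame_last - connected$frame_first + 1L
  tb <- table(N)
  tibble::tibble(N = as.integer(names(tb)), count = as.integer(tb))
}

#' Expected blink-duration pmf
#'
#' Blinking-event durations are geometric with per-frame stop probability
#' `p = 1 - exp(-k)`, `k = k_off + k_bleach`: `P(N = j) = p (1-p)^(j-1)`.
#'
#' @param k Summed off + bleach rate, frame^-1.
#' @param N Durations at which to evaluate (default 1..50).
#' @return A tibble with `N` and probability `p`.
#' @export
expected_duration_pmf <- function(k, N = 1:50) {
  p <- 1 - exp(-k)
  tibble::tibble(N = as.integer(N), p = p * (1 - p)^(N - 1))
}

#' Evaluate frame-connection methods against the ideal result
#'
#' Runs each connector on each simulation, computes the nearest-neighbor
#' distance CDF of its output pooled across simulations, and the deviation
#' `delta` from the pooled ideal-connection CDF; also pools duration
#' histograms per method.
#'
#' @param sims A list of `smlm_sim` objects (or a single one).
#' @param methods Character vector of connector names (see [frame_connect()]).
#' @param max_frame_gap Frame window for the nearest-neighbor statistic and
#'   the ideal connection (default 5).
#' @param bin_width,max_r CDF binning (see [binned_cdf()]).
#' @param method_args Named list of per-method argument lists passed on to
#'   the connectors.
#' @return An object of class `fc_evaluation`: list with `curves` (tibble:
#'   `method`, `r`, `F`, `delta`), `durations` (tibble: `method`, `N`,
#'   `count`; includes `"ideal"`), and `n_pairs` (pooled sample sizes).
#' @export
evaluate_methods <- function(sims,
                             methods = c("lapfc", "classical",
                                         "revised_classical",
                                         "hypothesis_test"),
                             max_frame_gap = 5, bin_width = 0.01, max_r = 2,
                             method_args = list()) {
  if (inherits(sims, "smlm_sim")) sims <- list(sims)
  dist_pool <- c(list(ideal = numeric(0)),
                 setNames(rep(list(numeric(0)), length(methods)), methods))
  dur_pool <- list()
  for (s in seq_along(sims)) {
    locs <- sims[[s]]$localizations
    ideal <- ideal_frame_connection(locs, max_frame_gap = max_frame_gap)
    dist_pool$ideal <- c(dist_pool$ideal, nn_distances(ideal, max_frame_gap))
    dur_pool[[length(dur_pool) + 1L]] <-
      dplyr::mutate(duration_histogram(ideal), method = "ideal")
    for (m in methods) {
      conn <- do.call(frame_connect,
                      c(list(locs = locs, method = m), method_args[[m]]))
      dist_pool[[m]] <- c(dist_pool[[m]], nn_distances(conn, max_frame_gap))
      dur_pool[[length(dur_pool) + 1L]] <-
        dplyr::mutate(duration_histogram(conn), method = m)
    }
  }
  ideal_cdf <- binned_cdf(dist_pool$ideal, bin_width, max_r)
  curves <- purrr::map_dfr(methods, function(m) {
    cv <- cdf_deviation(binned_cdf(dist_pool[[m]], bin_width, max_r), ideal_cdf)
    dplyr::mutate(cv, method = m, .before = 1)
  })
  durations <- dplyr::bind_rows(dur_pool) |>
    dplyr::group_by(.data$method, .data$N) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(
    list(curves = curves, durations = durations,
         ideal_cdf = ideal_cdf,
         n_pairs = vapply(dist_pool, length, integer(1))),
    class = "fc_evaluation"
  )
}

#' @export
print.fc_evaluation <- function(x, ...) {
  worst <- x$curves |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(max_abs_delta = max(abs(.data$delta)),
                     min_delta = min(.data$delta), .groups = "drop")
  cat("Frame-connection evaluation against the ideal result:\n")
  print(as.data.frame(worst), row.names = FALSE)
  invisible(x)
}
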