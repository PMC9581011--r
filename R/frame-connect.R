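# Inverse-variance (maximum-likelihood) combination of a set of localization
# rows: per-axis weighted mean position with Fisher-information error,
# photons summed, background averaged.  Shared by every connector.
.combine_rows <- function(locs, rows) {
  wx <- 1 / locs$sigma_x[rows]^2
  wy <- 1 / locs$sigma_y[rows]^2
  eid <- unique(locs$emitter_id[rows])
  frames <- locs$frame[rows]
  list(
    frame = min(frames),
    x = sum(locs$x[rows] * wx) / sum(wx),
    y = sum(locs$y[rows] * wy) / sum(wy),
    sigma_x = sqrt(1 / sum(wx)),
    sigma_y = sqrt(1 / sum(wy)),
    photons = sum(locs$photons[rows]),
    background = mean(locs$background[rows]),
    emitter_id = if (length(eid) == 1) eid else -1L,
    frame_first = min(frames),
    frame_last = max(frames),
    n_members = length(rows),
    member_ids = list(sort(locs$id[rows]))
  )
}

.bind_combined <- function(parts) {
  parts <- unname(parts)
  if (length(parts) == 0) {
    return(tibble::tibble(
      id = integer(), frame = integer(), x = numeric(), y = numeric(),
      sigma_x = numeric(), sigma_y = numeric(), photons = numeric(),
      background = numeric(), emitter_id = integer(),
      frame_first = integer(), frame_last = integer(),
      n_members = integer(), member_ids = list()
    ))
  }
  out <- tibble::tibble(
    frame = vapply(parts, `[[`, integer(1), "frame"),
    x = vapply(parts, `[[`, numeric(1), "x"),
    y = vapply(parts, `[[`, numeric(1), "y"),
    sigma_x = vapply(parts, `[[`, numeric(1), "sigma_x"),
    sigma_y = vapply(parts, `[[`, numeric(1), "sigma_y"),
    photons = vapply(parts, `[[`, numeric(1), "photons"),
    background = vapply(parts, `[[`, numeric(1), "background"),
    emitter_id = vapply(parts, `[[`, integer(1), "emitter_id"),
    frame_first = vapply(parts, `[[`, integer(1), "frame_first"),
    frame_last = vapply(parts, `[[`, integer(1), "frame_last"),
    n_members = vapply(parts, `[[`, integer(1), "n_members"),
    member_ids = lapply(parts, function(p) p$member_ids[[1]])
  )
  out <- out[order(out$frame_first, out$x, out$y), ]
  out$id <- seq_len(nrow(out))
  out[c("id", setdiff(names(out), "id"))]
}

#' Combine the localizations of one cluster
#'
#' Maximum-likelihood combination of `m` independent Gaussian observations of
#' one position: per axis, the inverse-variance weighted mean
#' `x_hat = sum(x_i / sigma_i^2) / sum(1 / sigma_i^2)` with combined error
#' `sigma_hat^2 = 1 / sum(1 / sigma_i^2)` (the inverse Fisher information).
#' Photons are summed, background averaged, the canonical frame is the first
#' member frame, and the ground-truth `emitter_id` is kept only when all
#' members agree.
#'
#' @param members Localization tibble of the cluster members (m >= 1 rows).
#' @return A one-row combined localization tibble with the extra columns
#'   `frame_first`, `frame_last`, `n_members`, `member_ids`.
#' @export
combine_cluster <- function(members) {
  stopifnot(nrow(members) >= 1)
  .bind_combined(list(.combine_rows(members, seq_len(nrow(members)))))
}

#' Extract clusters from an assignment
#'
#' Selections in the upper-left connection block (row `i` to column `j`,
#' both `<= n_c`) are directed links `i -> j`; clusters are the resulting
#' chains, started by births and ended by deaths.  Every localization lands
#' in exactly one cluster.
#'
#' @param assignment Assignment vector from [solve_lap()].
#' @param n_c Number of localizations in the precluster.
#' @return A list of integer vectors of member indices (1..n_c).
#' @export
assignments_to_clusters <- function(assignment, n_c) {
  succ <- rep(NA_integer_, n_c)
  for (i in seq_len(n_c)) {
    j <- assignment[i]
    if (j <= n_c) {
      if (j == i) abort("malformed assignment: self-link")
      succ[i] <- j
    }
  }
  has_pred <- logical(n_c)
  has_pred[succ[!is.na(succ)]] <- TRUE
  starts <- which(!has_pred)
  clusters <- vector("list", length(starts))
  seen <- logical(n_c)
  for (k in seq_along(starts)) {
    chain <- integer(0)
    i <- starts[k]
    while (!is.na(i)) {
      if (seen[i]) abort("malformed assignment: cycle in links")
      seen[i] <- TRUE
      chain <- c(chain, i)
      i <- succ[i]
    }
    clusters[[k]] <- chain
  }
  if (!all(seen)) abort("malformed assignment: localization in no cluster")
  clusters
}

#' Frame connection via the linear assignment problem (LAP-FC)
#'
#' The full pipeline: precluster the localizations ([precluster()]),
#' self-calibrate blinking kinetics and local densities
#' ([estimate_kinetics()]), then for each precluster assemble the block cost
#' matrix ([build_cost_matrix()]), solve the assignment problem
#' ([solve_lap()]), extract the clusters, and combine each cluster into one
#' higher-precision localization ([combine_cluster()]).
#'
#' @param locs A localization tibble.
#' @param max_frame_gap,n_sigma Preclustering parameters.
#' @param model Optional [kinetic_model()] of externally prescribed rates;
#'   when `NULL` (default) rates are estimated from the data.  Local
#'   densities are always estimated from the data.
#' @param k_neighbors Neighbor rank for the local density estimate.
#' @param roi Optional ROI rectangle `c(x_min, x_max, y_min, y_max)`.
#' @return A combined localization tibble (see [combine_cluster()] for
#'   columns), with the kinetic fit and per-precluster cluster counts
#'   attached as attribute `"diagnostics"`.
#' @export
frame_connect_lap <- function(locs, max_frame_gap = 5, n_sigma = 5,
                              model = NULL, k_neighbors = 2, roi = NULL) {
  locs <- as_localizations(locs)
  if (nrow(locs) == 0) {
    out <- .bind_combined(list())
    attr(out, "diagnostics") <- list(model = model, n_preclusters = 0L)
    return(out)
  }
  locs <- precluster(locs, max_frame_gap = max_frame_gap, n_sigma = n_sigma)
  kin <- estimate_kinetics(locs, k_neighbors = k_neighbors, roi = roi)
  if (is.null(model)) model <- kin$model
  rho0 <- setNames(kin$densities$rho0_local, kin$densities$precluster)
  # re-derive rho0 from rho_c under an externally prescribed model
  if (!identical(model, kin$model) && kin$f_end > 1) {
    rho0 <- setNames(
      estimate_rho0_local(kin$densities$rho_c, model, kin$f_end),
      kin$densities$precluster
    )
  }
  groups <- split(seq_len(nrow(locs)), locs$precluster)
  parts <- vector("list", 2L * length(groups))
  np <- 0L
  clusters_per_precluster <- integer(length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 1) {
      np <- np + 1L
      parts[[np]] <- .combine_rows(locs, rows)
      clusters_per_precluster[g] <- 1L
      next
    }
    ord <- rows[order(locs$frame[rows], locs$id[rows])]
    cm <- build_cost_matrix(locs[ord, ], model, rho0[[names(groups)[g]]])
    a <- solve_lap(cm)
    cl <- assignments_to_clusters(a, length(ord))
    clusters_per_precluster[g] <- length(cl)
    for (ch in cl) {
      np <- np + 1L
      parts[[np]] <- .combine_rows(locs, ord[ch])
    }
  }
  out <- .bind_combined(parts[seq_len(np)])
  attr(out, "diagnostics") <- list(
    model = model, kinetics = kin,
    n_preclusters = length(groups),
    clusters_per_precluster = clusters_per_precluster
  )
  out
}

#' Frame connection front end
#'
#' Dispatches to one of the four connectors with its conventional defaults:
#' `"lapfc"` ([frame_connect_lap()]), `"classical"`
#' ([frame_connect_classical()]), `"revised_classical"`
#' ([frame_connect_revised_classical()]), or `"hypothesis_test"`
#' ([frame_connect_hypothesis_test()]).
#'
#' @param locs A localization tibble.
#' @param method Connector name.
#' @param ... Passed to the connector.
#' @return A combined localization tibble.
#' @export
frame_connect <- function(locs, method = c("lapfc", "classical",
                                           "revised_classical",
                                           "hypothesis_test"), ...) {
  method <- match.arg(method)
  switch(method,
    lapfc = frame_connect_lap(locs, ...),
    classical = frame_connect_classical(locs, ...),
    revised_classical = frame_connect_revised_classical(locs, ...),
    hypothesis_test = frame_connect_hypothesis_test(locs, ...)
  )
}
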