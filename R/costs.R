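#' Connection, birth, and death costs
#'
#' Costs are negative log probabilities of the corresponding events under the
#' three-state blinking model.
#'
#' `connection_cost()` is the cost of declaring two localizations, `delta_f`
#' frames apart (`delta_f >= 1`), observations of the same blinking event:
#' the Gaussian probability of their separation given the summed per-axis
#' variances, times the probability of missing the `delta_f - 1` intervening
#' frames, times the probability of not switching off for `delta_f` frames.
#'
#' `birth_cost()` is the cost of declaring a localization the first
#' observation of a new emitter after `N_p` candidate frames have elapsed:
#' either an off-state emitter (density `rho_off` at the localization's
#' frame) switched on now having stayed off for `N_p` frames, or an on-state
#' emitter (density `rho_on` at the first candidate frame) was missed for
#' `N_p` frames.
#'
#' `death_cost()` is the cost of observing nothing more from a cluster for
#' the remaining `N_f` candidate frames: the emitter bleached, switched off,
#' or was missed every remaining frame.  Its argument can exceed 1, so death
#' costs may be negative; the solver handles arbitrary finite costs.
#'
#' @param dx,dy Positional separation between the two localizations, pixels.
#' @param var_x,var_y Summed per-axis variances
#'   `sigma_{x,1}^2 + sigma_{x,2}^2` (and same for y), pixels^2.
#' @param delta_f Frame separation (localization 2 strictly later).
#' @param model A [kinetic_model()].
#' @param N_p Candidate frames elapsed before the localization appears.
#' @param N_f Candidate frames remaining after the localization appears.
#' @param rho_off Local off-state emitter density at the localization's
#'   frame, emitters/pixel^2.
#' @param rho_on Local on-state emitter density `N_p` frames earlier,
#'   emitters/pixel^2.
#' @return The cost (dimensionless, -log probability).  Vectorized over the
#'   numeric arguments.
#' @name costs
NULL

#' @rdname costs
#' @export
connection_cost <- function(dx, dy, var_x, var_y, delta_f, model) {
  if (any(delta_f < 1)) {
    abort("connection requires delta_f >= 1 (same-frame connection is prohibited)")
  }
  gauss <- 0.5 * log(2 * pi * var_x) + dx^2 / (2 * var_x) +
    0.5 * log(2 * pi * var_y) + dy^2 / (2 * var_y)
  miss <- -log(1 - model$p_miss) - (delta_f - 1) * log(model$p_miss)
  # p_miss^0 = 1 even when p_miss = 0
  miss[delta_f == 1] <- -log(1 - model$p_miss)
  gauss + miss + (model$k_off + model$k_bleach) * delta_f
}

#' @rdname costs
#' @export
birth_cost <- function(N_p, model, rho_off, rho_on) {
  stopifnot(all(N_p >= 0), all(rho_off >= 0), all(rho_on >= 0))
  p_new <- rho_off * (1 - exp(-model$k_on)) * exp(-model$k_on * N_p) *
    (1 - model$p_miss)
  p_missed <- rho_on * (1 - model$p_miss) * model$p_miss^N_p
  -log(p_new + p_missed)
}

#' @rdname costs
#' @export
death_cost <- function(N_f, model) {
  stopifnot(all(N_f >= 0))
  -log((1 - exp(-model$k_bleach)) + (1 - exp(-model$k_off)) +
         model$p_miss^N_f)
}

#' Assemble the block cost matrix for one precluster
#'
#' The `2 n_c x 2 n_c` assignment matrix is built from four `n_c x n_c`
#' blocks: upper-left holds halved connection costs for pairs ordered in
#' time (upper-triangular in allowed entries; same-frame pairs and the
#' diagonal are prohibited), upper-right holds death costs on its diagonal,
#' lower-left holds birth costs on its diagonal, and the lower-right
#' auxiliary block is the transpose of the upper-left (allowed wherever the
#' mirrored connection is allowed).  Connection costs are halved so that a
#' selected pair — an upper-left entry and its lower-right mirror — together
#' contribute one full connection cost.
#'
#' Candidate frames are the precluster's observed span: a localization in
#' frame `M` has `N_p = M - frame_start` elapsed and `N_f = frame_end - M`
#' remaining candidate frames; birth densities are `rho_off` at `M` and
#' `rho_on` at `frame_start`, derived from `rho0_local`.
#'
#' Any non-finite cost at an allowed position is replaced by twice the sum
#' of all finite allowed costs, so it is selected only when no alternative
#' exists.
#'
#' @param members Localization tibble of one precluster.
#' @param model A [kinetic_model()].
#' @param rho0_local Initial local emitter density for this precluster,
#'   emitters/pixel^2.
#' @return An object of class `cost_matrix`: list with the `values` matrix,
#'   the logical `prohibited` mask, and `n_c`.
#' @export
build_cost_matrix <- function(members, model, rho0_local) {
  ord <- order(members$frame, members$id)
  members <- members[ord, ]
  n_c <- nrow(members)
  stopifnot(n_c >= 1)
  frame <- members$frame
  f_start <- min(frame); f_end <- max(frame)

  size <- 2L * n_c
  vals <- matrix(NA_real_, size, size)
  prohibited <- matrix(TRUE, size, size)

  idx <- seq_len(n_c)
  # upper-left: halved connection costs, strictly later column frame
  dfmat <- outer(frame, frame, function(a, b) b - a)
  allowed_ul <- dfmat >= 1
  if (any(allowed_ul)) {
    ij <- which(allowed_ul, arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    cc <- connection_cost(
      dx = members$x[j] - members$x[i],
      dy = members$y[j] - members$y[i],
      var_x = members$sigma_x[i]^2 + members$sigma_x[j]^2,
      var_y = members$sigma_y[i]^2 + members$sigma_y[j]^2,
      delta_f = dfmat[allowed_ul],
      model = model
    ) / 2
    vals[cbind(i, j)] <- cc
    prohibited[cbind(i, j)] <- FALSE
    # lower-right auxiliary block: transpose of upper-left
    vals[cbind(n_c + j, n_c + i)] <- cc
    prohibited[cbind(n_c + j, n_c + i)] <- FALSE
  }
  # upper-right diagonal: death costs
  vals[cbind(idx, n_c + idx)] <- death_cost(f_end - frame, model)
  prohibited[cbind(idx, n_c + idx)] <- FALSE
  # lower-left diagonal: birth costs
  N_p <- frame - f_start
  dens_now <- rho_on_off(rho0_local, model, frame)
  dens_start <- rho_on_off(rho0_local, model, f_start)
  vals[cbind(n_c + idx, idx)] <- birth_cost(
    N_p, model, rho_off = dens_now$rho_off, rho_on = rep(dens_start$rho_on, n_c)
  )
  prohibited[cbind(n_c + idx, idx)] <- FALSE

  # Non-finite allowed costs are substituted so they are selected only when
  # no other assignment is available: twice the summed magnitude of all
  # finite allowed costs (the magnitude guards the intent when death costs
  # make the plain sum negative).
  allowed <- !prohibited
  bad <- allowed & !is.finite(vals)
  if (any(bad)) {
    vals[bad] <- 2 * sum(abs(vals[allowed & is.finite(vals)]))
  }
  structure(list(values = vals, prohibited = prohibited, n_c = n_c),
            class = "cost_matrix")
}

#' Solve a linear assignment problem
#'
#' Minimum-cost perfect assignment by the Jonker–Volgenant shortest
#' augmenting path algorithm with dual-variable updates.  Prohibited entries
#' (the mask of a [build_cost_matrix()] object, or non-finite entries of a
#' plain matrix) are never selected; an error is raised if no feasible full
#' assignment exists.
#'
#' @param costs A `cost_matrix` object or a square numeric matrix (`Inf` =
#'   prohibited).
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`
#'   (a permutation).
#' @export
solve_lap <- function(costs) {
  if (inherits(costs, "cost_matrix")) {
    C <- costs$values
    C[costs$prohibited] <- Inf
  } else {
    C <- as.matrix(costs)
  }
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  # shift so all finite entries are handled identically (algorithm accepts
  # arbitrary finite costs; no shift needed, kept as-is)
  u <- numeric(n); v <- numeric(n)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, n)
  for (cur in seq_len(n)) {
    # Dijkstra over columns with reduced costs
    shortest <- rep(Inf, n)
    path <- rep(NA_integer_, n)
    SR <- logical(n)
    remaining <- seq_len(n)
    minVal <- 0
    i <- cur
    sink <- NA_integer_
    while (is.na(sink)) {
      SR[i] <- TRUE
      r <- minVal + C[i, remaining] - u[i] - v[remaining]
      upd <- which(r < shortest[remaining])
      if (length(upd) > 0) {
        cols <- remaining[upd]
        shortest[cols] <- r[upd]
        path[cols] <- i
      }
      jbest <- which.min(shortest[remaining])
      lowest <- shortest[remaining][jbest]
      if (!is.finite(lowest)) {
        abort("infeasible assignment problem: no allowed full assignment")
      }
      # prefer an unassigned column among ties
      ties <- remaining[shortest[remaining] == lowest]
      free <- ties[is.na(row4col[ties])]
      j <- if (length(free) > 0) free[1] else ties[1]
      minVal <- lowest
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
      remaining <- remaining[remaining != j]
    }
    # dual updates
    u[cur] <- u[cur] + minVal
    others <- which(SR & seq_len(n) != cur)
    if (length(others) > 0) {
      u[others] <- u[others] + minVal - shortest[col4row[others]]
    }
    scanned <- setdiff(seq_len(n), remaining)
    scanned <- scanned[scanned != sink]
    v[scanned] <- v[scanned] - (minVal - shortest[scanned])
    # augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- tmp
    }
  }
  col4row
}

#' Total cost of an assignment
#'
#' @param costs A `cost_matrix` object or square numeric matrix.
#' @param assignment Integer vector mapping rows to columns.
#' @return The summed cost.
#' @export
assignment_cost <- function(costs, assignment) {
  if (inherits(costs, "cost_matrix")) {
    C <- costs$values
    C[costs$prohibited] <- Inf
  } else {
    C <- as.matrix(costs)
  }
  sum(C[cbind(seq_along(assignment), assignment)])
}
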