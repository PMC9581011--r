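# Small fixture builders and independent oracles shared across tests.

make_locs <- function(frame, x, y, sigma = 0.05, photons = 1000,
                      background = 5, emitter_id = -1L) {
  tibble::tibble(
    frame = as.integer(frame), x = x, y = y,
    sigma_x = rep_len(sigma, length(frame)),
    sigma_y = rep_len(sigma, length(frame)),
    photons = rep_len(photons, length(frame)),
    background = rep_len(background, length(frame)),
    emitter_id = as.integer(rep_len(emitter_id, length(frame)))
  )
}

random_locs <- function(n, n_frames = 20, roi = 4, sigma = 0.05, seed = 1) {
  set.seed(seed)
  make_locs(
    frame = sample.int(n_frames, n, replace = TRUE),
    x = runif(n, 0, roi), y = runif(n, 0, roi), sigma = sigma,
    emitter_id = sample.int(max(2, n %/% 3), n, replace = TRUE)
  )
}

# one isolated three-frame blink of a single emitter
single_blink_fixture <- function() {
  make_locs(frame = 1:3, x = c(5, 5.02, 4.99), y = c(5, 4.98, 5.01),
            emitter_id = 1L)
}

# exhaustive-permutation minimum assignment cost (Inf = prohibited entries;
# returns Inf when no feasible assignment exists)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

brute_force_lap <- function(C) {
  n <- nrow(C)
  P <- all_perms(n)
  suppressWarnings(min(apply(P, 1, function(p) sum(C[cbind(seq_len(n), p)]))))
}

# O(n^2) nearest-neighbor-distance oracle (frame window, same frame excluded)
brute_force_nn <- function(locs, max_frame_gap = 5) {
  n <- nrow(locs)
  out <- c()
  for (i in seq_len(n)) {
    df <- abs(locs$frame - locs$frame[i])
    ok <- df >= 1 & df <= max_frame_gap
    if (!any(ok)) next
    out <- c(out, sqrt(min((locs$x[ok] - locs$x[i])^2 +
                             (locs$y[ok] - locs$y[i])^2)))
  }
  out
}

# literal, slow reimplementation of the sequential precluster rule
brute_force_precluster <- function(locs, max_frame_gap = 5, n_sigma = 5) {
  ord <- order(locs$frame, locs$id)
  locs <- locs[ord, ]
  n <- nrow(locs)
  sbar2 <- (locs$sigma_x^2 + locs$sigma_y^2) / 2
  cl <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(n)) {
      df <- locs$frame[i] - locs$frame[j]
      if (df < 1 || df > max_frame_gap) next
      d <- sqrt((locs$x[i] - locs$x[j])^2 + (locs$y[i] - locs$y[j])^2)
      if (d > n_sigma * sqrt(sbar2[i])) next
      if (d < bestd || (d == bestd && locs$id[j] < locs$id[best])) {
        best <- j; bestd <- d
      }
    }
    if (is.na(best)) {
      nxt <- nxt + 1L; cl[i] <- nxt
    } else {
      cl[i] <- cl[best]
    }
  }
  # return membership keyed by id
  stats::setNames(cl, locs$id)
}
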