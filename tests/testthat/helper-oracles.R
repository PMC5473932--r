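# Independent oracles and fixture builders shared across tests.

# Brute-force longest run of ones: for every start position, extend while on.
oracle_longest_run <- function(x) {
  best <- 0L
  n <- length(x)
  for (start in seq_len(n)) {
    len <- 0L
    t <- start
    while (t <= n && x[t] == 1) {
      len <- len + 1L
      t <- t + 1L
    }
    if (len > best) best <- len
  }
  best
}

# Exhaustive single-threshold scan: every midpoint of sorted unique values
# plus the two extremes, both directions; returns the best achievable
# accuracy on (values, labels) with `positive` on either side.
oracle_best_threshold_accuracy <- function(values, labels, positive) {
  u <- sort(unique(values))
  thr <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  truth <- labels == positive
  best <- 0
  for (t in thr) {
    for (dir in c("above", "below")) {
      pred <- if (dir == "above") values > t else values <= t
      best <- max(best, mean(pred == truth))
    }
  }
  best
}

# Random rigid-body transform of an n x 3 coordinate matrix.
random_rigid_transform <- function(X, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 10)
  sweep(X %*% R, 2, shift, "+")
}

# Small CA-only trajectory from a list of n x 3 frame matrices.
traj_from_frames <- function(frames, resid = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(resid)) resid <- seq_len(n)
  coords <- array(0, c(length(frames), n, 3))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  trajectory(topology(resid = resid), coords)
}

# Canonical edge order used by the graph importers: (type, i, j).
sort_by_key <- function(graph) {
  out <- graph[order(graph$type, graph$i, graph$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-state ensembles with scripted interaction schedules; returns
# trajectories plus the scripted longest runs for each state.
scripted_two_state <- function(n_frames, runs_ox, runs_red, pairs, seed) {
  stopifnot(length(runs_ox) == length(runs_red),
            nrow(pairs) == length(runs_ox))
  mk <- function(runs, seed) {
    sched <- lapply(seq_along(runs), function(k) {
      schedule_entry(pairs[k, 1], pairs[k, 2], "salt_bridge", runs[k],
                     total_on = runs[k])
    })
    spec <- synthetic_spec(n_domains = 2, residues_per_domain = 25,
                           n_frames = n_frames, hinge_amplitude = 5,
                           jitter_sigma = 0.1, interaction_schedule = sched,
                           seed = seed)
    make_hinge_trajectory(spec)
  }
  list(ox = mk(runs_ox, seed), red = mk(runs_red, seed + 1))
}
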