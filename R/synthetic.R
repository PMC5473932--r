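#' Specification for a synthetic two-state ensemble
#'
#' The generator builds desk-scale stand-ins for multi-domain protein MD
#' ensembles with known ground truth: domains are compact Gaussian blobs of
#' CA pseudo-atoms spaced on a line; the terminal domain performs a rigid
#' hinge rotation; thermal motion is independent Gaussian jitter; interaction
#' time series are scripted exactly. One global `seed` is expanded into
#' per-operation substreams, so every stage is reproducible bit-for-bit.
#'
#' @param n_domains number of domains (>= 2), laid out along x.
#' @param residues_per_domain CA pseudo-atoms per domain.
#' @param n_frames number of frames (>= 1).
#' @param hinge_amplitude hinge rotation amplitude, degrees. The terminal
#'   domain rotates by `amplitude * sin(2*pi*t/n_frames)` at frame t (0-based).
#' @param hinge_axis unit 3-vector; the rotation axis passes through the
#'   boundary between the last two domains.
#' @param jitter_sigma per-atom, per-frame isotropic Gaussian jitter sd,
#'   Angstrom (>= 0).
#' @param feature_specs named list of per-feature, per-state Gaussian mixture
#'   specs; see [default_feature_specs()] for the layout.
#' @param interaction_schedule list of [schedule_entry()] items scripting
#'   binary interaction time series with known longest runs.
#' @param seed integer master seed.
#' @return A validated `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_domains = 4, residues_per_domain = 25,
                           n_frames = 200, hinge_amplitude = 20,
                           hinge_axis = c(0, 0, 1), jitter_sigma = 0.1,
                           feature_specs = default_feature_specs(),
                           interaction_schedule = list(), seed = 1) {
  if (n_domains < 2) .stopf("need at least 2 domains")
  if (residues_per_domain < 1) .stopf("residues_per_domain must be positive")
  if (n_frames < 1) .stopf("n_frames must be >= 1")
  if (jitter_sigma < 0) .stopf("jitter_sigma must be >= 0")
  if (length(hinge_axis) != 3 || abs(.vnorm(hinge_axis) - 1) > 1e-6) {
    .stopf("hinge_axis must be a unit 3-vector")
  }
  for (fname in names(feature_specs)) {
    for (sname in names(feature_specs[[fname]])) {
      comp <- feature_specs[[fname]][[sname]]
      if (abs(sum(comp$weights) - 1) > 1e-8) {
        .stopf("mixture weights for feature '%s', state '%s' must sum to 1",
               fname, sname)
      }
      if (any(comp$sds < 0)) {
        .stopf("negative sd in feature '%s', state '%s'", fname, sname)
      }
      if (length(comp$means) != length(comp$weights) ||
          length(comp$sds) != length(comp$weights)) {
        .stopf("weights/means/sds length mismatch in feature '%s'", fname)
      }
    }
  }
  n_res <- n_domains * residues_per_domain
  for (e in interaction_schedule) {
    if (e$longest_run > e$total_on || e$total_on > n_frames) {
      .stopf("schedule entry (%d,%d): need longest_run <= total_on <= n_frames",
             e$i, e$j)
    }
    if (e$i < 1 || e$j < 1 || e$i > n_res || e$j > n_res) {
      .stopf("schedule entry references residues outside 1..%d", n_res)
    }
    if (abs(e$i - e$j) < 2) {
      .stopf("schedule pairs must be separated by >= 2 in sequence")
    }
  }
  structure(list(n_domains = n_domains,
                 residues_per_domain = residues_per_domain,
                 n_frames = n_frames, hinge_amplitude = hinge_amplitude,
                 hinge_axis = hinge_axis, jitter_sigma = jitter_sigma,
                 feature_specs = feature_specs,
                 interaction_schedule = interaction_schedule,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' One scripted interaction time series
#'
#' @param i,j 1-based residue indices (sequence separation >= 2).
#' @param type one of `"hydrogen_bond"`, `"van_der_waals"`, `"salt_bridge"`,
#'   `"pi_pi"`, `"cation_pi"`.
#' @param longest_run target maximum run of consecutive on-frames.
#' @param total_on total number of on-frames (defaults to `longest_run`).
#' @return list usable in `interaction_schedule`.
#' @export
schedule_entry <- function(i, j, type = "salt_bridge", longest_run,
                           total_on = NULL) {
  type <- match.arg(type, .interaction_types)
  if (is.null(total_on)) total_on <- longest_run
  list(i = as.integer(i), j = as.integer(j), type = type,
       longest_run = as.integer(longest_run), total_on = as.integer(total_on))
}

#' Default two-state feature distributions
#'
#' Two inter-domain distance-like features emulating the qualitative shapes
#' seen in redox-dependent multi-domain ensembles: a unimodal feature whose
#' mean shifts between states (separable by a single threshold up to the
#' Gaussian overlap), and a feature that is unimodal in the reduced state but
#' strongly bimodal in the oxidized state, which a single threshold cannot
#' capture while a radial-basis SVM can.
#'
#' @return named list of per-feature, per-state mixture specs with fields
#'   `weights`, `means`, `sds`.
#' @export
default_feature_specs <- function() {
  list(
    R_bpap = list(
      red = list(weights = 1, means = 0, sds = 1),
      ox = list(weights = 1, means = 2, sds = 1)
    ),
    R_bbp = list(
      red = list(weights = 1, means = 0, sds = 1),
      ox = list(weights = c(0.5, 0.5), means = c(-4, 4), sds = c(1, 1))
    )
  )
}

# Deterministic base geometry: blob CA coordinates, hinge pivot,
# terminal-domain residue indices.
.synthetic_base <- function(spec) {
  nd <- spec$n_domains
  rpd <- spec$residues_per_domain
  spacing <- 30
  blob_sd <- 4
  centers <- cbind((seq_len(nd) - 1) * spacing, 0, 0)
  ca0 <- .with_seed(.substream(spec$seed, 1), {
    do.call(rbind, lapply(seq_len(nd), function(d) {
      sweep(matrix(stats::rnorm(rpd * 3, sd = blob_sd), rpd, 3), 2,
            centers[d, ], "+")
    }))
  })
  pivot <- (centers[nd, ] + centers[nd - 1, ]) / 2
  list(ca0 = ca0, pivot = pivot,
       terminal = ((nd - 1) * rpd + 1):(nd * rpd),
       n_res = nd * rpd)
}

#' Generate a rigid-hinge trajectory with scripted interactions
#'
#' The terminal domain rotates rigidly about `hinge_axis` through the
#' boundary between the last two domains by `amplitude * sin(2*pi*t/n_frames)`
#' degrees; independent Gaussian jitter of sd `jitter_sigma` is added to every
#' CA per frame. Each scripted interaction attaches typed pseudo-atoms
#' (donor/acceptor, charged centers, ring centroids) to its residue pair and
#' moves the partner atom in and out of the geometric criterion exactly on the
#' scheduled frames, so the interaction-detection stage recovers the scripted
#' series verbatim. The realized ground-truth series are attached as
#' `attr(traj, "schedule_series")`.
#'
#' @param spec a [synthetic_spec()].
#' @return A [trajectory()] of `n_frames` frames.
#' @export
make_hinge_trajectory <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  base <- .synthetic_base(spec)
  nf <- spec$n_frames
  n_res <- base$n_res
  amp <- spec$hinge_amplitude * pi / 180

  # per-frame CA coordinates: hinge rotation of the terminal domain + jitter
  jitter <- if (spec$jitter_sigma > 0) {
    .with_seed(.substream(spec$seed, 2),
               array(stats::rnorm(nf * n_res * 3, sd = spec$jitter_sigma),
                     c(nf, n_res, 3)))
  } else {
    array(0, c(nf, n_res, 3))
  }
  ca <- array(0, c(nf, n_res, 3))
  for (t in seq_len(nf)) {
    theta <- amp * sin(2 * pi * (t - 1) / nf)
    frame <- base$ca0
    if (theta != 0) {
      R <- .rotation_matrix(spec$hinge_axis, theta)
      term <- base$ca0[base$terminal, , drop = FALSE]
      frame[base$terminal, ] <-
        sweep(sweep(term, 2, base$pivot) %*% t(R), 2, base$pivot, "+")
    }
    ca[t, , ] <- frame + jitter[t, , ]
  }

  sched <- spec$interaction_schedule
  series <- lapply(seq_along(sched), function(k) {
    e <- sched[[k]]
    make_adjacency_schedule(nf, e$longest_run, .substream(spec$seed, 10 + k),
                            total_on = e$total_on)
  })

  # topology: one CA per residue, plus per-entry pseudo-atoms appended to
  # their residues (residue order is preserved)
  atoms <- data.frame(resid = seq_len(n_res), resname = "GLY", atom = "CA",
                      element = "C", stringsAsFactors = FALSE)
  extra <- list()
  for (k in seq_along(sched)) {
    e <- sched[[k]]
    roles <- .pseudo_roles(e$type)
    for (r in roles$i) {
      extra[[length(extra) + 1]] <- data.frame(resid = e$i, resname = "GLY",
                                               atom = r$atom, element = r$element,
                                               stringsAsFactors = FALSE)
    }
    for (r in roles$j) {
      extra[[length(extra) + 1]] <- data.frame(resid = e$j, resname = "GLY",
                                               atom = r$atom, element = r$element,
                                               stringsAsFactors = FALSE)
    }
  }
  atoms <- rbind(atoms, do.call(rbind, extra))
  if (!is.null(atoms)) atoms <- atoms[order(atoms$resid), , drop = FALSE]
  top <- topology(resid = atoms$resid, resname = atoms$resname,
                  atom = atoms$atom, element = atoms$element, chain = "A")

  coords <- array(0, c(nf, nrow(atoms), 3))
  ca_rows <- which(atoms$atom == "CA")
  coords[, ca_rows, ] <- ca[, atoms$resid[ca_rows], , drop = FALSE]

  # pseudo-atoms: anchored above residue i in a per-entry y-shell so entries
  # never interfere; the partner atom is teleported 500 A away on off-frames
  if (length(sched) > 0) {
    # rows per (resid, atom name) are consumed in schedule order, so a residue
    # appearing in several entries gets one pseudo-atom set per entry
    claim <- new.env(parent = emptyenv())
    next_row <- function(resid_idx, atom_name) {
      key <- paste(resid_idx, atom_name)
      n_used <- if (is.null(claim[[key]])) 0L else claim[[key]]
      claim[[key]] <- n_used + 1L
      which(atoms$atom == atom_name & atoms$resid == resid_idx)[n_used + 1L]
    }
    for (k in seq_along(sched)) {
      e <- sched[[k]]
      roles <- .pseudo_roles(e$type)
      shell <- c(0, 60 + 30 * k, 0)
      off_frames <- series[[k]] == 0
      anchor <- matrix(ca[, e$i, ], nf, 3) # follows residue i, jitter included
      for (r in roles$i) {
        row <- next_row(e$i, r$atom)
        coords[, row, ] <- sweep(anchor, 2, shell + r$offset, "+")
      }
      for (r in roles$j) {
        row <- next_row(e$j, r$atom)
        pos <- sweep(anchor, 2, shell + r$offset, "+")
        pos[off_frames, 1] <- pos[off_frames, 1] + 500
        coords[, row, ] <- pos
      }
    }
  }

  traj <- trajectory(top, coords)
  attr(traj, "schedule_series") <- series
  attr(traj, "schedule") <- sched
  traj
}

# pseudo-atom layout per interaction type: atoms attached to residue i
# (anchor side) and residue j (partner side), with offsets from the anchor
# point chosen to satisfy the default geometric criterion on on-frames
.pseudo_roles <- function(type) {
  switch(type,
    salt_bridge = list(
      i = list(list(atom = "PPOS", element = "X", offset = c(0, 0, 0))),
      j = list(list(atom = "PNEG", element = "X", offset = c(3, 0, 0)))
    ),
    hydrogen_bond = list(
      i = list(list(atom = "PDON", element = "X", offset = c(0, 0, 0)),
               list(atom = "PHDO", element = "X", offset = c(1, 0, 0))),
      j = list(list(atom = "PACC", element = "X", offset = c(2.9, 0, 0)))
    ),
    pi_pi = list(
      i = list(list(atom = "PRNG", element = "X", offset = c(0, 0, 0))),
      j = list(list(atom = "PRNG", element = "X", offset = c(5, 0, 0)))
    ),
    cation_pi = list(
      i = list(list(atom = "PPOS", element = "X", offset = c(0, 0, 0))),
      j = list(list(atom = "PRNG", element = "X", offset = c(4, 0, 0)))
    ),
    van_der_waals = list(
      i = list(list(atom = "PVDW", element = "C", offset = c(0, 0, 0))),
      j = list(list(atom = "PVDW", element = "C", offset = c(3, 0, 0)))
    ),
    .stopf("unknown interaction type '%s'", type)
  )
}

#' Domain partition matching a synthetic trajectory
#'
#' For four domains the tags are `a`, `b`, `bp`, `ap` (N- to C-terminal);
#' otherwise `d1`, `d2`, ...
#'
#' @param spec a [synthetic_spec()].
#' @return A `DomainPartition` covering residues
#'   `1..n_domains*residues_per_domain`.
#' @export
synthetic_partition <- function(spec) {
  nd <- spec$n_domains
  rpd <- spec$residues_per_domain
  tags <- if (nd == 4) c("a", "b", "bp", "ap") else paste0("d", seq_len(nd))
  ranges <- lapply(seq_len(nd), function(d) c((d - 1) * rpd + 1, d * rpd))
  names(ranges) <- tags
  top <- topology(resid = seq_len(nd * rpd))
  domain_partition(ranges, top)
}

#' Analytic hinge displacement mode of a synthetic spec
#'
#' Tangent displacement direction of the planted hinge at zero rotation:
#' `axis x (r - pivot)` for CA atoms of the terminal domain, zero elsewhere,
#' normalized over the concatenated CA coordinate vector. This is the
#' ground-truth collective mode against which recovered principal components
#' are compared.
#'
#' @param spec a [synthetic_spec()].
#' @return unit numeric vector of length `3 * n_residues` (atom-major xyz).
#' @export
hinge_mode_vector <- function(spec) {
  base <- .synthetic_base(spec)
  v <- matrix(0, base$n_res, 3)
  a <- spec$hinge_axis
  for (i in base$terminal) {
    r <- base$ca0[i, ] - base$pivot
    v[i, ] <- c(a[2] * r[3] - a[3] * r[2],
                a[3] * r[1] - a[1] * r[3],
                a[1] * r[2] - a[2] * r[1])
  }
  v <- as.vector(t(v))
  v / .vnorm(v)
}

#' Generate a binary sequence with an exact longest run of ones
#'
#' Constructs a 0/1 sequence of length `n_frames` whose maximum run of
#' consecutive ones is exactly `longest_run` and whose total number of ones
#' is `total_on` (default: `longest_run`, one clean block). Placement of
#' blocks and gaps is randomized but deterministic given `seed`.
#'
#' @param n_frames sequence length.
#' @param longest_run target maximum run (0 gives the all-zero sequence).
#' @param seed integer seed.
#' @param total_on total ones; must satisfy
#'   `longest_run <= total_on` and `n_frames - total_on >= ceil(total_on/longest_run) - 1`.
#' @return integer vector of 0/1 of length `n_frames`.
#' @export
make_adjacency_schedule <- function(n_frames, longest_run, seed,
                                    total_on = NULL) {
  n_frames <- as.integer(n_frames)
  longest_run <- as.integer(longest_run)
  if (longest_run < 0 || longest_run > n_frames) {
    .stopf("longest_run must be in 0..n_frames")
  }
  if (is.null(total_on)) total_on <- longest_run
  total_on <- as.integer(total_on)
  if (longest_run == 0) {
    if (total_on != 0) .stopf("longest_run 0 requires total_on 0")
    return(integer(n_frames))
  }
  if (total_on < longest_run || total_on > n_frames) {
    .stopf("need longest_run <= total_on <= n_frames")
  }
  k <- ceiling(total_on / longest_run) # number of blocks
  zeros <- n_frames - total_on
  if (zeros < k - 1) {
    .stopf("cannot fit %d ones with longest run %d in %d frames",
           total_on, longest_run, n_frames)
  }
  sizes <- rep(longest_run, k)
  sizes[k] <- total_on - (k - 1) * longest_run
  .with_seed(seed, {
    sizes <- sample(sizes)
    # blocks of equal size: shuffling keeps max run == longest_run because at
    # least one block has exactly that size and all gaps are >= 1
    if (sizes[1] != longest_run) {
      swap <- which(sizes == longest_run)[1]
      sizes[c(1, swap)] <- sizes[c(swap, 1)]
    }
    extra <- zeros - (k - 1)
    slots <- tabulate(sample.int(k + 1, extra, replace = TRUE), k + 1)
    # gaps: leading slot, (k-1) interior gaps of at least one zero, trailing
    gaps <- if (k > 1) c(slots[1], slots[2:k] + 1L, slots[k + 1]) else slots
    out <- integer(0)
    for (b in seq_len(k)) {
      out <- c(out, integer(gaps[b]), rep(1L, sizes[b]))
    }
    out <- c(out, integer(gaps[k + 1]))
    out
  })
}

#' Draw labeled feature samples from the per-state mixtures
#'
#' @param spec a [synthetic_spec()] whose `feature_specs` name at least two
#'   states per feature.
#' @param n_per_state samples drawn per feature per state.
#' @return data frame with a `state` column and one column per feature,
#'   deterministic given `spec$seed`.
#' @export
make_feature_samples <- function(spec, n_per_state) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  fs <- spec$feature_specs
  if (length(fs) == 0) .stopf("spec has no feature_specs")
  states <- names(fs[[1]])
  if (length(states) < 2) .stopf("need at least two state labels")
  out <- data.frame(state = rep(states, each = n_per_state),
                    stringsAsFactors = FALSE)
  for (fi in seq_along(fs)) {
    col <- numeric(0)
    for (si in seq_along(states)) {
      comp <- fs[[fi]][[states[si]]]
      vals <- .with_seed(.substream(spec$seed, 100 + fi * 16 + si), {
        z <- sample.int(length(comp$weights), n_per_state, replace = TRUE,
                        prob = comp$weights)
        stats::rnorm(n_per_state, mean = comp$means[z], sd = comp$sds[z])
      })
      col <- c(col, vals)
    }
    out[[names(fs)[fi]]] <- col
  }
  out
}

#' Write a synthetic spec as a YAML config
#' @param spec a [synthetic_spec()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a synthetic spec from a YAML config
#' @param path path written by [write_synthetic_spec()].
#' @return A `SyntheticSpec`.
#' @export
read_synthetic_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$interaction_schedule <- lapply(x$interaction_schedule, function(e) {
    schedule_entry(e$i, e$j, e$type, e$longest_run, e$total_on)
  })
  do.call(synthetic_spec, x)
}
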