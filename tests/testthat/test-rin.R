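# Frame builders with explicitly placed chemistry: real atom names on real
# residue names, so the detection rules are exercised without pseudo-atoms.
arg_glu_frame <- function(gap) {
  # Arg guanidinium group and Glu carboxylate group `gap` Angstrom apart,
  # plus a far-away spacer residue
  top <- topology(
    resid = c(1, 1, 1, 1, 5, 5, 5, 9),
    resname = c("ARG", "ARG", "ARG", "ARG", "GLU", "GLU", "GLU", "ALA"),
    atom = c("CA", "NE", "NH1", "NH2", "CA", "OE1", "OE2", "CA"),
    element = c("C", "N", "N", "N", "C", "O", "O", "C"))
  X <- rbind(c(-3, 0, 0),                      # Arg CA
             c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),  # guanidinium N's
             c(gap + 3, 0, 0),                 # Glu CA
             c(gap, 1, 0), c(gap, -1, 0),      # carboxylate O's (centroid on x)
             c(50, 50, 50))
  trajectory(top, array(X, c(1, nrow(X), 3)))
}

hbond_frame <- function(angle_deg, da_dist = 2.9) {
  # donor N (residue 1) with one hydrogen, acceptor backbone O (residue 4);
  # the hydrogen is placed to realize the requested D-H...A angle
  d <- c(0, 0, 0)
  a <- c(da_dist, 0, 0)
  # H on the unit circle around the donor such that angle(D, H, A) = angle_deg
  # solve by placing H at distance 1 from D in the xy-plane
  th <- seq(0, pi, length.out = 20000)
  best <- which.min(abs(vapply(th, function(t) {
    h <- c(cos(t), sin(t), 0)
    mdrin:::.angle_deg(d, h, a)
  }, 0) - angle_deg))
  h <- c(cos(th[best]), sin(th[best]), 0)
  top <- topology(resid = c(1, 1, 4), resname = c("GLY", "GLY", "GLY"),
                  atom = c("N", "H", "O"), element = c("N", "H", "O"))
  trajectory(top, array(rbind(d, h, a), c(1, 3, 3)))
}

test_that("salt bridges are detected from charged-group centroids", {
  edges <- detect_interactions(arg_glu_frame(3.0))
  sb <- edges[edges$type == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(c(sb$i, sb$j), c(1, 5))
  # beyond the 4 A default cutoff: no salt bridge
  far <- detect_interactions(arg_glu_frame(4.5))
  expect_equal(nrow(far[far$type == "salt_bridge", ]), 0)
})

test_that("everything beyond 10 A yields an empty edge set", {
  top <- topology(resid = c(1, 4, 8), resname = "ALA", atom = "CA",
                  element = "C")
  X <- rbind(c(0, 0, 0), c(15, 0, 0), c(0, 20, 0))
  traj <- trajectory(top, array(X, c(1, 3, 3)))
  edges <- detect_interactions(traj)
  expect_equal(nrow(edges), 0)
})

test_that("hydrogen bonds respect the D-H...A angle gate", {
  good <- detect_interactions(hbond_frame(160))
  expect_true(any(good$type == "hydrogen_bond" & good$i == 1 & good$j == 4))
  bad <- detect_interactions(hbond_frame(95))
  expect_false(any(bad$type == "hydrogen_bond"))
  # without a modeled hydrogen the heavy-atom rule applies
  traj <- hbond_frame(95)
  keep <- traj$topology$atom != "H"
  noh <- trajectory(topology(resid = traj$topology$resid[keep],
                             resname = traj$topology$resname[keep],
                             atom = traj$topology$atom[keep],
                             element = traj$topology$element[keep]),
                    traj$coords[, keep, , drop = FALSE])
  expect_true(any(detect_interactions(noh)$type == "hydrogen_bond"))
})

test_that("sequence neighbors are excluded and criteria are configurable", {
  # two CA carbons 3 A apart: a vdW contact, but only if |i-j| >= 2
  mk <- function(r1, r2) {
    top <- topology(resid = c(r1, r2), resname = "ALA", atom = "CA",
                    element = "C")
    trajectory(top, array(rbind(c(0, 0, 0), c(3, 0, 0)), c(1, 2, 3)))
  }
  expect_equal(nrow(detect_interactions(mk(1, 2))), 0)
  vdw <- detect_interactions(mk(1, 3))
  expect_true(any(vdw$type == "van_der_waals"))
  # tightening the slack below the 3 A gap removes the contact
  tight <- interaction_criteria(vdw_slack = 0.0001)
  # 3 > 1.7 + 1.7 would still hit; move atoms to 3.6 A instead
  top <- topology(resid = c(1, 3), resname = "ALA", atom = "CA", element = "C")
  traj <- trajectory(top, array(rbind(c(0, 0, 0), c(3.6, 0, 0)), c(1, 2, 3)))
  expect_true(any(detect_interactions(traj)$type == "van_der_waals"))
  expect_equal(nrow(detect_interactions(traj, criteria = tight)), 0)
})

test_that("detection is deterministic and rigid-motion invariant", {
  spec <- synthetic_spec(n_domains = 2, residues_per_domain = 10, n_frames = 1,
                         jitter_sigma = 0.5, seed = 31)
  traj <- make_hinge_trajectory(spec)
  e1 <- detect_interactions(traj)
  e2 <- detect_interactions(traj)
  expect_identical(e1, e2)
  X <- matrix(traj$coords[1, , ], ncol = 3)
  moved <- trajectory(traj$topology,
                      array(random_rigid_transform(X, 17),
                            c(1, nrow(X), 3)))
  expect_identical(detect_interactions(moved), e1)
})

test_that("criteria configs round-trip through YAML", {
  crit <- interaction_criteria(hbond_dist = 3.2, salt_dist = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(crit, path)
  expect_equal(read_criteria(path), crit)
  expect_error(interaction_criteria(salt_dist = -1), "positive")
})

test_that("adjacency series reflect static and scripted interactions", {
  # static: one salt bridge repeated over all frames
  f <- arg_glu_frame(3.0)
  coords <- array(0, c(6, dim(f$coords)[2], 3))
  for (t in 1:6) coords[t, , ] <- f$coords[1, , ]
  static <- trajectory(f$topology, coords)
  adj <- build_adjacency_series(static)
  expect_equal(adjacency_series(adj, "salt_bridge", 1, 5), rep(1L, 6))
  # scripted frames {3,4,5} of 10 give 0011100000
  spec <- synthetic_spec(n_domains = 2, residues_per_domain = 5, n_frames = 10,
                         jitter_sigma = 0, seed = 33,
                         interaction_schedule = list(
                           schedule_entry(1, 8, "salt_bridge", 3, 3)))
  traj <- make_hinge_trajectory(spec)
  truth <- attr(traj, "schedule_series")[[1]]
  adj2 <- build_adjacency_series(traj)
  expect_identical(adjacency_series(adj2, "salt_bridge", 1, 8),
                   as.integer(truth))
  expect_equal(oracle_longest_run(truth), 3)
})

test_that("per-frame re-detection equals slicing the assembled series", {
  spec <- synthetic_spec(n_domains = 2, residues_per_domain = 8, n_frames = 15,
                         jitter_sigma = 0.3, seed = 35,
                         interaction_schedule = list(
                           schedule_entry(2, 10, "hydrogen_bond", 4, 7),
                           schedule_entry(3, 12, "cation_pi", 6, 6)))
  traj <- make_hinge_trajectory(spec)
  adj <- build_adjacency_series(traj)
  for (t in seq_len(15)) {
    ed <- detect_interactions(traj, t)
    keys_frame <- sort(paste(ed$type, ed$i, ed$j))
    on_series <- vapply(seq_len(nrow(adj$index)), function(r) {
      adj$series[[r]][t] == 1L
    }, logical(1))
    keys_series <- sort(paste(adj$index$type[on_series],
                              adj$index$i[on_series], adj$index$j[on_series]))
    expect_identical(keys_series, keys_frame)
  }
})

test_that("adjacency sets round-trip through the RLE TSV layout", {
  spec <- synthetic_spec(n_domains = 2, residues_per_domain = 6, n_frames = 25,
                         jitter_sigma = 0.2, seed = 36,
                         interaction_schedule = list(
                           schedule_entry(1, 9, "salt_bridge", 5, 9)))
  adj <- build_adjacency_series(make_hinge_trajectory(spec))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_series(adj, path)
  back <- read_adjacency_series(path)
  expect_equal(back$n_frames, adj$n_frames)
  expect_equal(back$index, adj$index, ignore_attr = TRUE)
  expect_identical(back$series, adj$series)
})
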