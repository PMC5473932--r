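.interaction_types <- c("hydrogen_bond", "van_der_waals", "salt_bridge",
                        "pi_pi", "cation_pi")

# van der Waals radii (Angstrom) by element
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Geometric criteria for the five non-covalent interaction types
#'
#' Literature-standard, fully user-overridable rules deciding, per frame,
#' whether a residue pair forms a typed edge:
#' hydrogen bond — donor-acceptor heavy-atom distance and, when a donor
#' hydrogen is present, a minimum D-H...A angle (heavy-atom-only fallback
#' otherwise); salt bridge — charged-group centroid distance between basic
#' (Arg, Lys, His+) and acidic (Asp, Glu) groups; van der Waals — heavy-atom
#' distance below the sum of the elements' radii plus a slack; pi-pi —
#' aromatic ring-centroid distance; cation-pi — cation center to ring
#' centroid. Residue pairs closer than `seq_sep` in sequence are never
#' reported (covalent neighbors are not non-covalent contacts).
#'
#' @param hbond_dist donor-acceptor cutoff, Angstrom.
#' @param hbond_angle minimum D-H...A angle, degrees.
#' @param salt_dist charged-centroid cutoff, Angstrom.
#' @param vdw_slack slack added to the sum of van der Waals radii, Angstrom.
#' @param pipi_dist ring-centroid cutoff, Angstrom.
#' @param catpi_dist cation-to-ring-centroid cutoff, Angstrom.
#' @param seq_sep minimum sequence separation |i - j|.
#' @return An `InteractionCriteria` list.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                                 salt_dist = 4.0, vdw_slack = 0.5,
                                 pipi_dist = 6.5, catpi_dist = 6.0,
                                 seq_sep = 2) {
  vals <- c(hbond_dist, hbond_angle, salt_dist, vdw_slack, pipi_dist, catpi_dist)
  if (any(vals <= 0)) .stopf("all cutoffs must be positive")
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 salt_dist = salt_dist, vdw_slack = vdw_slack,
                 pipi_dist = pipi_dist, catpi_dist = catpi_dist,
                 seq_sep = seq_sep, version = "1"),
            class = "InteractionCriteria")
}

#' Write interaction criteria as YAML
#' @param criteria an [interaction_criteria()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

#' Read interaction criteria from YAML
#' @param path path written by [write_criteria()].
#' @return An `InteractionCriteria`.
#' @export
read_criteria <- function(path) {
  x <- yaml::read_yaml(path)
  x$version <- NULL
  do.call(interaction_criteria, x)
}

# Role tables from a topology: which atoms (or atom groups) can act as
# hydrogen-bond donors/acceptors, charged centers, aromatic ring centroids
# and vdW heavy atoms. Pseudo-atom names (PDON/PHDO/PACC/PPOS/PNEG/PRNG)
# declare roles directly, so coarse synthetic fixtures work without chemistry.
.role_tables <- function(top) {
  n <- nrow(top)
  res <- top$resid
  name <- top$atom
  rn <- top$resname
  grp <- function(resname, members) {
    idx <- which(rn == resname & name %in% members)
    split(idx, res[idx])
  }
  single <- function(sel) lapply(which(sel), identity)

  donors <- which(
    (name == "N" & rn != "PRO") |
      (rn == "SER" & name == "OG") | (rn == "THR" & name == "OG1") |
      (rn == "TYR" & name == "OH") | (rn == "ASN" & name == "ND2") |
      (rn == "GLN" & name == "NE2") | (rn == "LYS" & name == "NZ") |
      (rn == "ARG" & name %in% c("NE", "NH1", "NH2")) |
      (rn == "HIS" & name %in% c("ND1", "NE2")) |
      (rn == "TRP" & name == "NE1") | (rn == "CYS" & name == "SG") |
      name == "PDON")
  acceptors <- which(
    name == "O" |
      (rn == "ASP" & name %in% c("OD1", "OD2")) |
      (rn == "GLU" & name %in% c("OE1", "OE2")) |
      (rn == "ASN" & name == "OD1") | (rn == "GLN" & name == "OE1") |
      (rn == "SER" & name == "OG") | (rn == "THR" & name == "OG1") |
      (rn == "TYR" & name == "OH") | (rn == "MET" & name == "SD") |
      (rn == "HIS" & name %in% c("ND1", "NE2")) |
      name == "PACC")
  hydrogens <- which(top$element == "H" | name == "PHDO")

  pos_groups <- c(grp("ARG", c("NE", "NH1", "NH2")),
                  grp("LYS", "NZ"),
                  grp("HIS", c("ND1", "NE2")),
                  lapply(which(name == "PPOS"), identity))
  neg_groups <- c(grp("ASP", c("OD1", "OD2")),
                  grp("GLU", c("OE1", "OE2")),
                  lapply(which(name == "PNEG"), identity))
  ring_groups <- c(grp("PHE", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                   grp("TYR", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
                   grp("TRP", c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
                   grp("HIS", c("CG", "ND1", "CD2", "CE1", "NE2")),
                   lapply(which(name == "PRNG"), identity))
  heavy <- which(top$element %in% names(.vdw_radii) & top$element != "H")

  list(donors = donors, acceptors = acceptors, hydrogens = hydrogens,
       pos = pos_groups, neg = neg_groups, rings = ring_groups, heavy = heavy)
}

# centers (k x 3) and residue ids of a list of atom-index groups
.group_centers <- function(groups, X, res) {
  if (length(groups) == 0) {
    return(list(xyz = matrix(0, 0, 3), resid = integer(0)))
  }
  xyz <- t(vapply(groups, function(g) colMeans(X[g, , drop = FALSE]),
                  numeric(3)))
  list(xyz = xyz, resid = vapply(groups, function(g) res[g[1]], integer(1)))
}

# residue pairs (i < j) from two role position sets within a cutoff
.pairs_within <- function(A, ra, B, rb, cutoff, seq_sep) {
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  D <- .pdist2(A, B)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(matrix(integer(0), 0, 2))
  i <- ra[hit[, 1]]
  j <- rb[hit[, 2]]
  keep <- abs(i - j) >= seq_sep
  cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE]
}

.dedupe_pairs <- function(m) {
  if (nrow(m) == 0) return(m)
  unique(m)
}

#' Detect typed residue-residue interactions in one frame
#'
#' Applies the geometric rules of [interaction_criteria()] to the
#' coordinates of a single frame and returns the typed edge set of the
#' residue interaction network. A residue pair may carry several edges of
#' different types. Residues lacking the atoms a rule needs are silently
#' skipped by that rule.
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param criteria an [interaction_criteria()].
#' @return data frame with columns `type`, `i`, `j` (`i < j`).
#' @export
detect_interactions <- function(traj, frame = 1,
                                criteria = interaction_criteria()) {
  top <- traj$topology
  X <- matrix(traj$coords[frame, , ], nrow(top), 3)
  roles <- .role_tables(top)
  res <- top$resid
  ss <- criteria$seq_sep
  edges <- list()
  add <- function(type, m) {
    m <- .dedupe_pairs(m)
    if (nrow(m) > 0) {
      edges[[length(edges) + 1]] <<- data.frame(type = type, i = m[, 1],
                                                j = m[, 2])
    }
  }

  # hydrogen bonds: donor-acceptor distance, plus D-H...A angle when the
  # donor carries a hydrogen within bonding distance (1.3 A)
  if (length(roles$donors) > 0 && length(roles$acceptors) > 0) {
    Dxyz <- X[roles$donors, , drop = FALSE]
    Axyz <- X[roles$acceptors, , drop = FALSE]
    DA <- .pdist2(Dxyz, Axyz)
    hit <- which(DA <= criteria$hbond_dist, arr.ind = TRUE)
    keep <- matrix(integer(0), 0, 2)
    if (nrow(hit) > 0) {
      Hxyz <- X[roles$hydrogens, , drop = FALSE]
      Hres <- res[roles$hydrogens]
      for (r in seq_len(nrow(hit))) {
        da <- roles$donors[hit[r, 1]]
        aa <- roles$acceptors[hit[r, 2]]
        ri <- res[da]
        rj <- res[aa]
        if (ri == rj || abs(ri - rj) < ss) next
        hs <- which(Hres == ri)
        if (length(hs) > 0) {
          dh <- .pdist2(matrix(X[da, ], 1, 3), Hxyz[hs, , drop = FALSE])
          hs <- hs[dh[1, ] <= 1.3]
        }
        ok <- if (length(hs) == 0) {
          TRUE # no modeled hydrogens: heavy-atom-only rule
        } else {
          any(vapply(hs, function(h) {
            ang <- .angle_deg(X[da, ], Hxyz[h, ], X[aa, ])
            is.finite(ang) && ang >= criteria$hbond_angle
          }, logical(1)))
        }
        if (ok) keep <- rbind(keep, c(min(ri, rj), max(ri, rj)))
      }
    }
    add("hydrogen_bond", keep)
  }

  # van der Waals: heavy-atom contact below the radii sum plus slack
  if (length(roles$heavy) > 1) {
    Hx <- X[roles$heavy, , drop = FALSE]
    rad <- .vdw_radii[top$element[roles$heavy]]
    D <- .pdist2(Hx, Hx)
    cut <- outer(rad, rad, "+") + criteria$vdw_slack
    hit <- which(D <= cut, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      i <- res[roles$heavy[hit[, 1]]]
      j <- res[roles$heavy[hit[, 2]]]
      keep <- abs(i - j) >= ss
      add("van_der_waals", cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE])
    }
  }

  pos <- .group_centers(roles$pos, X, res)
  neg <- .group_centers(roles$neg, X, res)
  rng <- .group_centers(roles$rings, X, res)
  add("salt_bridge",
      .pairs_within(pos$xyz, pos$resid, neg$xyz, neg$resid,
                    criteria$salt_dist, ss))
  add("pi_pi",
      .pairs_within(rng$xyz, rng$resid, rng$xyz, rng$resid,
                    criteria$pipi_dist, ss))
  add("cation_pi",
      .pairs_within(pos$xyz, pos$resid, rng$xyz, rng$resid,
                    criteria$catpi_dist, ss))

  if (length(edges) == 0) {
    return(data.frame(type = character(0), i = integer(0), j = integer(0)))
  }
  out <- do.call(rbind, edges)
  out <- out[order(out$type, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary interaction time series over a trajectory
#'
#' Runs [detect_interactions()] on every frame and assembles, per
#' (interaction type, residue pair), the binary adjacency time series
#' A_ij(t). Pairs that are never on are omitted (implicitly all-zero).
#'
#' @param traj a [trajectory()].
#' @param criteria an [interaction_criteria()].
#' @return An `AdjacencySet`: list with `n_frames`, `index` (data frame
#'   `type`, `i`, `j`) and `series` (list of 0/1 integer vectors, one per
#'   index row).
#' @export
build_adjacency_series <- function(traj, criteria = interaction_criteria()) {
  nf <- n_frames(traj)
  store <- new.env(parent = emptyenv())
  for (t in seq_len(nf)) {
    ed <- detect_interactions(traj, t, criteria)
    if (nrow(ed) == 0) next
    keys <- paste(ed$type, ed$i, ed$j, sep = ":")
    for (key in keys) {
      s <- store[[key]]
      if (is.null(s)) s <- integer(nf)
      s[t] <- 1L
      store[[key]] <- s
    }
  }
  keys <- sort(ls(store))
  parts <- strsplit(keys, ":", fixed = TRUE)
  index <- data.frame(
    type = vapply(parts, `[`, "", 1),
    i = as.integer(vapply(parts, `[`, "", 2)),
    j = as.integer(vapply(parts, `[`, "", 3))
  )
  structure(list(n_frames = nf, index = index,
                 series = lapply(keys, function(k) store[[k]])),
            class = "AdjacencySet")
}

#' @export
print.AdjacencySet <- function(x, ...) {
  cat(sprintf("AdjacencySet: %d series over %d frames (%s)\n",
              nrow(x$index), x$n_frames,
              paste(sprintf("%s: %d", names(table(x$index$type)),
                            table(x$index$type)), collapse = ", ")))
  invisible(x)
}

#' Extract one binary series from an adjacency set
#' @param adj an `AdjacencySet`.
#' @param type interaction type.
#' @param i,j residue pair (order-free).
#' @return integer 0/1 vector of length `n_frames` (all zeros if absent).
#' @export
adjacency_series <- function(adj, type, i, j) {
  lo <- min(i, j)
  hi <- max(i, j)
  hit <- which(adj$index$type == type & adj$index$i == lo & adj$index$j == hi)
  if (length(hit) == 0) return(integer(adj$n_frames))
  adj$series[[hit]]
}

#' Write an adjacency set as run-length-encoded TSV
#'
#' One row per (type, pair) with the series stored as a run-length string
#' (`value x length` pairs, e.g. `0x5,1x3,0x2`), a compact plain-text layout
#' for sparse on/off series.
#'
#' @param adj an `AdjacencySet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency_series <- function(adj, path) {
  rle_str <- vapply(adj$series, function(s) {
    r <- rle(s)
    paste(sprintf("%dx%d", r$values, r$lengths), collapse = ",")
  }, "")
  out <- cbind(adj$index, n_frames = adj$n_frames, rle = rle_str)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an adjacency set written by [write_adjacency_series()]
#' @param path TSV path.
#' @return An `AdjacencySet`.
#' @export
read_adjacency_series <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  series <- lapply(tab$rle, function(s) {
    runs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "x", fixed = TRUE)
    inverse.rle(list(values = as.integer(vapply(runs, `[`, "", 1)),
                     lengths = as.integer(vapply(runs, `[`, "", 2))))
  })
  structure(list(n_frames = tab$n_frames[1],
                 index = tab[, c("type", "i", "j")],
                 series = series),
            class = "AdjacencySet")
}

#' Write one frame's edge list in SIF format
#' @param edges data frame from [detect_interactions()].
#' @param path output path (`.sif`).
#' @return `path`, invisibly.
#' @export
write_sif_edges <- function(edges, path) {
  writeLines(sprintf("%d\t%s\t%d", edges$i, edges$type, edges$j), path)
  invisible(path)
}
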