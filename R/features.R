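#' Per-frame domain centers
#'
#' The center of a domain in a frame is the unweighted mean of its CA
#' coordinates (center of geometry over CA atoms).
#'
#' @param traj a [trajectory()].
#' @param part a [domain_partition()].
#' @param domains domain tags to use, in order; defaults to `a`, `b`, `bp`,
#'   `ap` when present, otherwise all tags except `"other"`.
#' @return array `frames x domains x 3` with domain tags as dimnames.
#' @export
domain_centers <- function(traj, part, domains = NULL) {
  if (is.null(domains)) {
    tags <- setdiff(unique(part$domain), "other")
    domains <- if (all(c("a", "b", "bp", "ap") %in% tags)) {
      c("a", "b", "bp", "ap")
    } else {
      tags
    }
  }
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nf, length(domains), 3),
               dimnames = list(NULL, domains, c("x", "y", "z")))
  for (d in seq_along(domains)) {
    res <- domain_residues(part, domains[d])
    if (length(res) == 0) .stopf("domain '%s' has no residues", domains[d])
    cc <- ca_coords(traj, res)
    out[, d, ] <- apply(cc, c(1, 3), mean)
  }
  out
}

#' Inter-domain distances, angles and torsion from domain centers
#'
#' For four centers (in order `a`, `b`, `bp`, `ap`) computes per frame the
#' six pairwise center distances `R_ij` (Angstrom), the two hinge angles
#' `theta_abbp` (at `b`, formed by `a` and `bp`) and `theta_bbpap` (at `bp`),
#' in degrees within \[0, 180\], and the signed torsion `phi_abbpap` of the
#' ordered centers (IUPAC right-handed convention, degrees in (-180, 180\]).
#' Frames with coincident or collinear centers get `NA` for the affected
#' angle/torsion.
#'
#' @param centers array `frames x 4 x 3` from [domain_centers()].
#' @return data frame, one row per frame, columns `R_<i><j>`,
#'   `theta_abbp`, `theta_bbpap`, `phi_abbpap`.
#' @export
domain_geometry_features <- function(centers) {
  if (length(dim(centers)) != 3 || dim(centers)[2] != 4) {
    .stopf("centers must be a frames x 4 x 3 array")
  }
  tags <- dimnames(centers)[[2]]
  if (is.null(tags)) tags <- c("a", "b", "bp", "ap")
  nf <- dim(centers)[1]
  pairs <- utils::combn(4, 2)
  out <- data.frame(frame = seq_len(nf))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    d <- sqrt(rowSums((centers[, i, , drop = FALSE] -
                         centers[, j, , drop = FALSE])^2, dims = 1))
    out[[paste0("R_", tags[i], tags[j])]] <- as.vector(d)
  }
  th1 <- numeric(nf)
  th2 <- numeric(nf)
  phi <- numeric(nf)
  for (t in seq_len(nf)) {
    p <- lapply(1:4, function(k) centers[t, k, ])
    th1[t] <- .angle_deg(p[[1]], p[[2]], p[[3]])
    th2[t] <- .angle_deg(p[[2]], p[[3]], p[[4]])
    phi[t] <- .dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  out[[paste0("theta_", tags[1], tags[2], tags[3])]] <- th1
  out[[paste0("theta_", tags[2], tags[3], tags[4])]] <- th2
  out[[paste0("phi_", paste(tags, collapse = ""))]] <- phi
  out
}

#' Per-frame CA-CA residue distance matrices
#'
#' Full symmetric Euclidean distance matrix between CA atoms of the selected
#' residues, per frame. Distances between specific residue pairs (e.g.
#' catalytic cysteine pairs) are obtained by restricting `residues`; there is
#' no separate code path.
#'
#' @param traj a [trajectory()].
#' @param residues residue indices to include (default: all with CA).
#' @return A `ResidueDistanceSeries`: list with `resid` and `d`, an array
#'   `frames x n x n` (Angstrom).
#' @export
residue_distance_series <- function(traj, residues = NULL) {
  cc <- ca_coords(traj, residues)
  resid <- as.integer(dimnames(cc)[[2]])
  nf <- dim(cc)[1]
  n <- dim(cc)[2]
  d <- array(0, c(nf, n, n), dimnames = list(NULL, resid, resid))
  for (t in seq_len(nf)) {
    X <- matrix(cc[t, , ], n, 3)
    d[t, , ] <- as.matrix(stats::dist(X))
  }
  structure(list(resid = resid, d = d), class = "ResidueDistanceSeries")
}

#' Distance time series for selected residue pairs
#'
#' Streaming-friendly companion to [residue_distance_series()]: evaluates
#' only the requested pairs, frame by frame, without forming the full matrix.
#'
#' @param traj a [trajectory()].
#' @param pairs 2-column matrix (or list of length-2 vectors) of residue
#'   index pairs.
#' @return matrix `frames x n_pairs`, columns named `"i-j"`.
#' @export
residue_pair_distances <- function(traj, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ci <- ca_coords(traj, pairs[, 1])
  cj <- ca_coords(traj, pairs[, 2])
  out <- sqrt(rowSums((ci - cj)^2, dims = 2))
  out <- matrix(out, nrow = dim(ci)[1])
  colnames(out) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  out
}
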