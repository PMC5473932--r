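#' Least-squares superposition of all frames onto a reference
#'
#' Removes global rotation and translation by a rigid-body least-squares
#' (Kabsch) fit of every frame onto the reference frame over the CA atoms of
#' the fit selection — for a four-domain a-b-bp-ap protein typically the CA
#' of domains b and bp, which act as the base for the terminal-domain hinge
#' motions. All atoms are transformed; only the fit selection defines the
#' superposition.
#'
#' @param traj a [trajectory()].
#' @param reference reference frame index (default 1).
#' @param fit_residues residue indices whose CA atoms define the fit
#'   (default: all residues with CA).
#' @return A new `Trajectory` with fitted coordinates.
#' @export
superpose_trajectory <- function(traj, reference = 1, fit_residues = NULL) {
  fit_idx <- .ca_atom_indices(traj$topology, fit_residues)
  if (length(fit_idx) < 3) .stopf("need at least 3 CA atoms in the fit selection")
  xyz <- .flatten_xyz(traj$coords)
  xyz_inds <- as.vector(rbind(3 * fit_idx - 2, 3 * fit_idx - 1, 3 * fit_idx))
  fitted <- bio3d::fit.xyz(fixed = xyz[reference, ], mobile = xyz,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  trajectory(traj$topology, .unflatten_xyz(fitted), traj$frame_labels)
}

# backbone atom indices for a residue selection: N, CA, C, O when present,
# CA only for coarse (CA-only) topologies
.backbone_atom_indices <- function(top, residues = NULL) {
  if (is.null(residues)) residues <- unique(top$resid)
  bb <- which(top$resid %in% residues & top$atom %in% c("N", "CA", "C", "O"))
  if (length(bb) == 0) .stopf("selection contains no backbone atoms")
  bb
}

#' Per-frame RMSD relative to a reference frame
#'
#' Backbone RMSD (N, CA, C, O when present; CA-only for coarse topologies)
#' of each selection in each frame against the reference frame, on the
#' coordinates as given (superpose first with [superpose_trajectory()] if
#' global motion should be removed).
#'
#' @param traj a [trajectory()].
#' @param reference reference frame index (default 1).
#' @param selections named list of residue-index vectors; `NULL` entries mean
#'   all residues. Default: one selection named `whole` covering everything.
#' @return data frame with `frame` and one RMSD column (Angstrom) per
#'   selection.
#' @export
rmsd_series <- function(traj, reference = 1, selections = list(whole = NULL)) {
  if (length(selections) == 0) .stopf("no selections given")
  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf))
  for (nm in names(selections)) {
    idx <- .backbone_atom_indices(traj$topology, selections[[nm]])
    ref <- traj$coords[reference, idx, , drop = TRUE]
    dev <- sweep(traj$coords[, idx, , drop = FALSE], c(2, 3), ref)
    out[[nm]] <- sqrt(rowSums(dev^2, dims = 1) / length(idx))
  }
  out
}

#' Dynamic cross-correlation matrix of CA displacements
#'
#' Normalized covariance of atomic displacement vectors about their
#' trajectory mean: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`,
#' entries in \[-1, 1\], unit diagonal. Atoms with zero displacement variance
#' get `NA` rows/columns. Compute on a superposed trajectory so the
#' correlations reflect internal motions.
#'
#' @param traj a (superposed) [trajectory()].
#' @param residues residue selection (default: all with CA).
#' @return symmetric matrix with residue ids as dimnames.
#' @export
cross_correlation_matrix <- function(traj, residues = NULL) {
  cc <- ca_coords(traj, residues)
  nf <- dim(cc)[1]
  if (nf < 2) .stopf("need at least 2 frames")
  n <- dim(cc)[2]
  S <- matrix(0, n, n)
  for (k in 1:3) {
    X <- matrix(cc[, , k], nf, n)
    X <- sweep(X, 2, colMeans(X))
    S <- S + crossprod(X) / nf
  }
  v <- diag(S)
  C <- S / sqrt(outer(v, v))
  C[v < 1e-12, ] <- NA_real_
  C[, v < 1e-12] <- NA_real_
  dimnames(C) <- list(dimnames(cc)[[2]], dimnames(cc)[[2]])
  C
}

#' Principal component analysis of CA Cartesian coordinates
#'
#' Eigendecomposition of the covariance matrix of the concatenated CA
#' coordinates (3N dimensions) of a superposed trajectory; the essential
#' dynamics of the selection. Degenerate directions simply carry zero
#' eigenvalues. Use `residues` to analyse two-domain subsets (ab, bbp, bpap).
#'
#' @param traj a (superposed) [trajectory()].
#' @param residues residue selection (default: all with CA).
#' @return A `PcaModel`: list with `mean` (3N), orthonormal `vectors`
#'   (3N x k), `values` (eigenvalues, Angstrom^2, descending), `projections`
#'   (frames x k, centered), `resid`.
#' @export
pca_modes <- function(traj, residues = NULL) {
  cc <- ca_coords(traj, residues)
  X <- .flatten_xyz(cc)
  nf <- nrow(X)
  if (nf < 2) .stopf("need at least 2 frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  values <- sv$d^2 / (nf - 1)
  k <- length(values)
  proj <- Xc %*% sv$v
  structure(list(mean = mu, vectors = sv$v, values = values,
                 projections = proj,
                 resid = as.integer(dimnames(cc)[[2]])),
            class = "PcaModel")
}

#' @export
print.PcaModel <- function(x, ...) {
  tv <- sum(x$values)
  frac <- if (tv > 0) x$values[1:min(4, length(x$values))] / tv else
    rep(0, min(4, length(x$values)))
  cat(sprintf("PcaModel: %d components over %d residues; PC1-PC%d variance fractions: %s\n",
              length(x$values), length(x$resid), length(frac),
              paste(sprintf("%.3f", frac), collapse = ", ")))
  invisible(x)
}

#' Fraction of total variance per principal component
#' @param model a `PcaModel`.
#' @return numeric vector summing to 1 (or zeros for a motionless input).
#' @export
variance_fraction <- function(model) {
  tv <- sum(model$values)
  if (tv <= 0) return(rep(0, length(model$values)))
  model$values / tv
}

#' Inner products between eigenvector sets of two PCA models
#'
#' Sampling-convergence check: entry (m, n) is the absolute inner product of
#' model A's m-th and model B's n-th eigenvectors. Identical subspaces give a
#' permutation-like matrix with diagonal entries near 1.
#'
#' @param a,b `PcaModel`s over the same atom selection.
#' @param k number of leading components to compare.
#' @return `k x k` matrix of absolute inner products in \[0, 1\].
#' @export
eigenvector_overlap <- function(a, b, k = 4) {
  if (nrow(a$vectors) != nrow(b$vectors)) {
    .stopf("eigenvector dimensions differ (%d vs %d)",
           nrow(a$vectors), nrow(b$vectors))
  }
  k <- min(k, ncol(a$vectors), ncol(b$vectors))
  abs(crossprod(a$vectors[, seq_len(k), drop = FALSE],
                b$vectors[, seq_len(k), drop = FALSE]))
}

#' Free-energy landscape projected on two principal components
#'
#' Gaussian-kernel density estimate of the projections on a component pair,
#' converted to a free-energy surface `F = -ln(p / p_max)` in units of kT, so
#' the global minimum is 0. Bandwidth defaults to the normal-reference
#' (Scott-type) rule per axis.
#'
#' @param model a `PcaModel`.
#' @param components length-2 integer vector of component indices.
#' @param grid_size number of grid points per axis.
#' @param bandwidth scalar or length-2 bandwidth (Angstrom); `NULL` for the
#'   normal-reference rule.
#' @return A `FELGrid`: list with `x`, `y` (grid coordinates), `F` (matrix,
#'   kT), `bandwidth`, `components`.
#' @export
fel_projection <- function(model, components = c(1, 2), grid_size = 100,
                           bandwidth = NULL) {
  stopifnot(length(components) == 2)
  p1 <- model$projections[, components[1]]
  p2 <- model$projections[, components[2]]
  if (length(p1) < 100) {
    warning("fewer than 100 frames; the density estimate will be rough")
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(p1), MASS::bandwidth.nrd(p2))
  }
  bandwidth <- rep_len(bandwidth, 2)
  if (any(bandwidth <= 0)) .stopf("bandwidth must be positive")
  pad <- 3 * bandwidth
  kd <- MASS::kde2d(p1, p2, h = bandwidth, n = grid_size,
                    lims = c(range(p1) + c(-1, 1) * pad[1],
                             range(p2) + c(-1, 1) * pad[2]))
  FF <- -log(kd$z / max(kd$z))
  structure(list(x = kd$x, y = kd$y, F = FF, bandwidth = bandwidth,
                 components = components),
            class = "FELGrid")
}

#' Local minima of a free-energy landscape grid
#'
#' Grid cells whose free energy is strictly below all of their (up to 8)
#' neighbors and below `f_max`.
#'
#' @param fel a `FELGrid`.
#' @param f_max only report minima with `F < f_max` (kT); default 10.
#' @return data frame with columns `x`, `y`, `F`, ordered by depth.
#' @export
fel_local_minima <- function(fel, f_max = 10) {
  FF <- fel$F
  nx <- nrow(FF)
  ny <- ncol(FF)
  mins <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      f <- FF[i, j]
      if (!is.finite(f) || f >= f_max) next
      nb <- FF[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
      if (sum(nb < f) == 0 && sum(nb == f) == 1) {
        mins[[length(mins) + 1]] <- data.frame(x = fel$x[i], y = fel$y[j], F = f)
      }
    }
  }
  if (length(mins) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), F = numeric(0)))
  }
  out <- do.call(rbind, mins)
  out[order(out$F), , drop = FALSE]
}

#' Write a free-energy landscape as long-format TSV
#' @param fel a `FELGrid`.
#' @param path output path; columns `x`, `y`, `F`.
#' @return `path`, invisibly.
#' @export
write_fel <- function(fel, path) {
  long <- data.frame(x = rep(fel$x, times = length(fel$y)),
                     y = rep(fel$y, each = length(fel$x)),
                     F = as.vector(fel$F))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}
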