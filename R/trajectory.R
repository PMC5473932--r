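#' Build a topology table
#'
#' A topology is an ordered atom table: one row per atom with its 1-based
#' residue index, 3-letter residue name, atom name, element symbol and chain
#' id. Residue indices must be non-decreasing along the table. Coarse-grained
#' (pseudo-atom) topologies use element `"X"` for atoms that should not take
#' part in van der Waals contact detection.
#'
#' @param resid integer vector of 1-based residue indices (non-decreasing).
#' @param resname residue names (3-letter codes), recycled.
#' @param atom atom names (e.g. `"CA"`, `"N"`, `"OD1"`), recycled.
#' @param element element symbols; derived from the first letter of the atom
#'   name when `NULL`.
#' @param chain chain identifier, single string.
#' @return A `Topology` data frame.
#' @export
topology <- function(resid, resname = "ALA", atom = "CA", element = NULL,
                     chain = "A") {
  resid <- as.integer(resid)
  n <- length(resid)
  if (n < 1) .stopf("topology needs at least one atom")
  if (any(diff(resid) < 0)) .stopf("residue indices must be non-decreasing")
  resname <- rep_len(as.character(resname), n)
  atom <- rep_len(as.character(atom), n)
  if (is.null(element)) {
    element <- substr(gsub("[0-9']", "", atom), 1, 1)
  }
  element <- rep_len(as.character(element), n)
  top <- data.frame(resid = resid, resname = resname, atom = atom,
                    element = element, chain = rep_len(chain, n),
                    stringsAsFactors = FALSE)
  class(top) <- c("Topology", "data.frame")
  top
}

#' Build a trajectory object
#'
#' A trajectory couples a [topology()] with a `frames x atoms x 3` coordinate
#' array in Angstrom and optional per-frame state labels.
#'
#' @param top a `Topology`.
#' @param coords numeric array `frames x atoms x 3` (Angstrom).
#' @param frame_labels optional character vector of per-frame state tags.
#' @return A `Trajectory` object.
#' @export
trajectory <- function(top, coords, frame_labels = NULL) {
  if (!inherits(top, "Topology")) top <- as_topology(top)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    .stopf("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != nrow(top)) {
    .stopf("coords has %d atoms but topology has %d", dim(coords)[2], nrow(top))
  }
  if (!all(is.finite(coords))) .stopf("coordinates contain non-finite values")
  if (!is.null(frame_labels) && length(frame_labels) != dim(coords)[1]) {
    .stopf("frame_labels length must equal the number of frames")
  }
  structure(list(topology = top, coords = coords, frame_labels = frame_labels),
            class = "Trajectory")
}

as_topology <- function(x) {
  topology(resid = x$resid, resname = x$resname, atom = x$atom,
           element = x$element, chain = x$chain[1])
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues\n",
              n_frames(x), nrow(x$topology), length(unique(x$topology$resid))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# atom indices of the Calpha of each residue (in residue order)
.ca_atom_indices <- function(top, residues = NULL) {
  idx <- which(top$atom == "CA")
  res <- top$resid[idx]
  if (anyDuplicated(res)) .stopf("topology has residues with more than one CA")
  if (is.null(residues)) return(idx)
  pos <- match(residues, res)
  if (anyNA(pos)) {
    .stopf("residue(s) without CA atom: %s",
           paste(residues[is.na(pos)], collapse = ", "))
  }
  idx[pos]
}

#' Calpha coordinates of a trajectory
#'
#' @param traj a `Trajectory`.
#' @param residues optional residue indices to select (default: all residues
#'   that have a CA atom, in residue order).
#' @return array `frames x n_residues x 3` with residue ids as dimnames.
#' @export
ca_coords <- function(traj, residues = NULL) {
  top <- traj$topology
  idx <- .ca_atom_indices(top, residues)
  out <- traj$coords[, idx, , drop = FALSE]
  dimnames(out) <- list(NULL, top$resid[idx], c("x", "y", "z"))
  out
}

# frames x 3N matrix (atom-major xyz triples) from a frames x N x 3 array
.flatten_xyz <- function(arr) {
  nf <- dim(arr)[1]
  na <- dim(arr)[2]
  m <- matrix(0, nf, 3 * na)
  m[, seq(1, 3 * na, 3)] <- arr[, , 1]
  m[, seq(2, 3 * na, 3)] <- arr[, , 2]
  m[, seq(3, 3 * na, 3)] <- arr[, , 3]
  m
}

.unflatten_xyz <- function(m) {
  nf <- nrow(m)
  na <- ncol(m) / 3
  arr <- array(0, c(nf, na, 3))
  arr[, , 1] <- m[, seq(1, 3 * na, 3)]
  arr[, , 2] <- m[, seq(2, 3 * na, 3)]
  arr[, , 3] <- m[, seq(3, 3 * na, 3)]
  arr
}

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per `MODEL` record (a file without `MODEL` records yields one
#' frame). The atom order must be identical across models; a model with a
#' deviating atom count is rejected with its frame index. By default only
#' chain A is read; multi-chain files require an explicit `chain`.
#'
#' @param path path to a PDB file.
#' @param chain chain id to read (default `"A"`; used only when the file has
#'   more than one chain).
#' @return A [trajectory()].
#' @export
read_structure_frames <- function(path, chain = "A") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(is_atom[bounds[k]:(bounds[k + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      .stopf("inconsistent atom count in frame %d (%d atoms, expected %d)",
             bad, counts[bad], counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain[!is.na(at$chain)])
  sel <- rep(TRUE, nrow(at))
  if (length(chains) > 1) {
    if (!chain %in% chains) .stopf("chain '%s' not present in %s", chain, path)
    sel <- !is.na(at$chain) & at$chain == chain
  }
  keep <- which(sel)
  if (length(keep) == 0) .stopf("no atoms selected from %s", path)
  xyz_cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
  elem <- at$elesy[keep]
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- NULL
  } else {
    elem[is.na(elem) | elem == ""] <- substr(at$elety[keep][is.na(elem) | elem == ""], 1, 1)
  }
  top <- topology(resid = at$resno[keep], resname = at$resid[keep],
                  atom = at$elety[keep], element = elem,
                  chain = if (length(chains) >= 1) chains[1] else "A")
  trajectory(top, .unflatten_xyz(xyz))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written with the standard 3-decimal PDB precision
#' (round-trip accurate to 1e-3 Angstrom).
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_frames <- function(traj, path) {
  top <- traj$topology
  bio3d::write.pdb(file = path, xyz = .flatten_xyz(traj$coords),
                   resno = top$resid, resid = top$resname, elety = top$atom,
                   chain = top$chain, elesy = top$element)
  invisible(path)
}

#' Build a domain partition from residue ranges
#'
#' Assigns every residue of the topology to a domain tag. Residues not listed
#' in any range are tagged `"other"`. Overlapping ranges and ranges outside
#' the topology are rejected.
#'
#' @param ranges named list; each element is `c(start, end)` or a list of such
#'   ranges, keyed by domain tag (e.g. `a`, `b`, `bp`, `ap`, `x`).
#' @param top a `Topology`.
#' @return A `DomainPartition` data frame with columns `resid`, `domain`.
#' @export
domain_partition <- function(ranges, top) {
  res <- sort(unique(top$resid))
  tag <- rep("other", length(res))
  names(tag) <- res
  seen <- integer(0)
  for (dom in names(ranges)) {
    rr <- ranges[[dom]]
    if (!is.list(rr)) rr <- list(rr)
    for (r in rr) {
      r <- .parse_range(r)
      span <- seq.int(r[1], r[2])
      if (!all(span %in% res)) {
        .stopf("domain '%s' range %d-%d extends outside the topology",
               dom, r[1], r[2])
      }
      if (any(span %in% seen)) {
        .stopf("domain '%s' range %d-%d overlaps a previous assignment",
               dom, r[1], r[2])
      }
      seen <- c(seen, span)
      tag[as.character(span)] <- dom
    }
  }
  part <- data.frame(resid = res, domain = tag, row.names = NULL,
                     stringsAsFactors = FALSE)
  class(part) <- c("DomainPartition", "data.frame")
  part
}

.parse_range <- function(r) {
  if (is.character(r)) {
    parts <- as.integer(strsplit(r, "[-:]")[[1]])
  } else {
    parts <- as.integer(r)
  }
  if (length(parts) == 1) parts <- c(parts, parts)
  if (length(parts) != 2 || anyNA(parts) || parts[2] < parts[1]) {
    .stopf("malformed residue range: %s", paste(r, collapse = ","))
  }
  parts
}

#' Read a domain partition from a YAML or JSON config
#'
#' The config maps domain tags to residue ranges, e.g. in YAML
#' `a: [1, 134]` or `a: "1-134"`. An empty config assigns every residue to
#' `"other"`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param top a `Topology`.
#' @return A `DomainPartition`.
#' @export
read_domain_partition <- function(path, top) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  ranges <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    .stopf("unknown domain config format: .%s (use YAML or JSON)", ext)
  }
  if (is.null(ranges)) ranges <- list()
  domain_partition(ranges, top)
}

#' Residue indices belonging to given domain tags
#' @param part a `DomainPartition`.
#' @param domains character vector of domain tags.
#' @return integer residue indices.
#' @export
domain_residues <- function(part, domains) {
  part$resid[part$domain %in% domains]
}

#' Write a per-frame feature table as TSV
#'
#' One row per frame, tab-separated, header line naming the features; the
#' `state` column carries the per-frame labels. Numeric values are written
#' with round-trip (shortest exact) precision. Non-finite values are rejected
#' with their row and column.
#'
#' @param table data frame with a `state` column and numeric feature columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!"state" %in% names(table)) .stopf("feature table must have a 'state' column")
  for (cn in names(table)) {
    col <- table[[cn]]
    if (is.numeric(col) && !all(is.finite(col))) {
      bad <- which(!is.finite(col))[1]
      .stopf("non-finite value at row %d, column '%s'", bad, cn)
    }
  }
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path path to a TSV feature table.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t"))
}
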