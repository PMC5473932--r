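#' Maximum interaction lifetime of a binary series
#'
#' The maximum interaction lifetime Gamma of an interaction time series
#' A_ij(t) is the largest window length tau for which some start tau0 exists
#' with A_ij(t) = 1 for all t in \[tau0, tau0 + tau - 1\] — i.e. the length of
#' the longest run of consecutive on-frames. A series that is never on has
#' lifetime 0 (the window set is empty).
#'
#' @param series integer/logical vector of 0/1 over frames.
#' @return integer lifetime in frames.
#' @export
max_lifetime <- function(series) {
  if (is.logical(series)) series <- as.integer(series)
  if (length(series) == 0) return(0L)
  if (anyNA(series) || !all(series %in% c(0L, 1L))) {
    .stopf("series must contain only 0 and 1")
  }
  r <- rle(as.integer(series))
  on <- r$lengths[r$values == 1L]
  if (length(on) == 0) 0L else max(on)
}

#' Compile adjacency time series into a dynamic residue interaction network
#'
#' Reduces every per-pair, per-type binary adjacency series of one state's
#' ensemble to its maximum interaction lifetime Gamma_ij, producing one
#' weighted residue graph (the DRIN) covering all interaction types.
#' Zero-lifetime pairs are dropped. When several independent trajectories of
#' the same state are given, Gamma is computed per trajectory and the maximum
#' is taken — a run of consecutive frames cannot span the boundary between
#' independent simulations.
#'
#' @param adj an `AdjacencySet` (see [build_adjacency_series()]) or a list of
#'   them (one per trajectory of the state).
#' @param state state label stored on the graph (e.g. `"ox"`, `"red"`).
#' @return A `DRINGraph`: data frame `type`, `i`, `j`, `gamma` with
#'   attributes `state` and `n_frames`.
#' @export
compile_drin <- function(adj, state) {
  if (inherits(adj, "AdjacencySet")) adj <- list(adj)
  acc <- new.env(parent = emptyenv())
  total_frames <- 0L
  for (a in adj) {
    stopifnot(inherits(a, "AdjacencySet"))
    total_frames <- total_frames + a$n_frames
    for (r in seq_len(nrow(a$index))) {
      key <- paste(a$index$type[r], a$index$i[r], a$index$j[r], sep = ":")
      g <- max_lifetime(a$series[[r]])
      prev <- acc[[key]]
      if (is.null(prev) || g > prev) acc[[key]] <- g
    }
  }
  keys <- sort(ls(acc))
  gamma <- vapply(keys, function(k) acc[[k]], integer(1), USE.NAMES = FALSE)
  keep <- gamma > 0
  parts <- strsplit(keys[keep], ":", fixed = TRUE)
  out <- data.frame(
    type = vapply(parts, `[`, "", 1),
    i = as.integer(vapply(parts, `[`, "", 2)),
    j = as.integer(vapply(parts, `[`, "", 3)),
    gamma = gamma[keep]
  )
  structure(out, class = c("DRINGraph", "data.frame"),
            state = state, n_frames = total_frames)
}

#' Lifetime of one pair in a DRIN graph (0 when absent)
#' @param graph a `DRINGraph`.
#' @param type interaction type.
#' @param i,j residue pair (order-free).
#' @return integer Gamma in frames.
#' @export
drin_gamma <- function(graph, type, i, j) {
  lo <- min(i, j)
  hi <- max(i, j)
  hit <- which(graph$type == type & graph$i == lo & graph$j == hi)
  if (length(hit) == 0) 0L else graph$gamma[hit]
}

#' Differential dynamic residue interaction network
#'
#' Contrasts the two states' DRINs through the shrunken log2 fold change of
#' maximum interaction lifetimes,
#' `Delta_ij = log2((Gamma_ox + eps) / (Gamma_red + eps))`,
#' over the union of the two edge sets (an edge missing from one state
#' contributes Gamma = 0). The pseudocount eps keeps Delta finite; positive
#' Delta marks interactions dominating in the first (ox) state, negative in
#' the second (red), and swapping the states negates every Delta exactly.
#'
#' @param ox,red `DRINGraph`s of the two states.
#' @param eps pseudocount in frames (> 0); default 1.
#' @return A `DifferentialGraph`: data frame `type`, `i`, `j`, `gamma_ox`,
#'   `gamma_red`, `delta` with attributes `eps` and the state labels.
#' @export
differential_drin <- function(ox, red, eps = 1) {
  if (eps <= 0) .stopf("eps must be positive")
  key_ox <- paste(ox$type, ox$i, ox$j, sep = ":")
  key_rd <- paste(red$type, red$i, red$j, sep = ":")
  keys <- sort(union(key_ox, key_rd))
  g_ox <- ox$gamma[match(keys, key_ox)]
  g_rd <- red$gamma[match(keys, key_rd)]
  g_ox[is.na(g_ox)] <- 0L
  g_rd[is.na(g_rd)] <- 0L
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    type = vapply(parts, `[`, "", 1),
    i = as.integer(vapply(parts, `[`, "", 2)),
    j = as.integer(vapply(parts, `[`, "", 3)),
    gamma_ox = g_ox,
    gamma_red = g_rd,
    # written as a difference of logs so state swap negates delta bitwise
    delta = log2(g_ox + eps) - log2(g_rd + eps)
  )
  structure(out, class = c("DifferentialGraph", "data.frame"),
            eps = eps,
            states = c(attr(ox, "state") %||% "ox",
                       attr(red, "state") %||% "red"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.DRINGraph <- function(x, ...) {
  cat(sprintf("DRINGraph [%s]: %d edges over %d frames (%s)\n",
              attr(x, "state") %||% "?", nrow(x), attr(x, "n_frames"),
              paste(sprintf("%s: %d", names(table(x$type)), table(x$type)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.DifferentialGraph <- function(x, ...) {
  cutoff <- attr(x, "cutoff")
  cat(sprintf("DifferentialGraph: %d edges (eps = %s%s)\n", nrow(x),
              format(attr(x, "eps")),
              if (is.null(cutoff)) "" else sprintf(", |Delta| >= %s",
                                                   format(cutoff))))
  if (nrow(x) > 0) {
    top <- x[order(-abs(x$delta)), , drop = FALSE][seq_len(min(3, nrow(x))), ]
    for (r in seq_len(nrow(top))) {
      cat(sprintf("  %s %d-%d: Gamma %d vs %d, Delta = %.2f\n", top$type[r],
                  top$i[r], top$j[r], top$gamma_ox[r], top$gamma_red[r],
                  top$delta[r]))
    }
  }
  invisible(x)
}

#' Threshold a differential network and merge interaction types
#'
#' Keeps edges with `|Delta| >= cutoff` and merges all interaction types into
#' a single residue graph in which a residue pair may carry parallel edges of
#' different types. The node set is the set of endpoints of surviving edges.
#'
#' @param diff a `DifferentialGraph` (all types together) or a list of
#'   per-type `DifferentialGraph`s.
#' @param cutoff minimum |Delta| (>= 0); default 1, i.e. a two-fold
#'   persistence change.
#' @return A `DifferentialGraph` restricted to surviving edges, with
#'   attribute `cutoff`.
#' @export
threshold_merge <- function(diff, cutoff = 1) {
  if (cutoff < 0) .stopf("cutoff must be >= 0")
  if (!inherits(diff, "DifferentialGraph") && is.list(diff)) {
    eps <- unique(vapply(diff, function(d) attr(d, "eps"), numeric(1)))
    if (length(eps) != 1) .stopf("cannot merge graphs with different eps")
    merged <- do.call(rbind, lapply(diff, as.data.frame))
    diff <- structure(merged, class = c("DifferentialGraph", "data.frame"),
                      eps = eps, states = attr(diff[[1]], "states"))
  }
  keep <- abs(diff$delta) >= cutoff
  out <- diff[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("DifferentialGraph", "data.frame"),
            eps = attr(diff, "eps"), states = attr(diff, "states"),
            cutoff = cutoff)
}

#' Node table of a differential network
#'
#' One row per residue incident to at least one edge, with the display size
#' rule used for network rendering: a node's size is the maximum |Delta| over
#' its incident edges. Domain tags are attached when a partition is given.
#'
#' @param graph a `DifferentialGraph`.
#' @param partition optional [domain_partition()].
#' @return data frame `resid`, `size`, and `domain` when available.
#' @export
drin_nodes <- function(graph, partition = NULL) {
  res <- sort(unique(c(graph$i, graph$j)))
  size <- vapply(res, function(r) {
    max(abs(graph$delta[graph$i == r | graph$j == r]))
  }, numeric(1))
  out <- data.frame(resid = res, size = size)
  if (!is.null(partition)) {
    out$domain <- partition$domain[match(res, partition$resid)]
  }
  out
}

# sigmoid-like display weight: 0 at Delta = 0, saturating towards 1
.display_weight <- function(delta) 2 / (1 + exp(-abs(delta))) - 1

#' Export a differential network for network viewers
#'
#' GraphML (single file, via igraph) or SIF plus attribute tables
#' (`<base>.sif`, `<base>.edges.tsv`, `<base>.nodes.tsv`). Nodes carry the
#' residue label, domain tag and size (max |Delta| over incident edges);
#' edges carry type, Gamma_ox, Gamma_red, Delta, and a sigmoid-like display
#' weight `2/(1+exp(-|Delta|)) - 1` for thickness/color mapping.
#'
#' @param graph a non-empty `DifferentialGraph`.
#' @param path output path (for SIF, the `.sif` path; companion tables are
#'   written next to it).
#' @param format `"graphml"` or `"sif"`.
#' @param partition optional [domain_partition()] for node domain tags.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif"),
                         partition = NULL) {
  format <- match.arg(format)
  if (nrow(graph) == 0) .stopf("refusing to export an empty graph")
  nodes <- drin_nodes(graph, partition)
  edges <- as.data.frame(graph)
  edges$display_weight <- .display_weight(edges$delta)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(edges$i), to = as.character(edges$j),
                     type = edges$type, gamma_ox = edges$gamma_ox,
                     gamma_red = edges$gamma_red, delta = edges$delta,
                     display_weight = edges$display_weight),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$resid),
                            size = nodes$size,
                            domain = if (is.null(nodes$domain)) ""
                                     else nodes$domain))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_sif_edges(edges, path)
    base <- sub("\\.sif$", "", path)
    data.table::fwrite(edges, paste0(base, ".edges.tsv"), sep = "\t")
    data.table::fwrite(nodes, paste0(base, ".nodes.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Re-import a differential network exported by [export_graph()]
#'
#' @param path a `.graphml` or `.sif` path.
#' @param format `"graphml"` or `"sif"` (guessed from the extension when
#'   missing).
#' @return A `DifferentialGraph` (edge attributes restored exactly).
#' @export
import_graph <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path)) "graphml" else "sif"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(type = el$type,
                      i = pmin(as.integer(el$from), as.integer(el$to)),
                      j = pmax(as.integer(el$from), as.integer(el$to)),
                      gamma_ox = el$gamma_ox, gamma_red = el$gamma_red,
                      delta = el$delta)
  } else {
    base <- sub("\\.sif$", "", path)
    el <- as.data.frame(data.table::fread(paste0(base, ".edges.tsv"),
                                          sep = "\t"))
    out <- el[, c("type", "i", "j", "gamma_ox", "gamma_red", "delta")]
  }
  out <- out[order(out$type, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("DifferentialGraph", "data.frame"))
}
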