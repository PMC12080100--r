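# Graph featurization: Gaussian-smeared edge features, the global residue
# graph (one node per residue, CA-CA edges within 15 A) and the local atom
# graph (C/H/N/O/S atoms within 10 A of a residue's CA, 5 A edges, capped at
# 150 edges per receiving node).

#' Gaussian smearing specification
#'
#' `K` Gaussian centers linearly spaced over `[d_min, d_max]`; the width
#' sigma equals the center spacing.
#'
#' @param K number of centers (>= 2).
#' @param d_min,d_max range, angstrom.
#' @return a `SmearingSpec` with fields `K`, `d_min`, `d_max`, `centers`,
#'   `sigma`.
#' @export
smearing_spec <- function(K = 300L, d_min = 0, d_max = 15) {
  if (K < 2L) stop("K must be >= 2")
  centers <- seq(d_min, d_max, length.out = K)
  structure(list(K = as.integer(K), d_min = d_min, d_max = d_max,
                 centers = centers, sigma = centers[2L] - centers[1L]),
            class = "SmearingSpec")
}

#' Expand scalar distances onto a Gaussian basis
#'
#' Component k is `exp(-(d - mu_k)^2 / (2 sigma^2))`; no normalization
#' across components.
#'
#' @param d numeric vector of distances, angstrom (finite, >= 0).
#' @param spec a [smearing_spec()].
#' @return length(d) x K matrix of edge features.
#' @export
smear <- function(d, spec) {
  stopifnot(all(is.finite(d)), all(d >= 0))
  diff <- outer(d, spec$centers, "-")
  exp(-diff^2 / (2 * spec$sigma^2))
}

#' Build the global residue graph
#'
#' One node per residue carrying the amino-acid index, the 15-dimensional
#' dihedral encoding (sin, cos, mask for phi, psi, chi1-3; masked angles
#' contribute sin = cos = 0) and the CA-to-center-of-mass distance.
#' Undirected edges (stored as both orientations) connect residues whose CA
#' atoms are within `spec$d_max` of each other (inclusive); edge features
#' are the smeared CA-CA distances.
#'
#' @param s a `ProteinStructure` with at least one residue.
#' @param spec smearing spec; default K = 300 over \[0, 15\] angstrom (the
#'   edge cutoff is `spec$d_max`).
#' @return a `ResidueGraph`: list with `n_nodes`, `aa_index` (0-based),
#'   `dihedral_feats` (n x 15), `com_dist`, `coords` (CA coordinates),
#'   `edge_index` (2 x E, 1-based, receiver first), `edge_dist`,
#'   `edge_feat` (E x K).
#' @export
build_residue_graph <- function(s, spec = smearing_spec(300L, 0, 15)) {
  n <- n_residues(s)
  if (n < 1L) stop("structure has no residues")
  aa_index <- match(s$residues$residue_type, STANDARD_AA) - 1L
  aa_index[is.na(aa_index)] <- 0L  # generic residues map to slot 0
  dih <- matrix(0, n, 15L)
  colnames(dih) <- as.vector(t(outer(c("phi", "psi", "chi1", "chi2", "chi3"),
                                     c("sin", "cos", "mask"), paste, sep = "_")))
  for (i in seq_len(n)) {
    ds <- backbone_dihedrals(s, i - 1L)
    for (k in seq_along(ds)) {
      a <- ds[[k]]
      off <- (k - 1L) * 3L
      if (a$exists) dih[i, off + 1:3] <- c(sin(a$angle), cos(a$angle), 1)
    }
  }
  com <- center_of_mass(s)
  ca <- ca_coords(s)
  com_dist <- sqrt(rowSums(sweep(ca, 2L, com)^2))

  dmat <- as.matrix(stats::dist(ca))
  adj <- which(dmat <= spec$d_max & row(dmat) != col(dmat), arr.ind = TRUE)
  # receiver first; ordered by receiver then sender for determinism
  o <- order(adj[, 1L], adj[, 2L])
  recv <- adj[o, 1L]; send <- adj[o, 2L]
  edist <- dmat[cbind(recv, send)]
  structure(list(kind = "residue", n_nodes = n, aa_index = aa_index,
                 dihedral_feats = dih, com_dist = com_dist, coords = ca,
                 edge_index = rbind(recv, send), edge_dist = edist,
                 edge_feat = smear(edist, spec), smearing = spec),
            class = "ProteinGraph")
}

ATOM_TYPES <- c("C", "H", "N", "O", "S")

#' Build the local atom graph around one residue
#'
#' Nodes are all C, H, N, O and S atoms within `selection_radius` of the
#' residue's CA (inclusive, the CA itself always included; other elements
#' and heteroatoms are excluded). Undirected edges connect atom pairs within
#' `edge_cutoff`; when a receiving node has more than `max_edges` in-edges,
#' only the `max_edges` nearest senders are kept (ties broken by atom
#' serial, ascending). Node features: parent-residue amino-acid index, atom
#' type index, partial charge.
#'
#' @param s a `ProteinStructure`; atoms must carry partial charges (PQR
#'   input or [assign_charges()]).
#' @param i center residue index (0-based).
#' @param selection_radius node selection radius, angstrom.
#' @param edge_cutoff edge distance cutoff, angstrom.
#' @param max_edges per-receiver edge cap.
#' @param spec smearing spec; default K = 300 over \[0, 5\] angstrom.
#' @return an `AtomGraph`: list with `n_nodes`, `aa_index`, `atom_type`
#'   (0-based over C,H,N,O,S), `charge`, `coords`, `ca_node`,
#'   `residue_node_set`, `edge_index`, `edge_dist`, `edge_feat`,
#'   `center_residue`.
#' @export
build_atom_graph <- function(s, i, selection_radius = 10, edge_cutoff = 5,
                             max_edges = 150L,
                             spec = smearing_spec(300L, 0, 5)) {
  if (i < 0L || i >= n_residues(s)) stop("residue index out of range: ", i)
  if (any(is.na(s$atoms$charge)))
    stop("atoms lack partial charges; supply PQR input or run assign_charges()")
  ca_row <- s$residues$ca_idx[i + 1L]
  ca <- atom_coords(s, ca_row)
  xyz <- atom_coords(s)
  d_ca <- sqrt(rowSums(sweep(xyz, 2L, as.numeric(ca))^2))
  sel <- which(d_ca <= selection_radius & s$atoms$element %in% ATOM_TYPES)
  if (!(ca_row %in% sel)) sel <- sort(c(sel, ca_row))
  a <- s$atoms[sel, , drop = FALSE]
  nxyz <- xyz[sel, , drop = FALSE]
  n <- length(sel)
  aa_index <- match(a$residue_type, STANDARD_AA) - 1L
  aa_index[is.na(aa_index)] <- 0L
  atom_type <- match(a$element, ATOM_TYPES) - 1L

  dmat <- as.matrix(stats::dist(nxyz))
  recv_l <- vector("list", n); send_l <- vector("list", n)
  for (v in seq_len(n)) {
    nb <- which(dmat[v, ] <= edge_cutoff & seq_len(n) != v)
    if (length(nb) > max_edges) {
      o <- order(dmat[v, nb], a$serial[nb])
      nb <- nb[o[seq_len(max_edges)]]
      nb <- sort(nb)
    }
    recv_l[[v]] <- rep.int(v, length(nb)); send_l[[v]] <- nb
  }
  recv <- unname(unlist(recv_l)); send <- unname(unlist(send_l))
  edist <- unname(dmat[cbind(recv, send)])
  structure(list(kind = "atom", n_nodes = n, aa_index = aa_index,
                 atom_type = atom_type, charge = a$charge, coords = nxyz,
                 ca_node = match(ca_row, sel),
                 residue_node_set = which(a$residue_index == i),
                 center_residue = i,
                 edge_index = rbind(recv, send), edge_dist = edist,
                 edge_feat = smear(edist, spec), smearing = spec),
            class = "ProteinGraph")
}

#' @export
print.ProteinGraph <- function(x, ...) {
  cat("<ProteinGraph:", x$kind, "> ", x$n_nodes, " nodes, ",
      ncol(x$edge_index), " directed edges\n", sep = "")
  invisible(x)
}

# concatenate graphs into one block-diagonal batch; `graph_id` marks node
# membership for per-graph readouts
batch_graphs <- function(graphs) {
  kind <- graphs[[1L]]$kind
  sizes <- vapply(graphs, function(g) g$n_nodes, integer(1L))
  offs <- c(0L, cumsum(sizes))
  edge_index <- do.call(cbind, lapply(seq_along(graphs), function(i) {
    graphs[[i]]$edge_index + offs[i]
  }))
  out <- list(
    kind = kind, n_nodes = sum(sizes),
    aa_index = unlist(lapply(graphs, `[[`, "aa_index")),
    coords = do.call(rbind, lapply(graphs, `[[`, "coords")),
    edge_index = edge_index,
    edge_dist = unlist(lapply(graphs, `[[`, "edge_dist")),
    edge_feat = do.call(rbind, lapply(graphs, `[[`, "edge_feat")),
    graph_id = rep(seq_along(graphs), sizes),
    n_graphs = length(graphs), node_offset = offs
  )
  if (kind == "residue") {
    out$dihedral_feats <- do.call(rbind, lapply(graphs, `[[`, "dihedral_feats"))
    out$com_dist <- unlist(lapply(graphs, `[[`, "com_dist"))
  } else {
    out$atom_type <- unlist(lapply(graphs, `[[`, "atom_type"))
    out$charge <- unlist(lapply(graphs, `[[`, "charge"))
    out$ca_node <- vapply(seq_along(graphs),
                          function(i) graphs[[i]]$ca_node + offs[i], integer(1L))
    out$residue_node_sets <- lapply(seq_along(graphs),
                                    function(i) graphs[[i]]$residue_node_set + offs[i])
  }
  class(out) <- "ProteinGraph"
  out
}
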