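# SMILES -> attributed molecular graph. Parsing and conformer generation go
# through ChemmineR/ChemmineOB (OpenBabel); interatomic distances come from a
# generated 3D conformer or from topological shortest paths on the bond graph.

ATOM_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Construct and validate a molecular graph
#'
#' @param atom_features numeric matrix (n_atoms x d_atom) of per-atom
#'   descriptors; padded rows must be all-zero.
#' @param adjacency binary symmetric bond adjacency with zero diagonal.
#' @param distances symmetric nonnegative interatomic distance matrix with
#'   zero diagonal (angstroms for conformer distances, bond hops for
#'   topological ones).
#' @param mask logical vector marking real (non-padding) atoms.
#' @param distance_source `"embed3d"` or `"topological"`.
#' @return object of class `molecule_graph`.
#' @export
molecule_graph <- function(atom_features, adjacency, distances, mask = NULL,
                           distance_source = "topological") {
  atom_features <- as.matrix(atom_features)
  adjacency <- as.matrix(adjacency)
  distances <- as.matrix(distances)
  n <- nrow(adjacency)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (nrow(atom_features) != n || ncol(adjacency) != n ||
      nrow(distances) != n || ncol(distances) != n || length(mask) != n) {
    stopf("molecule_graph: inconsistent dimensions")
  }
  if (!all(adjacency %in% c(0, 1))) stopf("adjacency must be binary")
  if (any(adjacency != t(adjacency))) stopf("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stopf("adjacency must have zero diagonal")
  if (any(distances < 0)) stopf("distances must be nonnegative")
  if (max(abs(distances - t(distances))) > 1e-8) stopf("distances must be symmetric")
  if (any(diag(distances) != 0)) stopf("distances must have zero diagonal")
  if (any(!mask)) {
    pad <- which(!mask)
    if (any(atom_features[pad, ] != 0) || any(adjacency[pad, ] != 0) ||
        any(adjacency[, pad] != 0)) {
      stopf("padded atoms must have zero features and zero adjacency")
    }
  }
  structure(list(atom_features = atom_features, adjacency = adjacency,
                 distances = distances, mask = as.logical(mask),
                 distance_source = distance_source),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d atoms (%d real), %d bonds, distances: %s\n",
              nrow(x$adjacency), sum(x$mask), sum(x$adjacency) / 2,
              x$distance_source))
  invisible(x)
}

# SDF charge field codes -> formal charges.
sdf_charge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

parse_smiles_sdf <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) {
    stopf("could not parse SMILES string: '%s'", smiles)
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0) stopf("could not parse SMILES string: '%s'", smiles)
  mol
}

# Attempt a 3D conformer through OpenBabel's distance-based embedding +
# forcefield cleanup; returns heavy-atom coordinates or NULL on failure.
conformer_coords <- function(smiles, n_heavy) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"),
                              options = data.frame(names = "gen3d", args = "")),
    error = function(e) NULL
  )
  if (is.null(txt) || !nzchar(txt)) return(NULL)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)), error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) return(NULL)
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  sym <- sub("_.*$", "", rownames(ab))
  heavy <- sym != "H"
  if (sum(heavy) != n_heavy) return(NULL)
  xyz <- ab[heavy, 1:3, drop = FALSE]
  if (all(xyz[, 3] == 0) && n_heavy > 3) return(NULL)  # embedding returned flat/degenerate coords
  xyz
}

#' Convert a SMILES string to an attributed molecular graph
#'
#' Parses the heavy-atom skeleton, builds the bond adjacency, per-atom
#' features (element one-hot over C/N/O/S/P/F/Cl/Br/I plus "other", degree
#' scaled by 1/4, ring-membership flag, formal charge), and an interatomic
#' distance matrix. With `distance = "embed3d"` a 3D conformer is generated
#' and Euclidean distances are used; if embedding fails (or with
#' `distance = "topological"`) shortest-path bond-hop distances are used and
#' the choice is recorded in `distance_source`. Conformer embedding is not
#' seedable and may differ between calls; topological distances are fully
#' deterministic. Molecules with more than `max_len` atoms are truncated to
#' the first `max_len` atoms.
#'
#' @param smiles a single SMILES string.
#' @param max_len maximum number of atoms kept (default 100).
#' @param distance `"topological"` (default) or `"embed3d"`.
#' @return a [molecule_graph()] (no padding; `mask` all `TRUE`).
#' @export
smiles_to_graph <- function(smiles, max_len = 100,
                            distance = c("topological", "embed3d")) {
  distance <- match.arg(distance)
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    stopf("could not parse SMILES string: empty input")
  }
  if (max_len < 1) stopf("max_len must be >= 1")
  mol <- parse_smiles_sdf(smiles)
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  sym <- sub("_.*$", "", rownames(ab))
  heavy <- which(sym != "H")
  n_all <- length(heavy)
  if (n_all == 0) stopf("could not parse SMILES string: '%s'", smiles)
  keep <- heavy[seq_len(min(n_all, max_len))]
  n <- length(keep)
  remap <- rep(NA_integer_, nrow(ab)); remap[keep] <- seq_len(n)

  adj <- matrix(0, n, n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      bi <- bb[r, 1]; bj <- bb[r, 2]
      if (bi < 1 || bj < 1 || bi > length(remap) || bj > length(remap)) next
      i <- remap[bi]; j <- remap[bj]
      if (!is.na(i) && !is.na(j) && i != j) { adj[i, j] <- 1; adj[j, i] <- 1 }
    }
  }

  # cyclic-environment flag: membership in the 2-core of the bond graph
  # (every ring atom is in the 2-core; bridge chains between rings also are,
  # which is acceptable for a coarse descriptor)
  in_ring <- rep(FALSE, n)
  if (n >= 3 && sum(adj) > 0) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    core <- igraph::coreness(g)
    in_ring <- core >= 2
  }

  charge_code <- if ("C5" %in% colnames(ab)) ab[keep, "C5"] else rep(0, n)
  degree <- rowSums(adj)
  elem <- sym[keep]
  one_hot <- matrix(0, n, length(ATOM_ELEMENTS) + 1,
                    dimnames = list(NULL, c(ATOM_ELEMENTS, "other")))
  for (i in seq_len(n)) {
    col <- match(elem[i], ATOM_ELEMENTS)
    one_hot[i, if (is.na(col)) ncol(one_hot) else col] <- 1
  }
  feats <- cbind(one_hot, degree = degree / 4,
                 in_ring = as.numeric(in_ring),
                 formal_charge = sdf_charge(charge_code))

  dist_source <- "topological"
  D <- NULL
  if (distance == "embed3d") {
    xyz <- conformer_coords(smiles, n_all)
    if (!is.null(xyz)) {
      xyz <- xyz[seq_len(n), , drop = FALSE]
      D <- as.matrix(stats::dist(xyz))
      dist_source <- "embed3d"
    }
  }
  if (is.null(D)) {
    if (n == 1) {
      D <- matrix(0, 1, 1)
    } else {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      D <- igraph::distances(g)
      D[!is.finite(D)] <- n  # disconnected fragments: beyond any real path
    }
  }
  dimnames(D) <- NULL
  diag(D) <- 0
  molecule_graph(feats, adj, D, mask = rep(TRUE, n), distance_source = dist_source)
}

#' Zero-pad a molecular graph to a fixed atom count
#'
#' Padding atoms get zero features, zero adjacency/distance rows and a
#' `FALSE` mask entry; encoders ignore them.
#' @param graph a [molecule_graph()].
#' @param n_total target atom count (>= current).
#' @export
pad_graph <- function(graph, n_total) {
  n <- nrow(graph$adjacency)
  if (n_total < n) stopf("cannot pad to fewer atoms than present")
  if (n_total == n) return(graph)
  grow <- function(m) {
    out <- matrix(0, n_total, ncol(m)); out[seq_len(n), ] <- m; out
  }
  grow_sq <- function(m) {
    out <- matrix(0, n_total, n_total); out[seq_len(n), seq_len(n)] <- m; out
  }
  molecule_graph(grow(graph$atom_features), grow_sq(graph$adjacency),
                 grow_sq(graph$distances),
                 mask = c(graph$mask, rep(FALSE, n_total - n)),
                 distance_source = graph$distance_source)
}
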