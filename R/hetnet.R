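# Heterogeneous network data model: four node types, six undirected binary
# edge types, meta-path adjacency construction, and edge splitting with
# negative sampling for link prediction.

#' Node and edge types of the heterogeneous network
#'
#' The network couples four entity types through six undirected, unweighted
#' association types: drug-protein (the prediction target), drug-drug,
#' protein-protein, drug-disease, protein-disease and drug-side_effect.
#'
#' @format `hetnet_node_types()` returns a character vector of the four node
#'   types; `hetnet_edge_types()` returns a named list mapping each canonical
#'   edge-type name to its `(row type, column type)` pair.
#' @export
hetnet_node_types <- function() c("drug", "protein", "disease", "side_effect")

#' @rdname hetnet_node_types
#' @export
hetnet_edge_types <- function() {
  list(
    drug_protein     = c("drug", "protein"),
    drug_drug        = c("drug", "drug"),
    protein_protein  = c("protein", "protein"),
    drug_disease     = c("drug", "disease"),
    protein_disease  = c("protein", "disease"),
    drug_side_effect = c("drug", "side_effect")
  )
}

# Resolve an unordered type pair to (canonical edge name, transposed?) or NULL.
resolve_edge_type <- function(t1, t2) {
  for (nm in names(hetnet_edge_types())) {
    pair <- hetnet_edge_types()[[nm]]
    if (t1 == pair[1] && t2 == pair[2]) return(list(name = nm, flip = FALSE))
    if (t1 == pair[2] && t2 == pair[1]) return(list(name = nm, flip = TRUE))
  }
  NULL
}

#' Construct and validate a heterogeneous network
#'
#' @param nodes named list of character vectors: node identifiers per type,
#'   one entry for each of [hetnet_node_types()]. Order fixes matrix indexing.
#' @param adjacency named list of binary matrices, one per edge type of
#'   [hetnet_edge_types()], with dimensions matching the node lists.
#' @return an object of class `hetero_network`.
#' @export
hetero_network <- function(nodes, adjacency) {
  types <- hetnet_node_types()
  for (tp in types) {
    if (is.null(nodes[[tp]])) nodes[[tp]] <- character(0)
    nodes[[tp]] <- as.character(nodes[[tp]])
    if (anyDuplicated(nodes[[tp]])) {
      stopf("duplicate %s node identifiers", tp)
    }
  }
  et <- hetnet_edge_types()
  for (nm in names(et)) {
    pair <- et[[nm]]
    dims <- c(length(nodes[[pair[1]]]), length(nodes[[pair[2]]]))
    if (is.null(adjacency[[nm]])) {
      adjacency[[nm]] <- matrix(0, dims[1], dims[2])
    }
    a <- as.matrix(adjacency[[nm]])
    storage.mode(a) <- "double"
    if (!identical(dim(a), as.integer(dims)) && !all(dim(a) == dims)) {
      stopf("adjacency '%s' has shape %dx%d, expected %dx%d",
            nm, nrow(a), ncol(a), dims[1], dims[2])
    }
    if (!all(a %in% c(0, 1))) stopf("adjacency '%s' has non-binary entries", nm)
    if (pair[1] == pair[2]) {
      if (!isTRUE(all.equal(a, t(a)))) stopf("within-type adjacency '%s' must be symmetric", nm)
      if (any(diag(a) != 0)) stopf("within-type adjacency '%s' must have zero diagonal", nm)
    }
    dimnames(a) <- list(nodes[[pair[1]]], nodes[[pair[2]]])
    adjacency[[nm]] <- a
  }
  structure(list(nodes = nodes[types], adjacency = adjacency[names(et)]),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network>\n")
  for (tp in names(x$nodes)) cat(sprintf("  %-12s %d nodes\n", tp, length(x$nodes[[tp]])))
  for (nm in names(x$adjacency)) {
    a <- x$adjacency[[nm]]
    pair <- hetnet_edge_types()[[nm]]
    n_edges <- if (pair[1] == pair[2]) sum(a) / 2 else sum(a)
    cat(sprintf("  %-18s %d edges\n", nm, n_edges))
  }
  invisible(x)
}

#' Build a heterogeneous network from node tables and an edge list
#'
#' Within-type edges are symmetrized (an edge given once yields both
#' orientations), self-loops are dropped, and duplicate edges collapse to 1.
#'
#' @param node_tables named list of character vectors of node ids per type.
#' @param edge_lists data frame with columns `src_type`, `src_id`, `dst_type`,
#'   `dst_id`, or a list of such data frames.
#' @return a [hetero_network()].
#' @export
build_network <- function(node_tables, edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edges <- do.call(rbind, lapply(edge_lists, function(e) {
    need <- c("src_type", "src_id", "dst_type", "dst_id")
    if (!all(need %in% names(e))) {
      stopf("edge list must have columns %s", paste(need, collapse = ", "))
    }
    e[need]
  }))
  net <- hetero_network(node_tables, list())
  adj <- net$adjacency
  if (!is.null(edges) && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      st <- as.character(edges$src_type[r]); dt <- as.character(edges$dst_type[r])
      si <- as.character(edges$src_id[r]);   di <- as.character(edges$dst_id[r])
      res <- resolve_edge_type(st, dt)
      if (is.null(res)) {
        stopf("edge (%s:%s, %s:%s): unsupported edge type pair %s-%s",
              st, si, dt, di, st, dt)
      }
      pair <- hetnet_edge_types()[[res$name]]
      if (res$flip) { tmp <- si; si <- di; di <- tmp }
      i <- match(si, net$nodes[[pair[1]]])
      j <- match(di, net$nodes[[pair[2]]])
      if (is.na(i)) stopf("edge (%s, %s): unknown %s id '%s'", si, di, pair[1], si)
      if (is.na(j)) stopf("edge (%s, %s): unknown %s id '%s'", si, di, pair[2], di)
      if (pair[1] == pair[2]) {
        if (i != j) { adj[[res$name]][i, j] <- 1; adj[[res$name]][j, i] <- 1 }
      } else {
        adj[[res$name]][i, j] <- 1
      }
    }
  }
  hetero_network(net$nodes, adj)
}

#' Extract the edge list of a network
#'
#' Inverse of [build_network()] up to edge ordering; within-type edges are
#' reported once with the lower index first.
#' @param network a [hetero_network()].
#' @return data frame with columns `src_type`, `src_id`, `dst_type`, `dst_id`.
#' @export
network_edges <- function(network) {
  out <- list()
  for (nm in names(network$adjacency)) {
    pair <- hetnet_edge_types()[[nm]]
    a <- network$adjacency[[nm]]
    if (pair[1] == pair[2]) a[lower.tri(a, diag = TRUE)] <- 0
    idx <- which(a == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    out[[nm]] <- data.frame(
      src_type = pair[1],
      src_id = network$nodes[[pair[1]]][idx[, 1]],
      dst_type = pair[2],
      dst_id = network$nodes[[pair[2]]][idx[, 2]],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(src_type = character(0), src_id = character(0),
                      dst_type = character(0), dst_id = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write an edge-list TSV
#'
#' TSV with header columns `src_type`, `src_id`, `dst_type`, `dst_id`, UTF-8.
#' @param path file path.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname read_edge_list
#' @param edges edge-list data frame, e.g. from [network_edges()].
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / load a network in the plain-matrix dialect
#'
#' One whitespace-delimited 0/1 matrix file per edge type
#' (`mat_<edge_type>.txt`) plus one newline-delimited node-id file per node
#' type (`node_<type>.txt`). Matrix rows follow the node-id file order.
#'
#' @param network a [hetero_network()].
#' @param directory directory to write to / read from.
#' @return `load_dtinet_matrices` returns a [hetero_network()];
#'   `write_dtinet_matrices` returns the directory invisibly.
#' @export
write_dtinet_matrices <- function(network, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(network$nodes)) {
    writeLines(network$nodes[[tp]], file.path(directory, paste0("node_", tp, ".txt")))
  }
  for (nm in names(network$adjacency)) {
    a <- network$adjacency[[nm]]
    lines <- apply(a, 1L, function(row) paste(as.integer(row), collapse = " "))
    if (nrow(a) == 0) lines <- character(0)
    writeLines(lines, file.path(directory, paste0("mat_", nm, ".txt")))
  }
  invisible(directory)
}

#' @rdname write_dtinet_matrices
#' @export
load_dtinet_matrices <- function(directory) {
  nodes <- list()
  for (tp in hetnet_node_types()) {
    f <- file.path(directory, paste0("node_", tp, ".txt"))
    nodes[[tp]] <- if (file.exists(f)) readLines(f) else character(0)
  }
  adj <- list()
  for (nm in names(hetnet_edge_types())) {
    pair <- hetnet_edge_types()[[nm]]
    f <- file.path(directory, paste0("mat_", nm, ".txt"))
    dims <- c(length(nodes[[pair[1]]]), length(nodes[[pair[2]]]))
    if (!file.exists(f)) next
    lines <- readLines(f)
    vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(vals) != dims[1]) {
      stopf("matrix '%s' has %d rows, expected %d", nm, length(vals), dims[1])
    }
    a <- if (dims[1] == 0) matrix(0, 0, dims[2]) else do.call(rbind, vals)
    if (dims[1] > 0 && ncol(a) != dims[2]) {
      stopf("matrix '%s' has %d columns, expected %d", nm, ncol(a), dims[2])
    }
    if (!all(a %in% c(0, 1))) stopf("matrix '%s' has non-binary entries", nm)
    adj[[nm]] <- a
    message(sprintf("loaded %s: %d x %d, %d ones", nm, dims[1], dims[2], sum(a)))
  }
  hetero_network(nodes, adj)
}

#' Define a meta-path
#'
#' A meta-path is an ordered chain of node types; every consecutive pair must
#' correspond to one of the six supported edge types. The two default paths of
#' the model are drug-protein-drug (`metapath_dpd()`) and
#' protein-disease-protein-drug (`metapath_pdpd()`).
#'
#' @param name label for reporting.
#' @param node_type_chain character vector of node types, length >= 3.
#' @export
metapath_spec <- function(name, node_type_chain) {
  if (length(node_type_chain) < 3) stopf("meta-path chain must have length >= 3")
  if (!all(node_type_chain %in% hetnet_node_types())) {
    stopf("unknown node type in chain: %s",
          paste(setdiff(node_type_chain, hetnet_node_types()), collapse = ", "))
  }
  for (i in seq_len(length(node_type_chain) - 1)) {
    if (is.null(resolve_edge_type(node_type_chain[i], node_type_chain[i + 1]))) {
      stopf("no supported edge type between '%s' and '%s'",
            node_type_chain[i], node_type_chain[i + 1])
    }
  }
  structure(list(name = name, chain = node_type_chain), class = "metapath_spec")
}

#' @rdname metapath_spec
#' @export
metapath_dpd <- function() metapath_spec("D-P-D", c("drug", "protein", "drug"))

#' @rdname metapath_spec
#' @export
metapath_pdpd <- function() {
  metapath_spec("P-Dis-P-D", c("protein", "disease", "protein", "drug"))
}

#' Meta-path neighbor structure
#'
#' Computes the (start type x end type) neighbor matrix of a meta-path:
#' entry (u, v) is 1 iff at least one path instance follows the type chain
#' from u to v. When start and end types coincide the diagonal is forced to
#' zero: a node is never its own meta-path neighbor, since self-information
#' enters the model through its free embedding. Path counts are discarded by
#' default; set `count_paths = TRUE` to keep multiplicities (diagonal still
#' zeroed).
#'
#' @param network a [hetero_network()].
#' @param spec a [metapath_spec()].
#' @param count_paths keep path counts instead of binarizing.
#' @return numeric matrix over (start type x end type) node sets.
#' @export
metapath_adjacency <- function(network, spec, count_paths = FALSE) {
  stopifnot(inherits(spec, "metapath_spec"))
  chain <- spec$chain
  step_matrix <- function(t1, t2) {
    res <- resolve_edge_type(t1, t2)
    if (is.null(res)) stopf("no supported edge type between '%s' and '%s'", t1, t2)
    a <- network$adjacency[[res$name]]
    if (res$flip) t(a) else a
  }
  m <- step_matrix(chain[1], chain[2])
  for (i in seq(2, length(chain) - 1)) {
    m <- m %*% step_matrix(chain[i], chain[i + 1])
  }
  if (chain[1] == chain[length(chain)]) diag(m) <- 0
  if (!count_paths) m <- (m > 0) + 0
  dimnames(m) <- list(network$nodes[[chain[1]]], network$nodes[[chain[length(chain)]]])
  m
}

#' Split drug-protein edges into train/test with negative sampling
#'
#' Positive (observed) drug-protein pairs are partitioned into
#' `k = round(1 / test_fraction)` folds; fold `fold_id` is held out. Negative
#' pairs are sampled uniformly without replacement from unobserved (zero)
#' entries at `neg_ratio` negatives per positive, once per seed, and
#' partitioned into the same folds, so both train and test keep the configured
#' class ratio. The fold assignment depends only on `seed`, so the k splits of
#' one seed partition the positive set exactly once.
#'
#' @param network a [hetero_network()].
#' @param test_fraction held-out fraction, in (0, 1); default 0.1.
#' @param neg_ratio negatives sampled per positive; default 10.
#' @param fold_id which fold (1..k) to hold out.
#' @param seed RNG seed controlling both the fold partition and the negatives.
#' @return object of class `edge_split` with two-column index matrices
#'   `train_positive`, `test_positive`, `train_negative`, `test_negative`
#'   (drug index, protein index; 1-based).
#' @export
split_edges <- function(network, test_fraction = 0.1, neg_ratio = 10,
                        fold_id = 1, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1)) stopf("test_fraction must be in (0,1)")
  if (neg_ratio <= 0) stopf("neg_ratio must be positive")
  a <- network$adjacency$drug_protein
  pos <- which(a == 1, arr.ind = TRUE)
  if (nrow(pos) == 0) stopf("drug-protein adjacency has no positive edges")
  k <- max(2L, as.integer(round(1 / test_fraction)))
  if (fold_id < 1 || fold_id > k) stopf("fold_id must be in 1..%d", k)
  n_pos <- nrow(pos)
  n_neg <- round(neg_ratio * n_pos)
  zeros <- which(a == 0, arr.ind = TRUE)
  if (n_neg > nrow(zeros)) {
    stopf("requested %d negatives but only %d zero entries available", n_neg, nrow(zeros))
  }
  with_seed(derive_seed(seed, "split"), {
    pos_fold <- rep_len(seq_len(k), n_pos)[sample.int(n_pos)]
    neg_idx <- sample.int(nrow(zeros), n_neg)
    neg <- zeros[neg_idx, , drop = FALSE]
    neg_fold <- rep_len(seq_len(k), n_neg)[sample.int(n_neg)]
    structure(list(
      train_positive = unname(pos[pos_fold != fold_id, , drop = FALSE]),
      test_positive  = unname(pos[pos_fold == fold_id, , drop = FALSE]),
      train_negative = unname(neg[neg_fold != fold_id, , drop = FALSE]),
      test_negative  = unname(neg[neg_fold == fold_id, , drop = FALSE]),
      fold_id = as.integer(fold_id), k = k,
      neg_ratio = neg_ratio, seed = seed
    ), class = "edge_split")
  })
}

#' Remove held-out positives from the message-passing graph
#'
#' Returns a copy of the network whose drug-protein adjacency contains only
#' training positives, so test edges are invisible to meta-path construction
#' and reconstruction targets.
#' @param network a [hetero_network()].
#' @param split an [split_edges()] result.
#' @export
mask_test_edges <- function(network, split) {
  a <- network$adjacency$drug_protein
  a[split$test_positive] <- 0
  network$adjacency$drug_protein <- a
  network
}

#' Write / read a split manifest (JSON)
#'
#' Records fold id, seed, ratio, and the four index-pair lists. Indices are
#' written 1-based (`index_base` field says so explicitly).
#' @param split an `edge_split`.
#' @param path JSON path.
#' @export
write_split_manifest <- function(split, path) {
  obj <- list(
    fold_id = split$fold_id, k = split$k, neg_ratio = split$neg_ratio,
    seed = split$seed, index_base = 1L,
    train_positive = unname(apply(split$train_positive, 1L, as.list)),
    test_positive  = unname(apply(split$test_positive, 1L, as.list)),
    train_negative = unname(apply(split$train_negative, 1L, as.list)),
    test_negative  = unname(apply(split$test_negative, 1L, as.list))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pairs <- function(x) {
    if (length(x) == 0) return(matrix(integer(0), 0, 2))
    m <- if (is.matrix(x)) x
         else if (is.data.frame(x)) as.matrix(x)
         else do.call(rbind, lapply(x, unlist))
    storage.mode(m) <- "integer"
    unname(m)
  }
  structure(list(
    train_positive = as_pairs(obj$train_positive),
    test_positive  = as_pairs(obj$test_positive),
    train_negative = as_pairs(obj$train_negative),
    test_negative  = as_pairs(obj$test_negative),
    fold_id = obj$fold_id, k = obj$k,
    neg_ratio = obj$neg_ratio, seed = obj$seed
  ), class = "edge_split")
}
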