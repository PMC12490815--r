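# Heterogeneous network construction, I/O, meta-path adjacency, and edge
# splitting.

test_that("build_network constructs, symmetrizes, and validates", {
  net <- tiny_network()
  expect_equal(unname(net$adjacency$drug_protein), matrix(c(1, 0), 2, 1))
  expect_equal(net$adjacency$drug_drug[1, 2], 1)
  expect_equal(net$adjacency$drug_drug[2, 1], 1)
  expect_equal(diag(net$adjacency$drug_drug), c(d1 = 0, d2 = 0))

  expect_error(
    build_network(list(drug = "d1", protein = "p1"),
                  data.frame(src_type = "drug", src_id = "d1",
                             dst_type = "side_effect", dst_id = "s_unknown")),
    "unknown side_effect id")
  expect_error(
    build_network(list(protein = "p1", side_effect = "s1"),
                  data.frame(src_type = "protein", src_id = "p1",
                             dst_type = "side_effect", dst_id = "s1")),
    "unsupported edge type")
  expect_error(
    hetero_network(list(drug = c("d1", "d1"), protein = "p1"), list()),
    "duplicate")
})

test_that("build_network is idempotent through its edge list", {
  for (seed in 1:5) {
    net <- random_network(n_per_type = 6, seed = seed)
    rebuilt <- build_network(net$nodes, network_edges(net))
    expect_equal(rebuilt$adjacency, net$adjacency)
  }
})

test_that("matrix-dialect round trip reproduces the network exactly", {
  dir <- withr::local_tempdir()
  net <- random_network(n_per_type = 7, seed = 3)
  write_dtinet_matrices(net, dir)
  loaded <- suppressMessages(load_dtinet_matrices(dir))
  expect_equal(loaded$adjacency, net$adjacency)
  expect_equal(loaded$nodes, net$nodes)

  # one DTI from a 2x1 matrix file
  dir2 <- withr::local_tempdir()
  writeLines(c("d1", "d2"), file.path(dir2, "node_drug.txt"))
  writeLines("p1", file.path(dir2, "node_protein.txt"))
  writeLines(c("1", "0"), file.path(dir2, "mat_drug_protein.txt"))
  net2 <- suppressMessages(load_dtinet_matrices(dir2))
  expect_equal(unname(net2$adjacency$drug_protein), matrix(c(1, 0), 2, 1))

  # non-binary entry rejected
  writeLines(c("2", "0"), file.path(dir2, "mat_drug_protein.txt"))
  expect_error(suppressMessages(load_dtinet_matrices(dir2)), "non-binary")
  # shape mismatch rejected
  writeLines("1", file.path(dir2, "mat_drug_protein.txt"))
  expect_error(suppressMessages(load_dtinet_matrices(dir2)), "rows")
})

test_that("edge-list TSV round trips", {
  net <- random_network(n_per_type = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(network_edges(net), path)
  rebuilt <- build_network(net$nodes, read_edge_list(path))
  expect_equal(rebuilt$adjacency, net$adjacency)
})

test_that("metapath specs validate their type chains", {
  expect_error(metapath_spec("x", c("drug", "protein")), "length >= 3")
  expect_error(metapath_spec("x", c("drug", "gene", "drug")), "unknown node type")
  expect_error(metapath_spec("x", c("protein", "side_effect", "protein")),
               "no supported edge type")
  expect_equal(metapath_dpd()$chain, c("drug", "protein", "drug"))
  expect_equal(metapath_pdpd()$chain, c("protein", "disease", "protein", "drug"))
})

test_that("meta-path adjacency: shared-target neighbors, zero diagonal", {
  net <- build_network(
    list(drug = c("d1", "d2"), protein = "p1", disease = "dis1"),
    data.frame(src_type = "drug", src_id = c("d1", "d2"),
               dst_type = "protein", dst_id = c("p1", "p1")))
  m <- metapath_adjacency(net, metapath_dpd())
  expect_equal(m["d1", "d2"], 1)
  expect_equal(m["d2", "d1"], 1)
  expect_equal(diag(m), c(d1 = 0, d2 = 0))
  expect_equal(m, t(m))

  # no drug-protein edges: all-zero result
  net0 <- build_network(list(drug = c("d1", "d2"), protein = "p1"),
                        data.frame(src_type = character(0), src_id = character(0),
                                   dst_type = character(0), dst_id = character(0)))
  expect_true(all(metapath_adjacency(net0, metapath_dpd()) == 0))
})

test_that("protein-disease-protein-drug path connects through shared disease", {
  net <- build_network(
    list(drug = "d1", protein = c("p1", "p2"), disease = "dis1"),
    data.frame(src_type = c("protein", "protein", "drug"),
               src_id = c("p1", "p2", "d1"),
               dst_type = c("disease", "disease", "protein"),
               dst_id = c("dis1", "dis1", "p2")))
  m <- metapath_adjacency(net, metapath_pdpd())
  expect_equal(m["p1", "d1"], 1)
  # independent oracle: boolean product A_pd . A_pd^T . A_dp with no
  # self-hop restriction beyond the start/end-type diagonal rule
  a_pdis <- net$adjacency$protein_disease
  a_dp <- net$adjacency$drug_protein
  oracle <- ((a_pdis %*% t(a_pdis)) %*% t(a_dp) > 0) + 0
  expect_equal(unname(m), unname(oracle))
})

# exhaustive path enumeration oracle following the type chain
enumerate_paths <- function(network, chain) {
  step <- function(t1, t2) {
    res <- hetdti:::resolve_edge_type(t1, t2)
    a <- network$adjacency[[res$name]]
    if (res$flip) t(a) else a
  }
  n_start <- length(network$nodes[[chain[1]]])
  n_end <- length(network$nodes[[chain[length(chain)]]])
  out <- matrix(0, n_start, n_end)
  walk <- function(pos, node) {
    if (pos == length(chain)) return(node)
    a <- step(chain[pos], chain[pos + 1])
    unlist(lapply(which(a[node, ] == 1), function(nb) walk(pos + 1, nb)))
  }
  for (u in seq_len(n_start)) {
    ends <- walk(1, u)
    if (length(ends) > 0) out[u, unique(ends)] <- 1
  }
  if (chain[1] == chain[length(chain)]) diag(out) <- 0
  out
}

test_that("meta-path adjacency equals exhaustive path enumeration", {
  for (seed in 1:6) {
    net <- random_network(n_per_type = sample(3:8, 1), p_edge = 0.35, seed = seed)
    for (spec in list(metapath_dpd(), metapath_pdpd(),
                      metapath_spec("D-Dis-D", c("drug", "disease", "drug")),
                      metapath_spec("P-D-P", c("protein", "drug", "protein")))) {
      expect_equal(unname(metapath_adjacency(net, spec)),
                   enumerate_paths(net, spec$chain),
                   info = sprintf("seed %d path %s", seed, spec$name))
    }
  }
})

test_that("split_edges partitions positives 90/10 and is deterministic", {
  set.seed(2)
  a <- matrix(0, 10, 10)
  a[cbind(sample(1:10), sample(1:10))] <- 1  # 10 positives
  net <- hetero_network(list(drug = paste0("d", 1:10), protein = paste0("p", 1:10)),
                        list(drug_protein = a))
  s <- split_edges(net, test_fraction = 0.1, neg_ratio = 2, fold_id = 1, seed = 7)
  expect_equal(nrow(s$train_positive), 9)
  expect_equal(nrow(s$test_positive), 1)
  expect_equal(nrow(s$train_negative) + nrow(s$test_negative), 20)

  s2 <- split_edges(net, test_fraction = 0.1, neg_ratio = 2, fold_id = 1, seed = 7)
  expect_identical(s, s2)

  # negatives and positives never overlap; all negatives are zero entries
  expect_true(all(a[s$train_negative] == 0))
  expect_true(all(a[s$test_negative] == 0))

  # folds partition the positive set exactly once
  seen <- matrix(0, 10, 10)
  for (f in 1:10) {
    sf <- split_edges(net, test_fraction = 0.1, neg_ratio = 2, fold_id = f, seed = 7)
    seen[sf$test_positive] <- seen[sf$test_positive] + 1
  }
  expect_equal(seen, a)

  # masking removes exactly the held-out positives from message passing
  masked <- mask_test_edges(net, s)
  expect_equal(sum(masked$adjacency$drug_protein), 9)
  expect_true(all(masked$adjacency$drug_protein[s$train_positive] == 1))
})

test_that("split_edges errors when negatives cannot be sampled", {
  net <- hetero_network(list(drug = "d1", protein = "p1"),
                        list(drug_protein = matrix(1, 1, 1)))
  expect_error(split_edges(net, test_fraction = 0.5, neg_ratio = 1, seed = 1),
               "zero entries")
})

test_that("split manifest JSON round trips", {
  net <- random_network(n_per_type = 6, p_edge = 0.2, seed = 4)
  s <- split_edges(net, test_fraction = 0.25, neg_ratio = 1, fold_id = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(s, path)
  s2 <- read_split_manifest(path)
  for (field in c("train_positive", "test_positive", "train_negative",
                  "test_negative")) {
    expect_equal(unname(s2[[field]]), unname(s[[field]]), info = field,
                 ignore_attr = TRUE)
  }
  expect_equal(s2$fold_id, s$fold_id)
  expect_equal(s2$neg_ratio, s$neg_ratio)
})
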