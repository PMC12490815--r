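# Shared fixtures built in code: tiny networks and bundles for unit tests.

tiny_network <- function() {
  build_network(
    node_tables = list(drug = c("d1", "d2"), protein = "p1",
                       disease = "dis1", side_effect = "s1"),
    edge_lists = data.frame(
      src_type = c("drug", "drug", "protein"),
      src_id = c("d1", "d1", "p1"),
      dst_type = c("protein", "drug", "disease"),
      dst_id = c("p1", "d2", "dis1")
    )
  )
}

# Random heterogeneous network with all six edge types, <= n nodes per type.
random_network <- function(n_per_type = 5, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- list(drug = paste0("d", 1:n_per_type),
                protein = paste0("p", 1:n_per_type),
                disease = paste0("x", 1:n_per_type),
                side_effect = paste0("s", 1:n_per_type))
  adj <- list()
  for (nm in names(hetnet_edge_types())) {
    pair <- hetnet_edge_types()[[nm]]
    a <- matrix(rbinom(n_per_type^2, 1, p_edge), n_per_type, n_per_type)
    if (pair[1] == pair[2]) {
      a[lower.tri(a, diag = TRUE)] <- 0
      a <- a + t(a)
    }
    adj[[nm]] <- a
  }
  hetero_network(nodes, adj)
}

small_bundle <- function(seed = 5) {
  simulate_bundle(synthetic_spec(
    n_drug = 15, n_protein = 20, n_disease = 6, n_side_effect = 6,
    latent_rank = 2,
    densities = list(drug_protein = 0.1, drug_drug = 0.12, protein_protein = 0.12,
                     drug_disease = 0.12, protein_disease = 0.12,
                     drug_side_effect = 0.12),
    feature_coupling = 0.8, seed = seed))
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(steps = 5, batch_size = 32, han_input_size = 12, han_heads = 1,
         mat_heads = 2, mat_stack = 1, neg_per_pos = 5, seed = 5),
    list(...))
  do.call(train_config, args)
}
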