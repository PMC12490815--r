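# Training loop: analytic gradients vs finite differences, reproducibility,
# loss improvement, evaluation, and cross-validation plumbing.

make_training_fixture <- function(seed = 3, d = 5, K = 2) {
  spec <- synthetic_spec(
    n_drug = 8, n_protein = 9, n_disease = 4, n_side_effect = 4,
    latent_rank = 2,
    densities = list(drug_protein = 0.25, drug_drug = 0.25,
                     protein_protein = 0.25, drug_disease = 0.25,
                     protein_disease = 0.25, drug_side_effect = 0.25),
    seed = seed)
  b <- simulate_bundle(spec)
  split <- split_edges(b$network, test_fraction = 0.25, neg_ratio = 2, seed = seed)
  cfg <- train_config(steps = 1, batch_size = 16, han_input_size = d,
                      han_heads = K, mat_heads = 1, mat_stack = 1,
                      dropout = 0, seed = seed)
  feats <- prepare_features(b$smiles, b$sequences, cfg)
  masked <- mask_test_edges(b$network, split)
  ctx <- list(nb_dpd = metapath_adjacency(masked, metapath_dpd()),
              nb_pdpd = metapath_adjacency(masked, metapath_pdpd()),
              A_dd = b$network$adjacency$drug_drug,
              A_pp = b$network$adjacency$protein_protein,
              S_drug = feats$S_drug, S_protein = feats$S_protein,
              lambda1 = 0.7, lambda2 = 1.3)
  pool <- rbind(split$train_positive, split$train_negative)
  y <- c(rep(1, nrow(split$train_positive)), rep(0, nrow(split$train_negative)))
  list(bundle = b, split = split, cfg = cfg, ctx = ctx,
       batch = list(i = pool[, 1], j = pool[, 2], y = y))
}

test_that("analytic gradients match finite differences", {
  fx <- make_training_fixture()
  # D-P-D neighbors must exist so the within-type attention path is exercised
  expect_gt(sum(fx$ctx$nb_dpd), 0)
  expect_gt(sum(fx$ctx$nb_pdpd), 0)
  state <- hetdti:::init_model_state(8, 9, fx$cfg)
  set.seed(99)
  rec_entries <- list(
    dd = rbind(which(fx$ctx$A_dd == 1, arr.ind = TRUE),
               which(fx$ctx$A_dd == 0, arr.ind = TRUE)[sample(20, 6), ]),
    pp = rbind(which(fx$ctx$A_pp == 1, arr.ind = TRUE),
               which(fx$ctx$A_pp == 0, arr.ind = TRUE)[sample(20, 6), ]))
  for (re in list(NULL, rec_entries)) {
    fw <- hetdti:::model_forward(state, fx$ctx, fx$batch, rec_entries = re)
    g <- hetdti:::flatten_grads(
      hetdti:::model_backward(state, fx$ctx, fw, fx$batch), state)
    flat <- hetdti:::collect_params(state)
    loss_at <- function(flat) {
      st <- hetdti:::assign_params(state, flat)
      hetdti:::model_forward(st, fx$ctx, fx$batch, rec_entries = re)$total
    }
    eps <- 1e-6
    for (nm in names(flat)) {
      idx <- seq_along(flat[[nm]])
      if (length(idx) > 12) {
        set.seed(1)
        idx <- sample(idx, 12)
      }
      for (ii in idx) {
        f2 <- flat
        f2[[nm]][ii] <- f2[[nm]][ii] + eps
        lp <- loss_at(f2)
        f2[[nm]][ii] <- f2[[nm]][ii] - 2 * eps
        lm <- loss_at(f2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][ii], num, tolerance = 1e-3,
                     info = sprintf("%s[%d] rec=%s", nm, ii, !is.null(re)))
      }
    }
  }
})

test_that("a 2-step run completes with a 2-entry trace", {
  b <- small_bundle()
  split <- split_edges(b$network, neg_ratio = 5, seed = 5)
  m <- train_model(b$network, b$smiles, b$sequences, split,
                   small_config(steps = 2))
  expect_length(m$trace, 2)
  expect_true(all(is.finite(m$trace)))
})

test_that("identical config and seed give bitwise-identical runs", {
  b <- small_bundle()
  split <- split_edges(b$network, neg_ratio = 5, seed = 5)
  cfg <- small_config(steps = 8, deterministic = TRUE)
  m1 <- train_model(b$network, b$smiles, b$sequences, split, cfg)
  m2 <- train_model(b$network, b$smiles, b$sequences, split, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$f_drug, m2$f_drug)
  expect_identical(m1$f_protein, m2$f_protein)
  m3 <- train_model(b$network, b$smiles, b$sequences, split,
                    small_config(steps = 8, deterministic = TRUE, seed = 6))
  expect_false(identical(m1$trace, m3$trace))
})

test_that("training reduces the loss on a coupled bundle", {
  spec <- synthetic_spec(n_drug = 30, n_protein = 40, n_disease = 10,
                         n_side_effect = 10, latent_rank = 3,
                         densities = list(drug_protein = 0.08),
                         feature_coupling = 0.8, seed = 17)
  b <- simulate_bundle(spec)
  split <- split_edges(b$network, neg_ratio = 10, seed = 17)
  cfg <- train_config(steps = 150, batch_size = 64, han_input_size = 24,
                      mat_heads = 2, mat_stack = 1, seed = 17)
  m <- train_model(b$network, b$smiles, b$sequences, split, cfg)
  expect_lt(tail(m$trace, 1), m$trace[1])
})

test_that("one optimizer step decreases the deterministic toy objective", {
  # 2 drugs x 2 proteins, one positive edge; full-batch, dense
  # reconstruction, no dropout: the objective is deterministic in the
  # parameters, so a small Adam step must strictly decrease it
  nodes <- list(drug = c("d1", "d2"), protein = c("p1", "p2"),
                disease = "x1", side_effect = "s1")
  adj <- list(drug_protein = matrix(c(1, 0, 1, 0), 2, 2),
              drug_drug = matrix(c(0, 1, 1, 0), 2, 2),
              protein_protein = matrix(c(0, 1, 1, 0), 2, 2))
  net <- hetero_network(nodes, adj)
  smiles <- c(d1 = "CCO", d2 = "CCC")
  seqs <- c(p1 = "MKVLAW", p2 = "TREDWA")
  for (seed in 1:20) {
    split <- split_edges(net, test_fraction = 0.5, neg_ratio = 1, seed = seed)
    cfg <- train_config(steps = 2, batch_size = 16, han_input_size = 6,
                        mat_heads = 1, mat_stack = 1, dropout = 0,
                        learning_rate = 1e-3, balanced_batches = FALSE,
                        seed = seed)
    m <- train_model(net, smiles, seqs, split, cfg)
    expect_lt(m$trace[2], m$trace[1])
  }
})

test_that("feature ablation flags zero out the corresponding view", {
  b <- small_bundle()
  split <- split_edges(b$network, neg_ratio = 5, seed = 5)
  m_full <- train_model(b$network, b$smiles, b$sequences, split,
                        small_config(steps = 3))
  m_abl <- train_model(b$network, b$smiles, b$sequences, split,
                       small_config(steps = 3, use_ProSF = FALSE,
                                    use_DruSF = FALSE))
  expect_null(m_abl$state$W_ad)
  expect_null(m_abl$state$W_ap)
  expect_false(identical(m_full$f_drug, m_abl$f_drug))
})

test_that("training validates id alignment", {
  b <- small_bundle()
  split <- split_edges(b$network, neg_ratio = 5, seed = 5)
  bad_smiles <- b$smiles
  names(bad_smiles)[1] <- "not_a_drug"
  expect_error(train_model(b$network, bad_smiles, b$sequences, split,
                           small_config()), "drug ids")
  bad_seq <- b$sequences[-1]
  expect_error(train_model(b$network, b$smiles, bad_seq, split,
                           small_config()), "protein ids")
})

test_that("evaluation flags single-class test sets", {
  b <- small_bundle()
  split <- split_edges(b$network, neg_ratio = 5, seed = 5)
  m <- train_model(b$network, b$smiles, b$sequences, split, small_config(steps = 2))
  empty_split <- split
  empty_split$test_negative <- split$test_negative[0, , drop = FALSE]
  expect_error(evaluate_model(m, empty_split), "single class")
})

test_that("cross-validation produces one metric row per fold and their mean", {
  b <- small_bundle()
  cv <- cross_validate(b$network, b$smiles, b$sequences, k = 2,
                       config = small_config(steps = 4))
  expect_equal(nrow(cv$folds), 2)
  expect_equal(unname(cv$mean["auroc"]), mean(cv$folds$auroc))
  expect_equal(unname(cv$mean["aupr"]), mean(cv$folds$aupr))

  # fold test sets are disjoint and cover all positives
  s1 <- split_edges(b$network, test_fraction = 0.5, neg_ratio = 5, fold_id = 1,
                    seed = 5)
  s2 <- split_edges(b$network, test_fraction = 0.5, neg_ratio = 5, fold_id = 2,
                    seed = 5)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(key(s1$test_positive), key(s2$test_positive)), 0)
  expect_setequal(c(key(s1$test_positive), key(s2$test_positive)),
                  key(which(b$network$adjacency$drug_protein == 1, arr.ind = TRUE)))
})
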