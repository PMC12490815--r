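# End-to-end training of the multiview link predictor. Trainable parameters:
# free node embeddings E_drug / E_protein (shared with the relational view's
# initial embeddings f0), per-meta-path attention parameters (W, a per head),
# and the fusion head (W0, b0). The drug and protein feature views act as
# fixed seeded featurizers whose outputs enter the fusion; gradients flow
# through the relational view and the fusion head, with analytic backprop
# verified against finite differences in the test suite.

#' Training configuration
#'
#' Defaults follow the reference hyperparameter table: 3000 optimizer steps,
#' batch size 128, Adam learning rate 0.001, dropout 0.1, relational-view
#' input size 1024, 16 molecular attention heads, stack depth 8, and 10
#' sampled negatives per positive. `use_ProSF` / `use_DruSF` switch the
#' protein-sequence and drug-structure feature views (ablations replace the
#' corresponding feature block with zeros).
#'
#' @param steps optimizer steps.
#' @param batch_size minibatch size for the cross-entropy term.
#' @param learning_rate Adam step size.
#' @param dropout dropout rate on the concatenated fusion input.
#' @param han_input_size embedding width d of the relational view (and of
#'   both feature-view outputs).
#' @param han_heads attention heads K of the node-level attention.
#' @param mat_heads,mat_stack molecular encoder heads / stack depth.
#' @param neg_per_pos negatives sampled per positive when splitting edges.
#' @param lambda1,lambda2 reconstruction loss weights.
#' @param balanced_batches stratify each minibatch to contain (up to) equal
#'   numbers of positive and negative training pairs. The data keep their
#'   configured class imbalance; only the per-step batch composition changes.
#'   Without stratification the heavily imbalanced cross-entropy applies a
#'   near-uniform repulsive pressure that can drive every ReLU unit of the
#'   fusion head negative (an absorbing all-zero state); default `TRUE`.
#' @param use_ProSF,use_DruSF feature-view ablation switches.
#' @param deterministic forces topological interatomic distances (conformer
#'   embedding is the only non-seedable code path).
#' @param distance_mode `"topological"` or `"embed3d"` for drug graphs.
#' @param seed master seed; every random draw in training derives from it.
#' @export
train_config <- function(steps = 3000, batch_size = 128, learning_rate = 0.001,
                         dropout = 0.1, han_input_size = 1024, han_heads = 1,
                         mat_heads = 16, mat_stack = 8, neg_per_pos = 10,
                         lambda1 = 1, lambda2 = 1, use_ProSF = TRUE,
                         use_DruSF = TRUE, deterministic = FALSE,
                         distance_mode = "topological", max_len = 100,
                         kmer_buckets = 512, threshold = 0.5, balanced_batches = TRUE,
                 seed = 1) {
  stopifnot(steps >= 1, batch_size >= 1, learning_rate > 0, dropout >= 0,
            dropout < 1, han_input_size >= 1, han_heads >= 1, neg_per_pos > 0,
            lambda1 >= 0, lambda2 >= 0)
  if (deterministic) distance_mode <- "topological"
  structure(list(steps = steps, batch_size = batch_size,
                 learning_rate = learning_rate, dropout = dropout,
                 han_input_size = han_input_size, han_heads = han_heads,
                 mat_heads = mat_heads, mat_stack = mat_stack,
                 neg_per_pos = neg_per_pos, lambda1 = lambda1,
                 lambda2 = lambda2, use_ProSF = use_ProSF,
                 use_DruSF = use_DruSF, deterministic = deterministic,
                 distance_mode = distance_mode, max_len = max_len,
                 kmer_buckets = kmer_buckets, threshold = threshold,
                 balanced_batches = balanced_batches, seed = seed),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' Fields present in the file override [train_config()] defaults.
#' @param path YAML file path.
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(train_config, vals)
}

#' Compute the fixed feature views of a bundle
#'
#' Parses and encodes all drugs and proteins once so the (deterministic,
#' seeded) feature matrices can be reused across folds and seeds.
#' @param smiles named character vector of SMILES by drug id.
#' @param sequences named character vector (or `protein_sequence` list) by
#'   protein id.
#' @param config a [train_config()].
#' @return list with `S_drug` and `S_protein` matrices (NULL for a view that
#'   is switched off).
#' @export
prepare_features <- function(smiles, sequences, config = train_config()) {
  d <- config$han_input_size
  S_drug <- if (config$use_DruSF) {
    mp <- mat_params(d_atom = length(ATOM_ELEMENTS) + 4, d_model = d,
                     n_heads = config$mat_heads, n_layers = config$mat_stack,
                     seed = derive_seed(config$seed, "mat-params"))
    encode_drug_table(smiles, mp, max_len = config$max_len,
                      distance = config$distance_mode)
  } else NULL
  S_protein <- if (config$use_ProSF) {
    enc <- kmer_encoder(d_h = d, n_buckets = config$kmer_buckets,
                        seed = derive_seed(config$seed, "kmer-params"))
    encode_protein_table(sequences, enc)
  } else NULL
  # column-center, then row-normalize: pooled encoder outputs carry a large
  # component shared by every entity; removing it exposes the discriminative
  # part, which the trainable per-view adapter then reorients
  standardize <- function(S) {
    if (is.null(S)) return(NULL)
    l2_normalize_rows(scale(S, center = TRUE, scale = FALSE))
  }
  list(S_drug = standardize(S_drug), S_protein = standardize(S_protein))
}

init_model_state <- function(n_drug, n_protein, config) {
  d <- config$han_input_size
  s <- config$seed
  dpd <- attention_params(d, d, K = config$han_heads,
                          seed = derive_seed(s, "att-dpd"))
  pdpd <- attention_params(d, d, K = config$han_heads,
                           seed = derive_seed(s, "att-pdpd"))
  fus <- fusion_params(d, d, d_out = d, lambda1 = config$lambda1,
                       lambda2 = config$lambda2, seed = derive_seed(s, "fus"))
  with_seed(derive_seed(s, "embeddings"), {
    list(E_d = matrix(stats::rnorm(n_drug * d, sd = 0.1), n_drug, d),
         E_p = matrix(stats::rnorm(n_protein * d, sd = 0.1), n_protein, d),
         # trainable adapters over the frozen feature views (the encoders'
         # final projection trains jointly with the rest of the model); small
         # init so an uninformative view can be annealed toward zero
         W_ad = if (config$use_DruSF) {
           matrix(stats::rnorm(d * d, sd = 0.1 / sqrt(d)), d, d)
         } else NULL,
         W_ap = if (config$use_ProSF) {
           matrix(stats::rnorm(d * d, sd = 0.1 / sqrt(d)), d, d)
         } else NULL,
         dpd = dpd, pdpd = pdpd, fusion = fus)
  })
}

# Squared-residual reconstruction term restricted to a set of (i, j) entries
# (NULL = the full dense matrix); keeps what the backward pass needs.
rec_term <- function(F, A, entries = NULL) {
  if (is.null(entries)) {
    P <- sigmoid(F %*% t(F))
    return(list(loss = sum((P - A)^2), P = P, entries = NULL))
  }
  m <- rowSums(F[entries[, 1], , drop = FALSE] * F[entries[, 2], , drop = FALSE])
  p <- sigmoid(m)
  a <- A[entries]
  list(loss = sum((p - a)^2), p = p, a = a, entries = entries)
}

# One full forward pass; ctx carries the fixed inputs. rec_entries optionally
# restricts the reconstruction terms to sampled entry minibatches.
model_forward <- function(state, ctx, batch = NULL, drop_d = NULL, drop_p = NULL,
                          rec_entries = NULL) {
  fw_dpd <- han_forward(state$E_d, state$E_d, ctx$nb_dpd, state$dpd)
  fw_pdpd <- han_forward(state$E_d, state$E_p, ctx$nb_pdpd, state$pdpd)
  s_d <- if (!is.null(ctx$S_drug)) ctx$S_drug %*% state$W_ad else NULL
  s_p <- if (!is.null(ctx$S_protein)) ctx$S_protein %*% state$W_ap else NULL
  fd <- fuse_forward(fw_dpd$embeddings, state$E_d, s_d, state$fusion,
                     dropout_mask = drop_d)
  fp <- fuse_forward(fw_pdpd$embeddings, state$E_p, s_p, state$fusion,
                     dropout_mask = drop_p)
  out <- list(fw_dpd = fw_dpd, fw_pdpd = fw_pdpd, fd = fd, fp = fp,
              s_d = s_d, s_p = s_p)
  out$rd <- rec_term(fd$f, ctx$A_dd, rec_entries$dd)
  out$rp <- rec_term(fp$f, ctx$A_pp, rec_entries$pp)
  out$rec_drug <- out$rd$loss
  out$rec_protein <- out$rp$loss
  if (!is.null(batch)) {
    logits <- rowSums(fd$f[batch$i, , drop = FALSE] * fp$f[batch$j, , drop = FALSE])
    p <- sigmoid(logits)
    out$p <- p
    out$ce <- cross_entropy_loss(batch$y, p)
    out$total <- total_loss(out$ce, out$rec_drug, out$rec_protein,
                            ctx$lambda1, ctx$lambda2)
  }
  out
}

# Backward through fusion: returns gradient pieces given dF (n x d_out).
fuse_backward <- function(fw, dF, params, dropout_mask = NULL) {
  nz <- fw$nrm > 0
  dr <- matrix(0, nrow(dF), ncol(dF))
  if (any(nz)) {
    fn <- fw$f[nz, , drop = FALSE]
    dfn <- dF[nz, , drop = FALSE]
    radial <- rowSums(fn * dfn)
    dr[nz, ] <- (dfn - fn * radial) / fw$nrm[nz]
  }
  dz <- dr * (fw$z > 0)
  dW0 <- t(fw$h) %*% dz
  db0 <- colSums(dz)
  dh <- dz %*% t(params$W0)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  dmate <- dh[, seq_len(params$d_mate), drop = FALSE]
  demb <- dh[, params$d_mate + seq_len(params$d_emb), drop = FALSE]
  list(dW0 = dW0, db0 = db0, dmate = dmate, demb = demb)
}

# Backward through node-level attention; dmate is the gradient w.r.t. the
# post-activation embeddings. Returns per-head dW, da plus dx_src, dx_tgt.
han_backward <- function(fw, dmate) {
  params <- fw$params
  dagg <- dmate * activation_grad(fw$agg, params$activation)
  dW <- vector("list", params$K); da <- vector("list", params$K)
  dx_src <- 0; dx_tgt <- 0
  for (k in seq_len(params$K)) {
    hd <- fw$heads[[k]]
    daggk <- dagg / params$K
    a1 <- params$a[[k]][seq_len(params$d_out)]
    a2 <- params$a[[k]][params$d_out + seq_len(params$d_out)]
    daggA <- daggk
    if (any(!fw$has_nb)) daggA[!fw$has_nb, ] <- 0
    dalpha <- daggA %*% t(hd$Hs)
    dHs <- t(hd$alpha) %*% daggA
    rs <- rowSums(hd$alpha * dalpha)
    de <- hd$alpha * (dalpha - rs)
    dC <- de * score_act_grad(hd$C, params)
    ds <- colSums(dC)
    dt_ <- rowSums(dC)
    dHs <- dHs + outer(ds, a1)
    dHt <- outer(dt_, a2)
    if (any(!fw$has_nb)) {
      dHt[!fw$has_nb, ] <- dHt[!fw$has_nb, , drop = FALSE] +
        daggk[!fw$has_nb, , drop = FALSE]
    }
    da1 <- drop(t(hd$Hs) %*% ds)
    da2 <- drop(t(hd$Ht) %*% dt_)
    dW[[k]] <- t(fw$x_src) %*% dHs + t(fw$x_tgt) %*% dHt
    da[[k]] <- c(da1, da2)
    dx_src <- dx_src + dHs %*% t(params$W[[k]])
    dx_tgt <- dx_tgt + dHt %*% t(params$W[[k]])
  }
  list(dW = dW, da = da, dx_src = dx_src, dx_tgt = dx_tgt)
}

# Accumulate rows of `values` into `target` grouped by `idx`.
index_add <- function(target, idx, values) {
  agg <- rowsum(values, group = idx)
  rows <- as.integer(rownames(agg))
  target[rows, ] <- target[rows, , drop = FALSE] + agg
  target
}

# Full backward pass; returns gradients for every trainable array.
model_backward <- function(state, ctx, fw, batch, drop_d = NULL, drop_p = NULL) {
  dF_d <- matrix(0, nrow(fw$fd$f), ncol(fw$fd$f))
  dF_p <- matrix(0, nrow(fw$fp$f), ncol(fw$fp$f))
  coef <- fw$p - batch$y  # d(ce)/d(logit), sum reduction
  dF_d <- index_add(dF_d, batch$i, coef * fw$fp$f[batch$j, , drop = FALSE])
  dF_p <- index_add(dF_p, batch$j, coef * fw$fd$f[batch$i, , drop = FALSE])
  if (is.null(fw$rd$entries)) {
    G_dd <- 2 * (fw$rd$P - ctx$A_dd) * fw$rd$P * (1 - fw$rd$P)
    dF_d <- dF_d + ctx$lambda1 * 2 * (G_dd %*% fw$fd$f)
  } else {
    e <- fw$rd$entries
    g <- ctx$lambda1 * 2 * (fw$rd$p - fw$rd$a) * fw$rd$p * (1 - fw$rd$p)
    dF_d <- index_add(dF_d, e[, 1], g * fw$fd$f[e[, 2], , drop = FALSE])
    dF_d <- index_add(dF_d, e[, 2], g * fw$fd$f[e[, 1], , drop = FALSE])
  }
  if (is.null(fw$rp$entries)) {
    G_pp <- 2 * (fw$rp$P - ctx$A_pp) * fw$rp$P * (1 - fw$rp$P)
    dF_p <- dF_p + ctx$lambda2 * 2 * (G_pp %*% fw$fp$f)
  } else {
    e <- fw$rp$entries
    g <- ctx$lambda2 * 2 * (fw$rp$p - fw$rp$a) * fw$rp$p * (1 - fw$rp$p)
    dF_p <- index_add(dF_p, e[, 1], g * fw$fp$f[e[, 2], , drop = FALSE])
    dF_p <- index_add(dF_p, e[, 2], g * fw$fp$f[e[, 1], , drop = FALSE])
  }

  bd <- fuse_backward(fw$fd, dF_d, state$fusion, drop_d)
  bp <- fuse_backward(fw$fp, dF_p, state$fusion, drop_p)
  hd <- han_backward(fw$fw_dpd, bd$dmate)
  hp <- han_backward(fw$fw_pdpd, bp$dmate)

  # feature-view adapters: demb is also the gradient w.r.t. the normalized
  # feature rows; undo the row normalization, then map back through the base
  adapter_grad <- function(fwf, s, demb, base) {
    if (is.null(s)) return(NULL)
    nz <- fwf$s_nrm > 0
    ds <- matrix(0, nrow(demb), ncol(demb))
    if (any(nz)) {
      sn <- fwf$s_norm[nz, , drop = FALSE]
      dn <- demb[nz, , drop = FALSE]
      ds[nz, ] <- (dn - sn * rowSums(sn * dn)) / fwf$s_nrm[nz]
    }
    t(base) %*% ds
  }

  list(
    E_d = bd$demb + hd$dx_src + hd$dx_tgt + hp$dx_src,
    E_p = bp$demb + hp$dx_tgt,
    W_ad = adapter_grad(fw$fd, fw$s_d, bd$demb, ctx$S_drug),
    W_ap = adapter_grad(fw$fp, fw$s_p, bp$demb, ctx$S_protein),
    dpd_W = hd$dW, dpd_a = hd$da,
    pdpd_W = hp$dW, pdpd_a = hp$da,
    W0 = bd$dW0 + bp$dW0,
    b0 = bd$db0 + bp$db0
  )
}

adam_state <- function(shapes) {
  lapply(shapes, function(x) list(m = x * 0, v = x * 0))
}

adam_update <- function(theta, g, opt, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$m <- b1 * opt$m + (1 - b1) * g
  opt$v <- b2 * opt$v + (1 - b2) * g^2
  mhat <- opt$m / (1 - b1^t)
  vhat <- opt$v / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), opt = opt)
}

# Flatten/unflatten the trainable arrays for the optimizer loop.
collect_params <- function(state) {
  out <- list(E_d = state$E_d, E_p = state$E_p, W0 = state$fusion$W0,
              b0 = state$fusion$b0)
  if (!is.null(state$W_ad)) out$W_ad <- state$W_ad
  if (!is.null(state$W_ap)) out$W_ap <- state$W_ap
  for (side in c("dpd", "pdpd")) {
    for (k in seq_len(state[[side]]$K)) {
      out[[paste0(side, "_W", k)]] <- state[[side]]$W[[k]]
      out[[paste0(side, "_a", k)]] <- state[[side]]$a[[k]]
    }
  }
  out
}

assign_params <- function(state, flat) {
  state$E_d <- flat$E_d; state$E_p <- flat$E_p
  state$fusion$W0 <- flat$W0; state$fusion$b0 <- flat$b0
  if (!is.null(flat$W_ad)) state$W_ad <- flat$W_ad
  if (!is.null(flat$W_ap)) state$W_ap <- flat$W_ap
  for (side in c("dpd", "pdpd")) {
    for (k in seq_len(state[[side]]$K)) {
      state[[side]]$W[[k]] <- flat[[paste0(side, "_W", k)]]
      state[[side]]$a[[k]] <- flat[[paste0(side, "_a", k)]]
    }
  }
  state
}

flatten_grads <- function(g, state) {
  out <- list(E_d = g$E_d, E_p = g$E_p, W0 = g$W0, b0 = g$b0)
  if (!is.null(state$W_ad)) out$W_ad <- g$W_ad
  if (!is.null(state$W_ap)) out$W_ap <- g$W_ap
  for (side in c("dpd", "pdpd")) {
    for (k in seq_len(state[[side]]$K)) {
      out[[paste0(side, "_W", k)]] <- g[[paste0(side, "_W")]][[k]]
      out[[paste0(side, "_a", k)]] <- g[[paste0(side, "_a")]][[k]]
    }
  }
  out
}

#' Train the multiview interaction model
#'
#' Runs `config$steps` Adam iterations of the joint objective
#' (cross-entropy over minibatches of training pairs plus weighted drug and
#' protein adjacency-reconstruction losses). Only training positives are
#' visible to meta-path construction: held-out edges are removed from the
#' drug-protein adjacency before neighbor structures are built. Fully
#' reproducible given `config$seed`.
#'
#' @param network a [hetero_network()].
#' @param smiles named character vector of SMILES by drug id (ids must match
#'   the network's drug nodes).
#' @param sequences named character vector or `protein_sequence` list by
#'   protein id.
#' @param split an [split_edges()] result.
#' @param config a [train_config()].
#' @param features optionally a precomputed [prepare_features()] result.
#' @param shuffle_labels permute the training labels (negative control).
#' @return object of class `dti_model` with the trained state, the fused
#'   representations, the per-step loss trace, and the configuration.
#' @export
train_model <- function(network, smiles, sequences, split,
                        config = train_config(), features = NULL,
                        shuffle_labels = FALSE) {
  drug_ids <- network$nodes$drug
  prot_ids <- network$nodes$protein
  if (!setequal(names(smiles), drug_ids)) {
    stopf("drug ids in the SMILES table do not match the network's drug nodes")
  }
  seq_names <- names(sequences)
  if (!setequal(seq_names, prot_ids)) {
    stopf("protein ids in the sequence table do not match the network's protein nodes")
  }
  smiles <- smiles[drug_ids]
  sequences <- sequences[prot_ids]
  if (is.null(features)) features <- prepare_features(smiles, sequences, config)

  masked <- mask_test_edges(network, split)
  ctx <- list(
    nb_dpd = metapath_adjacency(masked, metapath_dpd()),
    nb_pdpd = metapath_adjacency(masked, metapath_pdpd()),
    A_dd = network$adjacency$drug_drug,
    A_pp = network$adjacency$protein_protein,
    S_drug = if (config$use_DruSF) features$S_drug else NULL,
    S_protein = if (config$use_ProSF) features$S_protein else NULL,
    lambda1 = config$lambda1, lambda2 = config$lambda2
  )
  ctx$dd_ones <- which(ctx$A_dd == 1, arr.ind = TRUE)
  ctx$pp_ones <- which(ctx$A_pp == 1, arr.ind = TRUE)
  ctx$dd_zero_cells <- which(ctx$A_dd == 0, arr.ind = TRUE)
  ctx$pp_zero_cells <- which(ctx$A_pp == 0, arr.ind = TRUE)
  state <- init_model_state(length(drug_ids), length(prot_ids), config)

  pool <- rbind(split$train_positive, split$train_negative)
  y_pool <- c(rep(1, nrow(split$train_positive)), rep(0, nrow(split$train_negative)))
  n_pool <- nrow(pool)
  d <- config$han_input_size
  trace <- numeric(config$steps)

  flat <- collect_params(state)
  opt <- adam_state(flat)

  with_seed(derive_seed(config$seed, "train-loop"), {
    if (shuffle_labels) y_pool <- y_pool[sample.int(n_pool)]
    pos_idx <- which(y_pool == 1); neg_idx <- which(y_pool == 0)
    for (step in seq_len(config$steps)) {
      take <- if (config$balanced_batches && length(pos_idx) > 0 &&
                  length(neg_idx) > 0) {
        # stratified minibatches: equal attraction/repulsion pressure per
        # step, which keeps ReLU units alive under the 10:1 class imbalance
        n_half <- min(config$batch_size %/% 2, length(pos_idx))
        c(sample(pos_idx, n_half),
          sample(neg_idx, min(config$batch_size - n_half, length(neg_idx))))
      } else {
        sample.int(n_pool, min(config$batch_size, n_pool))
      }
      batch <- list(i = pool[take, 1], j = pool[take, 2], y = y_pool[take])
      drop_d <- drop_p <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        drop_d <- matrix(stats::rbinom(length(drug_ids) * 2 * d, 1, keep),
                         length(drug_ids), 2 * d) / keep
        drop_p <- matrix(stats::rbinom(length(prot_ids) * 2 * d, 1, keep),
                         length(prot_ids), 2 * d) / keep
      }
      rec_entries <- NULL
      if (config$balanced_batches) {
        # balanced entry minibatches for the reconstruction terms: all
        # within-type positive entries plus an equal-size sample of zeros
        rec_entries <- list(
          dd = rbind(ctx$dd_ones,
                     ctx$dd_zero_cells[sample.int(nrow(ctx$dd_zero_cells),
                                                  min(nrow(ctx$dd_ones),
                                                      nrow(ctx$dd_zero_cells))), ,
                                       drop = FALSE]),
          pp = rbind(ctx$pp_ones,
                     ctx$pp_zero_cells[sample.int(nrow(ctx$pp_zero_cells),
                                                  min(nrow(ctx$pp_ones),
                                                      nrow(ctx$pp_zero_cells))), ,
                                       drop = FALSE])
        )
      }
      fw <- model_forward(state, ctx, batch, drop_d, drop_p, rec_entries)
      if (!is.finite(fw$total)) stopf("training diverged at step %d (non-finite loss)", step)
      trace[step] <- fw$total
      g <- flatten_grads(model_backward(state, ctx, fw, batch, drop_d, drop_p),
                         state)
      for (nm in names(flat)) {
        upd <- adam_update(flat[[nm]], g[[nm]], opt[[nm]],
                           config$learning_rate, step)
        flat[[nm]] <- upd$theta
        opt[[nm]] <- upd$opt
      }
      state <- assign_params(state, flat)
    }
  })

  final <- model_forward(state, ctx)
  f_d <- final$fd$f; rownames(f_d) <- drug_ids
  f_p <- final$fp$f; rownames(f_p) <- prot_ids
  structure(list(state = state, f_drug = f_d, f_protein = f_p,
                 trace = trace, config = config, split = split,
                 drug_ids = drug_ids, protein_ids = prot_ids),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat(sprintf("<dti_model> %d drugs x %d proteins, %d steps, final loss %.4g\n",
              length(x$drug_ids), length(x$protein_ids),
              length(x$trace), utils::tail(x$trace, 1)))
  invisible(x)
}

#' Score drug-protein pairs with a trained model
#'
#' @param model a [train_model()] result.
#' @param pairs two-column index matrix (drug index, protein index); `NULL`
#'   returns the full score matrix.
#' @export
predict_interactions <- function(model, pairs = NULL) {
  if (is.null(pairs)) {
    return(interaction_probability(model$f_drug, model$f_protein))
  }
  sigmoid(rowSums(model$f_drug[pairs[, 1], , drop = FALSE] *
                    model$f_protein[pairs[, 2], , drop = FALSE]))
}

#' Evaluate a trained model on held-out edges
#'
#' @param model a `dti_model`.
#' @param split an `edge_split`; its `test_positive` / `test_negative` pairs
#'   are scored.
#' @param threshold cutoff for F1/MCC (default from the model config).
#' @return a [metric_set()] list.
#' @export
evaluate_model <- function(model, split = model$split, threshold = NULL) {
  pairs <- rbind(split$test_positive, split$test_negative)
  labels <- c(rep(1, nrow(split$test_positive)), rep(0, nrow(split$test_negative)))
  scores <- predict_interactions(model, pairs)
  metric_set(labels, scores,
             threshold = if (is.null(threshold)) model$config$threshold else threshold)
}

#' k-fold cross-validation
#'
#' Trains and evaluates once per fold of the edge partition from
#' [split_edges()]; folds are reproducible and their test sets partition the
#' positive set. Feature views are computed once and reused across folds.
#'
#' @param network a [hetero_network()].
#' @param smiles,sequences input tables as in [train_model()].
#' @param k number of folds (>= 2; default 10).
#' @param config a [train_config()].
#' @return list with `folds` (a data frame of per-fold metrics) and `mean`
#'   (named numeric vector of column means).
#' @export
cross_validate <- function(network, smiles, sequences, k = 10,
                           config = train_config()) {
  if (k < 2) stopf("k must be >= 2")
  smiles <- smiles[network$nodes$drug]
  sequences <- sequences[network$nodes$protein]
  features <- prepare_features(smiles, sequences, config)
  rows <- lapply(seq_len(k), function(fold) {
    split <- split_edges(network, test_fraction = 1 / k,
                         neg_ratio = config$neg_per_pos, fold_id = fold,
                         seed = config$seed)
    model <- train_model(network, smiles, sequences, split, config,
                         features = features)
    m <- evaluate_model(model, split)
    data.frame(fold = fold, auroc = m$auroc, aupr = m$aupr, f1 = m$f1,
               mcc = m$mcc)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds, mean = colMeans(folds[, c("auroc", "aupr", "f1", "mcc")]))
}

#' Shuffled-label negative control
#'
#' Retrains with permuted training labels and evaluates on the true held-out
#' edges; a sound model must beat this control by a wide margin.
#' @inheritParams train_model
#' @export
shuffled_label_control <- function(network, smiles, sequences, split,
                                   config = train_config(), features = NULL) {
  model <- train_model(network, smiles, sequences, split, config,
                       features = features, shuffle_labels = TRUE)
  evaluate_model(model, split)
}
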