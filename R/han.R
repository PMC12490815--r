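# Relational view: node-level attention over meta-path neighbors with an
# adaptive activation on the attention scores, plus semantic-level attention
# that fuses several meta-path embeddings of the same node set.

#' Adaptive activation (ACON-C family)
#'
#' Elementwise `(p1 - p2) * x * sigmoid(beta * (p1 - p2) * x) + p2 * x`.
#' Interpolates between linear (`p1 = p2`) and, for large `beta`, a smooth
#' maximum of `p1 * x` and `p2 * x` (ReLU-like at `p1 = 1, p2 = 0`).
#'
#' @param x numeric input (any shape).
#' @param p1,p2 slope parameters.
#' @param beta switching sharpness (>= 0).
#' @export
aconc <- function(x, p1 = 1, p2 = 0, beta = 1) {
  assert_finite(x, "aconc input")
  d <- p1 - p2
  d * x * sigmoid(beta * d * x) + p2 * x
}

# Derivative of aconc with respect to x (needed by training backprop).
aconc_grad <- function(x, p1 = 1, p2 = 0, beta = 1) {
  d <- p1 - p2
  s <- sigmoid(beta * d * x)
  d * s + d * x * s * (1 - s) * beta * d + p2
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

#' Parameters for node-level meta-path attention
#'
#' One shared linear transform `W` and one attention vector `a` per head;
#' attention scores pass through the adaptive activation ([aconc()]) or a
#' leaky ReLU. Head outputs are averaged and passed through `activation`.
#'
#' @param d_in input embedding width.
#' @param d_out output width per head.
#' @param K number of heads (>= 1; default 1).
#' @param score_activation `"aconc"` (default) or `"leaky_relu"`.
#' @param activation output nonlinearity: `"elu"` (default), `"relu"`, or
#'   `"identity"`.
#' @param p1,p2,beta adaptive-activation parameters (fixed hyperparameters).
#' @param seed RNG seed for the parameter draw.
#' @export
attention_params <- function(d_in, d_out = d_in, K = 1,
                             score_activation = c("aconc", "leaky_relu"),
                             activation = c("elu", "relu", "identity"),
                             p1 = 1, p2 = 0, beta = 1, seed = 1) {
  score_activation <- match.arg(score_activation)
  activation <- match.arg(activation)
  if (K < 1) stopf("K must be >= 1")
  with_seed(derive_seed(seed, "han"), {
    W <- lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out)
    })
    a <- lapply(seq_len(K), function(k) stats::rnorm(2 * d_out, sd = 0.1))
    structure(list(W = W, a = a, K = K, d_in = d_in, d_out = d_out,
                   score_activation = score_activation, activation = activation,
                   p1 = p1, p2 = p2, beta = beta, seed = seed),
              class = "attention_params")
  })
}

apply_activation <- function(x, kind) {
  switch(kind, elu = elu(x), relu = relu(x), identity = x)
}
activation_grad <- function(x, kind) {
  switch(kind, elu = elu_grad(x), relu = (x > 0) + 0, identity = array(1, dim(x)))
}
apply_score_act <- function(x, params) {
  if (params$score_activation == "aconc") aconc(x, params$p1, params$p2, params$beta)
  else leaky_relu(x)
}
score_act_grad <- function(x, params) {
  if (params$score_activation == "aconc") aconc_grad(x, params$p1, params$p2, params$beta)
  else leaky_relu_grad(x)
}

# Full forward pass of node-level attention, keeping every intermediate the
# backward pass needs. neighbors: binary n_tgt x n_src matrix.
han_forward <- function(x_src, x_tgt, neighbors, params) {
  x_src <- as.matrix(x_src); x_tgt <- as.matrix(x_tgt)
  if (ncol(x_src) != params$d_in || ncol(x_tgt) != params$d_in) {
    stopf("embedding width %d does not match attention d_in %d",
          ncol(x_src), params$d_in)
  }
  if (nrow(neighbors) != nrow(x_tgt) || ncol(neighbors) != nrow(x_src)) {
    stopf("neighbor matrix must be n_tgt x n_src")
  }
  M <- neighbors > 0
  has_nb <- rowSums(M) > 0
  heads <- vector("list", params$K)
  agg <- 0
  for (k in seq_len(params$K)) {
    Hs <- x_src %*% params$W[[k]]
    Ht <- x_tgt %*% params$W[[k]]
    a1 <- params$a[[k]][seq_len(params$d_out)]
    a2 <- params$a[[k]][params$d_out + seq_len(params$d_out)]
    s <- drop(Hs %*% a1)   # neighbor (source) term
    t_ <- drop(Ht %*% a2)  # target term
    C <- outer(t_, s, `+`)
    E <- apply_score_act(C, params)
    alpha <- masked_row_softmax(E, M)
    aggk <- alpha %*% Hs
    # empty neighborhoods: fall back to the node's own transformed embedding
    if (any(!has_nb)) aggk[!has_nb, ] <- Ht[!has_nb, , drop = FALSE]
    heads[[k]] <- list(Hs = Hs, Ht = Ht, s = s, t = t_, C = C, alpha = alpha,
                       aggk = aggk)
    agg <- agg + aggk / params$K
  }
  f <- apply_activation(agg, params$activation)
  list(embeddings = f, agg = agg, heads = heads, M = M, has_nb = has_nb,
       x_src = x_src, x_tgt = x_tgt, params = params)
}

#' Node-level attention over meta-path neighbors
#'
#' For target node v with meta-path neighbors N(v), attention coefficients are
#' a softmax over `aconc(a' [W f0(u) || W f0(v)])` for u in N(v); the output
#' embedding is `sigma(mean_k sum_u alpha_uv W_k f0(u))` over K heads. Nodes
#' with empty neighborhoods fall back to their own transformed embedding.
#' Attention over each nonempty neighborhood sums to one.
#'
#' @param x_src embeddings of the candidate neighbor nodes (n_src x d_in).
#' @param x_tgt embeddings of the target nodes (n_tgt x d_in); pass the same
#'   matrix as `x_src` for a within-type meta-path such as drug-protein-drug.
#' @param neighbors binary (n_tgt x n_src) meta-path neighbor matrix, e.g.
#'   from [metapath_adjacency()] (for a protein-...-drug path, rows are
#'   proteins and columns drugs).
#' @param params an [attention_params()].
#' @return list with `embeddings` (n_tgt x d_out) and `attention` (a list of
#'   per-head coefficient matrices, rows summing to 1 on nonempty
#'   neighborhoods).
#' @export
node_level_attention <- function(x_src, x_tgt, neighbors, params) {
  fw <- han_forward(x_src, x_tgt, neighbors, params)
  list(embeddings = fw$embeddings,
       attention = lapply(fw$heads, `[[`, "alpha"))
}

#' Parameters for semantic-level attention
#'
#' @param d embedding width of the per-meta-path tables.
#' @param d_att width of the attention projection.
#' @param seed RNG seed.
#' @export
semantic_params <- function(d, d_att = min(d, 32), seed = 1) {
  with_seed(derive_seed(seed, "semantic"), {
    structure(list(
      W_s = matrix(stats::rnorm(d * d_att, sd = 1 / sqrt(d)), d, d_att),
      b_s = stats::rnorm(d_att, sd = 0.1),
      q = stats::rnorm(d_att, sd = 0.1),
      d = d, d_att = d_att, seed = seed
    ), class = "semantic_params")
  })
}

#' Semantic-level attention across meta-paths
#'
#' Each meta-path's importance is the mean over nodes of
#' `q' tanh(W_s z(v) + b_s)`; a softmax over meta-paths yields weights
#' `beta`, and the fused embedding is the beta-weighted sum of the tables.
#'
#' @param tables named list of per-meta-path embedding matrices over the same
#'   node set (identical dimensions).
#' @param params a [semantic_params()].
#' @return list with `embeddings` (fused matrix), `weights` (softmax beta per
#'   meta-path) and `importance` (raw scores).
#' @export
semantic_attention <- function(tables, params) {
  if (length(tables) < 1) stopf("need at least one meta-path table")
  dims <- lapply(tables, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stopf("meta-path tables must share one node set (equal dimensions)")
  }
  w <- vapply(tables, function(Z) {
    mean(tanh(sweep(Z %*% params$W_s, 2, params$b_s, `+`)) %*% params$q)
  }, numeric(1))
  beta <- exp(w - max(w)); beta <- beta / sum(beta)
  fused <- Reduce(`+`, Map(function(b, Z) b * Z, beta, tables))
  list(embeddings = fused, weights = beta, importance = w)
}

#' Export attention weights for inspection
#'
#' Writes node/neighbor/weight triples (head-averaged) as TSV.
#' @param attention list of per-head coefficient matrices from
#'   [node_level_attention()].
#' @param path output TSV path.
#' @param node_ids,neighbor_ids optional identifier vectors.
#' @export
write_attention_weights <- function(attention, path, node_ids = NULL,
                                    neighbor_ids = NULL) {
  avg <- Reduce(`+`, attention) / length(attention)
  idx <- which(avg > 0, arr.ind = TRUE)
  df <- data.frame(
    node = if (is.null(node_ids)) idx[, 1] else node_ids[idx[, 1]],
    neighbor = if (is.null(neighbor_ids)) idx[, 2] else neighbor_ids[idx[, 2]],
    weight = avg[idx]
  )
  df <- df[order(df$node, -df$weight), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
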