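# Molecular attention encoder: stacked multi-head self-attention over atoms
# where each head mixes three row-stochastic components — scaled dot-product
# attention, a distance kernel g(D), and the bond adjacency — weighted by
# scalar coefficients (mu_a: distances, mu_b: self-attention, mu_c: adjacency).
# Per-atom outputs are mean-pooled over real atoms into the drug structural
# vector S_drug.

#' Parameters of the molecular attention encoder
#'
#' Weights are drawn once from seeded Gaussians (scaled by 1/sqrt(fan-in));
#' the encoder is a deterministic featurizer given its seed. Defaults: 16
#' heads and a stack of 8 layers.
#'
#' @param d_atom width of the per-atom feature vectors.
#' @param d_model model width (must be divisible by `n_heads`); this is also
#'   the width of the pooled drug vector.
#' @param n_heads number of attention heads (default 16).
#' @param n_layers stack depth (default 8).
#' @param mu length-3 nonnegative weights `c(mu_a, mu_b, mu_c)` for the
#'   distance, self-attention and adjacency components (default equal thirds).
#' @param dist_kernel `"softmax"` (masked row-wise softmax of -D, the
#'   default; keeps all three components row-stochastic) or `"exp"`
#'   (elementwise `exp(-D)`, row-normalized over real atoms).
#' @param seed RNG seed for the parameter draw.
#' @return object of class `mat_params`.
#' @export
mat_params <- function(d_atom, d_model = 64, n_heads = 16, n_layers = 8,
                       mu = c(1, 1, 1) / 3, dist_kernel = c("softmax", "exp"),
                       seed = 1) {
  dist_kernel <- match.arg(dist_kernel)
  if (d_model %% n_heads != 0) stopf("n_heads must divide d_model")
  if (length(mu) != 3 || any(mu < 0)) stopf("mu must be 3 nonnegative weights")
  d_k <- d_model / n_heads
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  with_seed(derive_seed(seed, "mat"), {
    layers <- lapply(seq_len(n_layers), function(l) {
      list(W_q = init(d_model, d_model), W_k = init(d_model, d_model),
           W_v = init(d_model, d_model), W_o = init(d_model, d_model),
           W_ff1 = init(d_model, 2 * d_model), b_ff1 = rep(0, 2 * d_model),
           W_ff2 = init(2 * d_model, d_model), b_ff2 = rep(0, d_model))
    })
    structure(list(W_embed = init(d_atom, d_model), layers = layers,
                   d_atom = d_atom, d_model = d_model, n_heads = n_heads,
                   n_layers = n_layers, d_k = d_k, mu = mu,
                   dist_kernel = dist_kernel, seed = seed),
              class = "mat_params")
  })
}

# Distance kernel g(D): row-stochastic weighting of atoms by proximity,
# restricted to real atoms.
distance_kernel <- function(D, mask, kind) {
  mm <- outer(mask, mask, `&`)
  if (kind == "softmax") {
    g <- masked_row_softmax(-D, mm)
  } else {
    g <- exp(-D) * mm
    rs <- rowSums(g)
    nz <- rs > 0
    g[nz, ] <- g[nz, , drop = FALSE] / rs[nz]
  }
  g[!mask, ] <- 0
  g
}

#' Per-head molecular attention
#'
#' The core attention map of the encoder: for head i,
#' `A(i) = (mu_b * rho(Q_i K_i' / sqrt(d_k)) + mu_a * g(D) + mu_c * A) V_i`,
#' with `rho` a masked row-wise softmax over real atoms and `g(D)` the
#' configured distance kernel. Returns one matrix per head (n_atoms x d_k);
#' [molecule_attention()] concatenates and mixes them.
#'
#' @param graph a [molecule_graph()].
#' @param params a [mat_params()].
#' @param x optional per-atom input (n_atoms x d_model); defaults to the
#'   embedded atom features.
#' @param layer which layer's projections to use.
#' @return list of per-head output matrices.
#' @export
mat_attention_heads <- function(graph, params, x = NULL, layer = 1) {
  mask <- graph$mask
  if (!any(mask)) stopf("degenerate input: mask excludes every atom")
  if (is.null(x)) x <- graph$atom_features %*% params$W_embed
  assert_finite(x, "attention input")
  L <- params$layers[[layer]]
  n <- nrow(x); h <- params$n_heads; d_k <- params$d_k
  mu <- params$mu
  g <- distance_kernel(graph$distances, mask, params$dist_kernel)
  A <- graph$adjacency
  mm <- outer(mask, mask, `&`)
  out <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    Q <- x %*% L$W_q[, cols, drop = FALSE]
    K <- x %*% L$W_k[, cols, drop = FALSE]
    V <- x %*% L$W_v[, cols, drop = FALSE]
    rho <- masked_row_softmax(Q %*% t(K) / sqrt(d_k), mm)
    att <- mu[2] * rho + mu[1] * g + mu[3] * A
    o <- att %*% V
    o[!mask, ] <- 0
    out[[i]] <- o
  }
  out
}

#' One molecular attention sublayer (all heads, concatenated and mixed)
#'
#' @inheritParams mat_attention_heads
#' @return matrix (n_atoms x d_model); padded rows are zero.
#' @export
molecule_attention <- function(graph, params, x = NULL, layer = 1) {
  heads <- mat_attention_heads(graph, params, x = x, layer = layer)
  concat <- do.call(cbind, heads)
  out <- concat %*% params$layers[[layer]]$W_o
  out[!graph$mask, ] <- 0
  out
}

#' Encode a molecule into its structural feature vector S_drug
#'
#' Applies the attention stack with residual connections and position-wise
#' feed-forward sublayers, then mean-pools per-atom outputs over real atoms.
#'
#' @param graph a [molecule_graph()].
#' @param params a [mat_params()].
#' @return numeric vector of length `d_model`.
#' @export
encode_drug <- function(graph, params) {
  mask <- graph$mask
  if (!any(mask)) stopf("degenerate input: mask excludes every atom")
  x <- graph$atom_features %*% params$W_embed
  x[!mask, ] <- 0
  for (l in seq_len(params$n_layers)) {
    x <- x + molecule_attention(graph, params, x = x, layer = l)
    L <- params$layers[[l]]
    ff <- relu(sweep(x %*% L$W_ff1, 2, L$b_ff1, `+`)) %*% L$W_ff2
    ff <- sweep(ff, 2, L$b_ff2, `+`)
    x <- x + ff
    x[!mask, ] <- 0
  }
  colMeans(x[mask, , drop = FALSE])
}

#' Encode a table of drugs
#'
#' Parses each SMILES once (results cached by string within the call) and
#' encodes it; rows follow the input order.
#'
#' @param smiles named character vector of SMILES, names are drug ids.
#' @param params a [mat_params()].
#' @param max_len,distance forwarded to [smiles_to_graph()].
#' @return matrix (n_drugs x d_model) with drug ids as rownames.
#' @export
encode_drug_table <- function(smiles, params, max_len = 100,
                              distance = "topological") {
  uniq <- unique(smiles)
  enc <- vapply(uniq, function(s) {
    encode_drug(smiles_to_graph(s, max_len = max_len, distance = distance), params)
  }, numeric(params$d_model))
  out <- t(enc)[match(smiles, uniq), , drop = FALSE]
  rownames(out) <- names(smiles)
  out
}
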