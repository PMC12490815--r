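# Multiview fusion, inner-product decoder, and the joint objective:
# cross-entropy on drug-protein pairs plus adjacency-reconstruction penalties
# on the drug-drug and protein-protein graphs.

#' Fusion head parameters
#'
#' A single linear map shared between the drug and protein heads: the
#' concatenated meta-path and embedding blocks are projected by `W0` and
#' shifted by `b0`, passed through ReLU, and row-normalized to unit length.
#'
#' @param d_mate width of the meta-path block.
#' @param d_emb width of the embedding (+ feature) block.
#' @param d_out fused representation width.
#' @param lambda1,lambda2 nonnegative weights of the drug and protein
#'   reconstruction losses in the total objective (defaults 1, 1).
#' @param seed RNG seed for the parameter draw.
#' @export
fusion_params <- function(d_mate, d_emb, d_out = d_emb, lambda1 = 1,
                          lambda2 = 1, seed = 1) {
  if (lambda1 < 0 || lambda2 < 0) stopf("lambda weights must be nonnegative")
  d_in <- d_mate + d_emb
  with_seed(derive_seed(seed, "fusion"), {
    structure(list(
      W0 = matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out),
      b0 = rep(0, d_out),
      d_mate = d_mate, d_emb = d_emb, d_out = d_out,
      lambda1 = lambda1, lambda2 = lambda2, seed = seed
    ), class = "fusion_params")
  })
}

# Shared fusion forward; keeps intermediates for backprop. The meta-path
# block is concatenated first, then the (embedding + normalized feature)
# block.
fuse_forward <- function(mate, e, s, params, dropout_mask = NULL) {
  mate <- as.matrix(mate); e <- as.matrix(e)
  if (ncol(mate) != params$d_mate) stopf("meta-path block width %d, expected %d",
                                         ncol(mate), params$d_mate)
  if (ncol(e) != params$d_emb) stopf("embedding block width %d, expected %d",
                                     ncol(e), params$d_emb)
  if (is.null(s)) {
    s_norm <- matrix(0, nrow(e), ncol(e))
    s_nrm <- rep(0, nrow(e))
  } else {
    s <- as.matrix(s)
    s_nrm <- sqrt(rowSums(s^2))
    s_norm <- l2_normalize_rows(s)
  }
  if (ncol(s_norm) != ncol(e)) stopf("feature width %d, expected %d", ncol(s_norm), ncol(e))
  h <- cbind(mate, e + s_norm)
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  z <- sweep(h %*% params$W0, 2, params$b0, `+`)
  r <- relu(z)
  nrm <- sqrt(rowSums(r^2))
  f <- r
  nz <- nrm > 0
  f[nz, ] <- r[nz, , drop = FALSE] / nrm[nz]
  list(f = f, r = r, z = z, h = h, nrm = nrm, s_norm = s_norm, s_nrm = s_nrm)
}

#' Fuse the drug views into the final drug representation
#'
#' `f_drug = L2Norm(ReLU([mate_DPD || E_drug + L2Norm(S_drug)] W0 + b0))`,
#' computed row-wise. Rows that ReLU silences stay exactly zero (no division
#' by a zero norm).
#'
#' @param mate_dpd meta-path (drug-protein-drug) embeddings, one row per drug.
#' @param e_drug free drug embeddings, row-aligned with `mate_dpd`.
#' @param s_drug drug structural features (or `NULL` / zeros when the
#'   structural view is ablated).
#' @param params a [fusion_params()].
#' @return matrix of unit-norm (or zero) rows.
#' @export
fuse_drug <- function(mate_dpd, e_drug, s_drug, params) {
  fuse_forward(mate_dpd, e_drug, s_drug, params)$f
}

#' @rdname fuse_drug
#' @param mate_pdpd meta-path (protein-disease-protein-drug) embeddings, one
#'   row per protein.
#' @param e_protein free protein embeddings.
#' @param s_protein protein sequence features (or `NULL` when ablated).
#' @export
fuse_protein <- function(mate_pdpd, e_protein, s_protein, params) {
  fuse_forward(mate_pdpd, e_protein, s_protein, params)$f
}

#' Inner-product interaction decoder
#'
#' `p = sigmoid(f_u' f_v)`. With matrix inputs returns the full
#' drugs x proteins score matrix.
#'
#' @param f_u drug representation (vector) or matrix of drug rows.
#' @param f_v protein representation (vector) or matrix of protein rows.
#' @export
interaction_probability <- function(f_u, f_v) {
  if (is.matrix(f_u) || is.matrix(f_v)) {
    f_u <- as.matrix(f_u); f_v <- as.matrix(f_v)
    if (ncol(f_u) != ncol(f_v)) stopf("representation widths differ")
    return(sigmoid(f_u %*% t(f_v)))
  }
  if (length(f_u) != length(f_v)) stopf("representation widths differ")
  sigmoid(sum(f_u * f_v))
}

#' Cross-entropy link loss
#'
#' `sum_r -y_r log p_r - (1 - y_r) log(1 - p_r)`; the sum convention is the
#' default, `reduction = "mean"` divides by the batch size. Probabilities are
#' clipped into `(eps, 1 - eps)` to guard the logarithms.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities, same length.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @param eps clipping constant (default 1e-7).
#' @export
cross_entropy_loss <- function(labels, probabilities, reduction = c("sum", "mean"),
                               eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(labels) != length(probabilities)) stopf("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  l <- -labels * log(p) - (1 - labels) * log(1 - p)
  if (reduction == "sum") sum(l) else mean(l)
}

#' Adjacency reconstruction loss
#'
#' The reconstructed adjacency is the sigmoid of the embedding Gram matrix,
#' `A_hat = sigmoid(F F')`; the loss is the squared Frobenius norm
#' `||A_hat - A||_F^2`.
#'
#' @param embeddings node embeddings, one row per node.
#' @param adjacency square binary within-type adjacency, row-aligned.
#' @export
reconstruction_loss <- function(embeddings, adjacency) {
  embeddings <- as.matrix(embeddings); adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stopf("adjacency must be square")
  if (nrow(embeddings) != nrow(adjacency)) stopf("embeddings and adjacency are not row-aligned")
  a_hat <- sigmoid(embeddings %*% t(embeddings))
  sum((a_hat - adjacency)^2)
}

#' Total training objective
#'
#' `ce + lambda1 * rec_drug + lambda2 * rec_protein`.
#' @param ce cross-entropy term.
#' @param rec_drug,rec_protein reconstruction terms.
#' @param lambda1,lambda2 nonnegative weights.
#' @export
total_loss <- function(ce, rec_drug, rec_protein, lambda1 = 1, lambda2 = 1) {
  stopifnot(is.finite(ce), is.finite(rec_drug), is.finite(rec_protein))
  ce + lambda1 * rec_drug + lambda2 * rec_protein
}

#' Write ranked predictions as TSV
#'
#' @param scores drugs x proteins score matrix with dimnames.
#' @param path output path; columns drug_id, protein_id, score, descending.
#' @param top_n optionally keep only the highest-scoring pairs.
#' @export
write_predictions <- function(scores, path, top_n = NULL) {
  idx <- which(!is.na(scores), arr.ind = TRUE)
  df <- data.frame(
    drug_id = rownames(scores)[idx[, 1]],
    protein_id = colnames(scores)[idx[, 2]],
    score = scores[idx]
  )
  df <- df[order(-df$score), ]
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
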