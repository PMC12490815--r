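# Adaptive activation, node-level attention over meta-path neighbors, and
# semantic-level fusion.

test_that("aconc closed forms: zero, linear, and large-beta ReLU limit", {
  expect_equal(aconc(0, p1 = 2, p2 = -1, beta = 3), 0)
  x <- seq(-2, 2, by = 0.5)
  expect_equal(aconc(x, p1 = 0.7, p2 = 0.7, beta = 5), 0.7 * x)
  expect_equal(aconc(c(-1, 1), p1 = 1, p2 = 0, beta = 100),
               pmax(c(-1, 1), 0), tolerance = 1e-2)
  expect_error(aconc(c(1, NaN)), "non-finite")
})

test_that("aconc derivative matches finite differences", {
  x <- seq(-2, 2, by = 0.37)
  eps <- 1e-6
  num <- (aconc(x + eps, 1.3, -0.2, 0.8) - aconc(x - eps, 1.3, -0.2, 0.8)) / (2 * eps)
  expect_equal(hetdti:::aconc_grad(x, 1.3, -0.2, 0.8), num, tolerance = 1e-6)
})

test_that("softmax of a singleton neighborhood gives weight one", {
  params <- attention_params(d_in = 4, d_out = 4, K = 1, seed = 2)
  x <- matrix(rnorm(12), 3, 4)
  nb <- matrix(0, 3, 3); nb[1, 2] <- 1
  res <- node_level_attention(x, x, nb, params)
  expect_equal(res$attention[[1]][1, 2], 1)
})

test_that("identical neighbors share attention equally", {
  params <- attention_params(d_in = 4, d_out = 4, K = 2, seed = 3)
  x <- matrix(rnorm(16), 4, 4)
  x[3, ] <- x[2, ]  # two identical neighbor embeddings
  nb <- matrix(0, 4, 4); nb[1, 2] <- 1; nb[1, 3] <- 1
  res <- node_level_attention(x, x, nb, params)
  for (k in 1:2) {
    expect_equal(res$attention[[k]][1, 2], 0.5, tolerance = 1e-12)
    expect_equal(res$attention[[k]][1, 3], 0.5, tolerance = 1e-12)
  }
})

# direct double-loop implementation of the aggregation equations
han_bruteforce <- function(x_src, x_tgt, nb, params) {
  n_tgt <- nrow(x_tgt)
  agg <- matrix(0, n_tgt, params$d_out)
  for (v in seq_len(n_tgt)) {
    nbr <- which(nb[v, ] == 1)
    acc <- rep(0, params$d_out)
    for (k in seq_len(params$K)) {
      W <- params$W[[k]]; a <- params$a[[k]]
      if (length(nbr) == 0) {
        acc <- acc + drop(x_tgt[v, ] %*% W)
        next
      }
      e <- vapply(nbr, function(u) {
        aconc(sum(a * c(x_src[u, ] %*% W, x_tgt[v, ] %*% W)),
              params$p1, params$p2, params$beta)
      }, numeric(1))
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      for (ii in seq_along(nbr)) {
        acc <- acc + alpha[ii] * drop(x_src[nbr[ii], ] %*% W)
      }
    }
    agg[v, ] <- acc / params$K
  }
  hetdti:::elu(agg)
}

test_that("node-level attention matches the double-loop oracle", {
  for (trial in 1:100) {
    set.seed(trial)
    n_src <- sample(2:8, 1); n_tgt <- sample(2:8, 1)
    d_in <- sample(2:5, 1); d_out <- sample(2:5, 1)
    K <- sample(1:3, 1)
    params <- attention_params(d_in, d_out, K = K, seed = trial,
                               p1 = runif(1, 0.5, 1.5), p2 = runif(1, -0.5, 0.5),
                               beta = runif(1, 0.2, 2))
    x_src <- matrix(rnorm(n_src * d_in), n_src, d_in)
    x_tgt <- matrix(rnorm(n_tgt * d_in), n_tgt, d_in)
    nb <- matrix(rbinom(n_tgt * n_src, 1, 0.4), n_tgt, n_src)
    res <- node_level_attention(x_src, x_tgt, nb, params)
    expect_equal(res$embeddings, han_bruteforce(x_src, x_tgt, nb, params),
                 tolerance = 1e-10, info = paste("trial", trial))
  }
})

test_that("attention over each nonempty neighborhood sums to one", {
  for (seed in 1:5) {
    set.seed(seed)
    params <- attention_params(6, 4, K = 2, seed = seed)
    x <- matrix(rnorm(60), 10, 6)
    nb <- matrix(rbinom(100, 1, 0.3), 10, 10)
    res <- node_level_attention(x, x, nb, params)
    for (k in 1:2) {
      rs <- rowSums(res$attention[[k]])
      nonempty <- rowSums(nb) > 0
      expect_equal(rs[nonempty], rep(1, sum(nonempty)))
      expect_equal(rs[!nonempty], rep(0, sum(!nonempty)))
    }
  }
})

test_that("neighbor enumeration order does not change the embeddings", {
  set.seed(11)
  params <- attention_params(5, 5, K = 2, seed = 11)
  x_src <- matrix(rnorm(40), 8, 5)
  x_tgt <- matrix(rnorm(20), 4, 5)
  nb <- matrix(rbinom(32, 1, 0.5), 4, 8)
  base <- node_level_attention(x_src, x_tgt, nb, params)$embeddings
  perm <- sample(8)
  shuffled <- node_level_attention(x_src[perm, ], x_tgt, nb[, perm], params)$embeddings
  expect_equal(shuffled, base, tolerance = 1e-12)
})

test_that("embeddings are local: non-neighbors cannot influence a node", {
  set.seed(12)
  params <- attention_params(5, 5, K = 1, seed = 12)
  x <- matrix(rnorm(30), 6, 5)
  nb <- matrix(0, 6, 6)
  nb[1, c(2, 3)] <- 1
  base <- node_level_attention(x, x, nb, params)$embeddings
  x2 <- x
  x2[5, ] <- rnorm(5) * 10  # node 5 is outside N(1)
  after <- node_level_attention(x2, x, nb, params)$embeddings
  expect_equal(after[1, ], base[1, ], tolerance = 1e-12)
})

test_that("empty neighborhoods fall back to the node's own transform", {
  params <- attention_params(4, 3, K = 2, seed = 13)
  x <- matrix(rnorm(20), 5, 4)
  nb <- matrix(0, 5, 5)
  res <- node_level_attention(x, x, nb, params)
  own <- hetdti:::elu((x %*% params$W[[1]] + x %*% params$W[[2]]) / 2)
  expect_equal(res$embeddings, own, tolerance = 1e-12)
})

test_that("attention rejects mismatched shapes", {
  params <- attention_params(4, 4, seed = 1)
  expect_error(node_level_attention(matrix(0, 3, 5), matrix(0, 3, 5),
                                    matrix(0, 3, 3), params), "width")
  expect_error(node_level_attention(matrix(0, 3, 4), matrix(0, 3, 4),
                                    matrix(0, 2, 2), params), "n_tgt x n_src")
})

test_that("semantic attention: singleton and symmetric cases", {
  sp <- semantic_params(d = 6, seed = 4)
  z1 <- matrix(rnorm(30), 5, 6)
  res1 <- semantic_attention(list(only = z1), sp)
  expect_equal(unname(res1$weights), 1)
  expect_equal(res1$embeddings, z1)

  res2 <- semantic_attention(list(a = z1, b = z1), sp)
  expect_equal(unname(res2$weights), c(0.5, 0.5))
  expect_equal(res2$embeddings, z1, tolerance = 1e-12)
})

test_that("semantic attention matches a per-node loop oracle", {
  set.seed(6)
  sp <- semantic_params(d = 5, d_att = 3, seed = 6)
  tables <- list(p1 = matrix(rnorm(40), 8, 5), p2 = matrix(rnorm(40), 8, 5))
  res <- semantic_attention(tables, sp)
  w <- vapply(tables, function(Z) {
    scores <- vapply(1:8, function(v) {
      sum(sp$q * tanh(drop(Z[v, ] %*% sp$W_s) + sp$b_s))
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  beta <- exp(w) / sum(exp(w))
  expect_equal(unname(res$weights), unname(beta), tolerance = 1e-12)
  expect_equal(res$embeddings, beta[1] * tables$p1 + beta[2] * tables$p2,
               tolerance = 1e-12)
  expect_error(
    semantic_attention(list(a = matrix(0, 3, 5), b = matrix(0, 4, 5)), sp),
    "node set")
})

test_that("attention weights export as ranked TSV", {
  params <- attention_params(3, 3, K = 1, seed = 7)
  x <- matrix(rnorm(12), 4, 3)
  nb <- matrix(rbinom(16, 1, 0.6), 4, 4)
  res <- node_level_attention(x, x, nb, params)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attention_weights(res$attention, path, node_ids = paste0("n", 1:4),
                          neighbor_ids = paste0("n", 1:4))
  df <- read.delim(path)
  expect_equal(names(df), c("node", "neighbor", "weight"))
  expect_equal(nrow(df), sum(res$attention[[1]] > 0))
})
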