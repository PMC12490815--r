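# Seeded generators for synthetic study inputs: a heterogeneous network with
# planted low-rank drug-protein interaction structure, small valid SMILES
# strings, and random amino-acid sequences. The planted latent factors are
# returned so recovery tests can compare against ground truth; the
# feature_coupling knob ties the generated SMILES/sequences to the same
# factors so that the feature views carry learnable signal.

CURATED_SMILES <- c(
  "CCO", "CC(=O)OC1=CC=CC=C1C(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O", "C1=CC=CC=C1", "CC(=O)NC1=CC=C(O)C=C1",
  "C1CCCCC1", "CCN(CC)CC", "CC(N)C(=O)O", "C1=CC=C2C=CC=CC2=C1",
  "CCOC(=O)C", "OCC(O)CO", "CCCCCCCCO", "CC1=CC=CC=C1", "ClC1=CC=CC=C1",
  "NC1=CC=CC=C1", "OC1=CC=CC=C1", "CC(C)O", "CSC", "CCCCC(C)CC"
)

#' Specification of a synthetic study bundle
#'
#' @param n_drug,n_protein,n_disease,n_side_effect node counts (defaults:
#'   100 drugs, 150 proteins, 30 diseases, 30 side effects).
#' @param latent_rank rank of the planted interaction factors (default 4;
#'   must not exceed `min(n_drug, n_protein)`).
#' @param densities named list of edge densities in (0, 1) per edge type.
#' @param feature_coupling strength in [0, 1] linking the planted factors to
#'   the generated drug/protein features (default 0.8; 0 makes the feature
#'   views pure noise).
#' @param length_range protein sequence length range.
#' @param seed RNG seed; every generator output is a pure function of it.
#' @export
synthetic_spec <- function(n_drug = 100, n_protein = 150, n_disease = 30,
                           n_side_effect = 30, latent_rank = 4,
                           densities = list(), feature_coupling = 0.8,
                           length_range = c(60, 180), seed = 1) {
  counts <- c(n_drug, n_protein, n_disease, n_side_effect)
  if (any(counts < 1)) stopf("all node counts must be >= 1")
  if (latent_rank > min(n_drug, n_protein)) {
    stopf("latent_rank %d exceeds min(n_drug, n_protein) = %d",
          latent_rank, min(n_drug, n_protein))
  }
  dens <- utils::modifyList(list(
    drug_protein = 0.04, drug_drug = 0.05, protein_protein = 0.05,
    drug_disease = 0.05, protein_disease = 0.05, drug_side_effect = 0.05
  ), densities)
  if (any(unlist(dens) <= 0) || any(unlist(dens) >= 1)) {
    stopf("all densities must lie in (0, 1)")
  }
  structure(list(n_drug = n_drug, n_protein = n_protein, n_disease = n_disease,
                 n_side_effect = n_side_effect, latent_rank = latent_rank,
                 densities = dens, feature_coupling = feature_coupling,
                 length_range = length_range, seed = seed),
            class = "synthetic_spec")
}

# Threshold a score matrix at the quantile giving the requested density.
threshold_density <- function(score, density) {
  thr <- stats::quantile(score, 1 - density, names = FALSE)
  (score > thr) + 0
}

# Symmetric within-type adjacency from a symmetric score matrix.
threshold_density_sym <- function(score, density) {
  ut <- upper.tri(score)
  thr <- stats::quantile(score[ut], 1 - density, names = FALSE)
  a <- matrix(0, nrow(score), ncol(score))
  a[ut] <- (score[ut] > thr) + 0
  a + t(a)
}

#' Generate a heterogeneous network with planted interaction structure
#'
#' Drug and protein nodes carry rank-r Gaussian latent factors U, V;
#' drug-protein edges are the top `density` fraction of the latent scores
#' `U V' / sqrt(r)`. Auxiliary edge types mix the corresponding factor
#' products with Gaussian noise at `feature_coupling`, so meta-paths carry
#' signal about the planted interactions (and degrade to noise at coupling
#' zero). Fully deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a [hetero_network()]) and `factors`
#'   (`U`, `V`, `W_disease`, `W_side_effect`).
#' @export
generate_hetnet <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  r <- spec$latent_rank
  cpl <- spec$feature_coupling
  with_seed(derive_seed(spec$seed, "hetnet"), {
    U <- matrix(stats::rnorm(spec$n_drug * r), spec$n_drug, r)
    V <- matrix(stats::rnorm(spec$n_protein * r), spec$n_protein, r)
    Wd <- matrix(stats::rnorm(spec$n_disease * r), spec$n_disease, r)
    Ws <- matrix(stats::rnorm(spec$n_side_effect * r), spec$n_side_effect, r)
    noise <- function(n1, n2) matrix(stats::rnorm(n1 * n2), n1, n2)
    sym_noise <- function(n) { z <- noise(n, n); (z + t(z)) / sqrt(2) }
    scale_fac <- function(m) m / stats::sd(m)
    mix <- function(signal, nz) cpl * scale_fac(signal) + (1 - cpl) * nz

    s_dp <- U %*% t(V) / sqrt(r)
    a_dp <- threshold_density(s_dp, spec$densities$drug_protein)
    a_dd <- threshold_density_sym(mix(U %*% t(U) / sqrt(r), sym_noise(spec$n_drug)),
                                  spec$densities$drug_drug)
    a_pp <- threshold_density_sym(mix(V %*% t(V) / sqrt(r), sym_noise(spec$n_protein)),
                                  spec$densities$protein_protein)
    a_ddis <- threshold_density(mix(U %*% t(Wd) / sqrt(r), noise(spec$n_drug, spec$n_disease)),
                                spec$densities$drug_disease)
    a_pdis <- threshold_density(mix(V %*% t(Wd) / sqrt(r), noise(spec$n_protein, spec$n_disease)),
                                spec$densities$protein_disease)
    a_dse <- threshold_density(mix(U %*% t(Ws) / sqrt(r), noise(spec$n_drug, spec$n_side_effect)),
                               spec$densities$drug_side_effect)

    ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
    net <- hetero_network(
      nodes = list(drug = ids("D", spec$n_drug), protein = ids("P", spec$n_protein),
                   disease = ids("DIS", spec$n_disease),
                   side_effect = ids("SE", spec$n_side_effect)),
      adjacency = list(drug_protein = a_dp, drug_drug = a_dd,
                       protein_protein = a_pp, drug_disease = a_ddis,
                       protein_disease = a_pdis, drug_side_effect = a_dse)
    )
    list(network = net,
         factors = list(U = U, V = V, W_disease = Wd, W_side_effect = Ws,
                        score = s_dp))
  })
}

# Random linear/branched alkane-ether SMILES of up to max_atoms heavy atoms;
# always valid (oxygens placed only in-chain after a carbon).
random_chain_smiles <- function(max_atoms) {
  n <- sample(3:max(3, max_atoms), 1)
  out <- "C"; used <- 1; prev_c <- TRUE
  while (used < n) {
    u <- stats::runif(1)
    if (prev_c && u < 0.15 && used + 1 < n) {
      out <- paste0(out, "(C)"); used <- used + 1; prev_c <- TRUE
    } else if (prev_c && u < 0.30) {
      out <- paste0(out, "O"); used <- used + 1; prev_c <- FALSE
    } else {
      out <- paste0(out, "C"); used <- used + 1; prev_c <- TRUE
    }
  }
  if (!prev_c) out <- paste0(out, "C")  # never end on an ether oxygen dangling rule-free
  out
}

#' Generate valid small-molecule SMILES
#'
#' Draws from a curated list of common small molecules plus random
#' linear/branched alkane-ether chains; every output parses under
#' [smiles_to_graph()]. Deterministic given seed.
#'
#' @param n number of SMILES.
#' @param max_atoms heavy-atom cap for the random chains (default 20).
#' @param seed RNG seed.
#' @export
generate_smiles <- function(n, max_atoms = 20, seed = 1) {
  if (n == 0) return(character(0))
  with_seed(derive_seed(seed, "smiles"), {
    vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.5) sample(CURATED_SMILES, 1)
      else random_chain_smiles(max_atoms)
    }, character(1))
  })
}

#' Generate random protein sequences
#'
#' Uniform sequences over the 20 standard amino acids with occasional
#' B/O/U/Z insertions (rate 1%) to exercise sanitization; lengths uniform in
#' `length_range`. Deterministic given seed.
#'
#' @param n number of sequences.
#' @param length_range integer pair (min, max).
#' @param seed RNG seed.
#' @return character vector of raw (unsanitized) sequences.
#' @export
generate_proteins <- function(n, length_range = c(60, 180), seed = 1) {
  if (n == 0) return(character(0))
  aa20 <- setdiff(AA_ALPHABET, "X")
  rare <- c("B", "O", "U", "Z")
  with_seed(derive_seed(seed, "proteins"), {
    vapply(seq_len(n), function(i) {
      len <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1, 1) - 1
      chars <- sample(aa20, len, replace = TRUE)
      swap <- stats::runif(len) < 0.01
      chars[swap] <- sample(rare, sum(swap), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
  })
}

mutate_sequence <- function(seq, rate, aa20) {
  chars <- strsplit(seq, "")[[1]]
  swap <- stats::runif(length(chars)) < rate
  if (any(swap)) chars[swap] <- sample(aa20, sum(swap), replace = TRUE)
  paste(chars, collapse = "")
}

#' Simulate a full study bundle
#'
#' Generates the heterogeneous network plus coupled drug SMILES and protein
#' sequences. Feature coupling works through latent-factor prototypes: drugs
#' (proteins) are clustered on their planted factors, each cluster shares a
#' prototype SMILES (sequence), and a drug keeps its prototype with
#' probability `feature_coupling` (sequences are point-mutated at rate
#' `1 - feature_coupling`), so latent-similar entities receive similar
#' features. At coupling zero the features are independent noise.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network`, `factors`, `smiles` (named by drug id),
#'   `sequences` (named raw strings by protein id), and `spec`.
#' @export
simulate_bundle <- function(spec = synthetic_spec()) {
  gen <- generate_hetnet(spec)
  net <- gen$network
  aa20 <- setdiff(AA_ALPHABET, "X")
  with_seed(derive_seed(spec$seed, "features"), {
    m_d <- min(8L, spec$n_drug)
    m_p <- min(8L, spec$n_protein)
    drug_proto <- sample(CURATED_SMILES, m_d)
    drug_cl <- if (spec$n_drug > m_d) {
      stats::kmeans(gen$factors$U, centers = m_d, nstart = 3)$cluster
    } else seq_len(spec$n_drug)
    rand_pool <- vapply(seq_len(spec$n_drug), function(i) random_chain_smiles(20),
                        character(1))
    keep_proto <- stats::runif(spec$n_drug) < spec$feature_coupling
    smiles <- ifelse(keep_proto, drug_proto[drug_cl], rand_pool)
    names(smiles) <- net$nodes$drug

    proto_len <- round(mean(spec$length_range))
    prot_proto <- vapply(seq_len(m_p), function(i) {
      paste(sample(aa20, proto_len, replace = TRUE), collapse = "")
    }, character(1))
    prot_cl <- if (spec$n_protein > m_p) {
      stats::kmeans(gen$factors$V, centers = m_p, nstart = 3)$cluster
    } else seq_len(spec$n_protein)
    sequences <- vapply(seq_len(spec$n_protein), function(i) {
      mutate_sequence(prot_proto[prot_cl[i]], 1 - spec$feature_coupling, aa20)
    }, character(1))
    names(sequences) <- net$nodes$protein

    list(network = net, factors = gen$factors, smiles = smiles,
         sequences = sequences, spec = spec)
  })
}

#' Write / read a study bundle on disk
#'
#' Writes the plain-matrix network dialect, a `drugs.tsv` SMILES table, a
#' `proteins.fasta` file and a JSON manifest into a directory.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param directory target directory.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_dtinet_matrices(bundle$network, directory)
  utils::write.table(
    data.frame(drug_id = names(bundle$smiles), smiles = unname(bundle$smiles)),
    file.path(directory, "drugs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(
    as.vector(rbind(paste0(">", names(bundle$sequences)), unname(bundle$sequences))),
    file.path(directory, "proteins.fasta"))
  manifest <- unclass(bundle$spec)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(directory)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory) {
  network <- suppressMessages(load_dtinet_matrices(directory))
  drugs <- utils::read.delim(file.path(directory, "drugs.tsv"),
                             stringsAsFactors = FALSE)
  smiles <- stats::setNames(drugs$smiles, drugs$drug_id)
  seqs <- read_fasta_sequences(file.path(directory, "proteins.fasta"))
  sequences <- stats::setNames(vapply(seqs, `[[`, character(1), "residues"),
                               names(seqs))
  manifest_path <- file.path(directory, "manifest.json")
  spec <- if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    synthetic_spec(m$n_drug, m$n_protein, m$n_disease, m$n_side_effect,
                   m$latent_rank, as.list(m$densities), m$feature_coupling,
                   m$length_range, m$seed)
  } else NULL
  list(network = network, smiles = smiles, sequences = sequences, spec = spec)
}
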