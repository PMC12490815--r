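# Protein sequence view: sanitization to the 20-letter alphabet plus X,
# per-residue embedding through a pluggable encoder, and mean pooling to the
# sequence-level vector S_protein.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases, maps each of the ambiguous/rare letters B, O, U, Z to the
#' universal token X, and rejects any character outside the 20 standard
#' amino acids plus X. Length is preserved. Idempotent.
#'
#' @param raw a nonempty sequence string.
#' @param protein_id optional identifier attached to the result.
#' @return object of class `protein_sequence` with fields `protein_id`,
#'   `residues`, `length`.
#' @export
sanitize_sequence <- function(raw, protein_id = NULL) {
  if (!is.character(raw) || length(raw) != 1) stopf("sequence must be a single string")
  s <- toupper(trimws(raw))
  if (!nzchar(s)) stopf("empty protein sequence")
  s <- chartr("BOUZ", "XXXX", s)
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stopf("sequence contains characters outside the amino-acid alphabet: %s",
          paste(bad, collapse = ", "))
  }
  structure(list(protein_id = protein_id, residues = s, length = nchar(s)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n",
              if (is.null(x$protein_id)) "?" else x$protein_id, x$length))
  invisible(x)
}

#' Deterministic hashed k-mer residue encoder
#'
#' The built-in fallback encoder: the k-mer starting at each residue (padded
#' with X past the sequence end) is hashed into one of `n_buckets` buckets,
#' and each bucket carries a fixed row of a seeded Gaussian projection matrix
#' of width `d_h`. Deterministic given `(sequence, seed)`; requires no
#' external model weights. An external protein language model can be plugged
#' in by defining an `embed_sequence` method for its own encoder class
#' honouring the same one-row-per-residue contract.
#'
#' @param d_h embedding width (default 1024, the relational-view input size).
#' @param n_buckets number of hash buckets.
#' @param k k-mer length (default 3).
#' @param seed RNG seed for the projection draw.
#' @export
kmer_encoder <- function(d_h = 1024, n_buckets = 512, k = 3, seed = 1) {
  with_seed(derive_seed(seed, "kmer"), {
    P <- matrix(stats::rnorm(n_buckets * d_h, sd = 1), n_buckets, d_h)
  })
  structure(list(projection = P, d_h = d_h, n_buckets = n_buckets, k = k,
                 seed = seed, encoder_tag = "fallback"),
            class = "kmer_encoder")
}

# Hash the k-mer starting at each position: base-21 code of the residue
# indices, modulo the bucket count.
kmer_buckets <- function(residues, k, n_buckets) {
  idx <- match(strsplit(residues, "")[[1]], AA_ALPHABET) - 1L
  n <- length(idx)
  pad_x <- match("X", AA_ALPHABET) - 1L
  idx_pad <- c(idx, rep(pad_x, k - 1))
  code <- numeric(n)
  for (j in seq_len(k)) {
    code <- code * 21 + idx_pad[seq_len(n) + (j - 1)]
  }
  as.integer(code %% n_buckets) + 1L
}

#' Embed a protein sequence into per-residue vectors
#'
#' @param sequence a [sanitize_sequence()] result (raw strings are sanitized
#'   on the fly).
#' @param encoder an encoder object, e.g. [kmer_encoder()].
#' @return object of class `residue_embedding` with fields `hidden`
#'   (n x d_h matrix) and `encoder_tag`.
#' @export
embed_sequence <- function(sequence, encoder) UseMethod("embed_sequence", encoder)

#' @export
embed_sequence.kmer_encoder <- function(sequence, encoder) {
  if (!inherits(sequence, "protein_sequence")) sequence <- sanitize_sequence(sequence)
  b <- kmer_buckets(sequence$residues, encoder$k, encoder$n_buckets)
  H <- encoder$projection[b, , drop = FALSE]
  rownames(H) <- NULL
  structure(list(hidden = H, encoder_tag = encoder$encoder_tag,
                 protein_id = sequence$protein_id),
            class = "residue_embedding")
}

#' Pool per-residue embeddings into the protein vector S_protein
#'
#' The exact arithmetic mean of the hidden rows over all residues.
#' @param embedding a `residue_embedding` (or a plain n x d matrix).
#' @return numeric vector of width d_h.
#' @export
pool_protein <- function(embedding) {
  H <- if (inherits(embedding, "residue_embedding")) embedding$hidden else as.matrix(embedding)
  if (nrow(H) == 0) stopf("cannot pool an empty embedding")
  colMeans(H)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are sanitized on read.
#' @param path FASTA file path.
#' @return named list of `protein_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  out <- lapply(seq_along(aa), function(i) {
    sanitize_sequence(as.character(aa[[i]]), protein_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Encode a table of proteins
#'
#' @param sequences named list of `protein_sequence` objects or named
#'   character vector of raw sequences.
#' @param encoder an encoder, e.g. [kmer_encoder()].
#' @return matrix (n_proteins x d_h) with protein ids as rownames.
#' @export
encode_protein_table <- function(sequences, encoder) {
  if (is.character(sequences)) {
    sequences <- mapply(sanitize_sequence, sequences, names(sequences),
                        SIMPLIFY = FALSE)
  }
  out <- t(vapply(sequences, function(s) {
    pool_protein(embed_sequence(s, encoder))
  }, numeric(encoder$d_h)))
  rownames(out) <- names(sequences)
  out
}
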