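# Redundancy-removal robustness filter: drops drug-target interactions that
# are "easy" because a near-duplicate entity exists, so a model can be
# re-evaluated on the de-redundified network. Similarity is Jaccard over
# binary profiles with a configurable threshold (the removed categories are
# standard; this particular similarity computation is the package's choice
# and is deliberately simple and transparent).

jaccard_rows <- function(m) {
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, `+`) - inter
  j <- inter / uni
  j[uni == 0] <- 0
  list(jaccard = j, intersection = inter)
}

#' Filter redundant drug-target interactions
#'
#' With `mode = "similar_drug_target"`, any pair of drugs (or of targets)
#' whose binary interaction profiles have Jaccard similarity at or above
#' `threshold` (and at least one shared interaction) has its shared DTIs
#' flagged and removed. With `mode = "similar_side_effect"`, drug pairs are
#' compared on their side-effect profiles instead, and the shared DTIs of
#' flagged pairs are removed.
#'
#' @param network a [hetero_network()].
#' @param mode `"similar_drug_target"` or `"similar_side_effect"`.
#' @param threshold Jaccard similarity cutoff in (0, 1].
#' @return list with `network` (filtered copy), and `report` containing the
#'   removed pair coordinates and the counts of distinct drugs, targets, and
#'   DTIs involved.
#' @export
redundancy_filter <- function(network, mode = c("similar_drug_target",
                                                "similar_side_effect"),
                              threshold = 0.9) {
  mode <- tryCatch(match.arg(mode), error = function(e) {
    stopf("unknown redundancy filter mode '%s'", mode[1])
  })
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  dp <- network$adjacency$drug_protein
  flag <- matrix(FALSE, nrow(dp), ncol(dp))

  flag_pairs <- function(sim_profiles, flag) {
    js <- jaccard_rows(sim_profiles)
    n <- nrow(sim_profiles)
    for (i in seq_len(max(0, n - 1))) {
      for (j in seq(i + 1, n)) {
        if (js$jaccard[i, j] >= threshold && js$intersection[i, j] > 0) {
          shared <- dp[i, ] == 1 & dp[j, ] == 1
          if (any(shared)) {
            flag[i, shared] <- TRUE
            flag[j, shared] <- TRUE
          }
        }
      }
    }
    flag
  }
  flag_target_pairs <- function(flag) {
    js <- jaccard_rows(t(dp))
    n <- ncol(dp)
    for (i in seq_len(max(0, n - 1))) {
      for (j in seq(i + 1, n)) {
        if (js$jaccard[i, j] >= threshold && js$intersection[i, j] > 0) {
          shared <- dp[, i] == 1 & dp[, j] == 1
          if (any(shared)) {
            flag[shared, i] <- TRUE
            flag[shared, j] <- TRUE
          }
        }
      }
    }
    flag
  }

  if (mode == "similar_drug_target") {
    flag <- flag_pairs(dp, flag)
    flag <- flag_target_pairs(flag)
  } else {
    flag <- flag_pairs(network$adjacency$drug_side_effect, flag)
  }

  removed <- which(flag & dp == 1, arr.ind = TRUE)
  dp[flag] <- 0
  network$adjacency$drug_protein <- dp
  report <- list(
    mode = mode, threshold = threshold,
    removed_pairs = data.frame(
      drug_id = network$nodes$drug[removed[, 1]],
      protein_id = network$nodes$protein[removed[, 2]]
    ),
    n_drugs = length(unique(removed[, 1])),
    n_targets = length(unique(removed[, 2])),
    n_dtis = nrow(removed)
  )
  list(network = network, report = report)
}
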