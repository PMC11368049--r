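# Molecular pairing: cross-merged difference-labeled training pairs and
# anchor-vs-candidate prediction pairs. Pair direction is fixed everywhere as
# (first = reference, second = candidate) with delta = potency(second) -
# potency(first), so a positive predicted delta means "candidate improves on
# the reference".

#' Cross-merge a training set into difference-labeled pairs
#'
#' Forms all ordered pairs of training molecules (including self-pairs by
#' default), each labeled with the potency difference second minus first.
#' An n-molecule set expands to n^2 training examples — the combinatorial
#' expansion that lets pair models train on very small datasets. Because the
#' label is a difference, any constant shift of all potencies (a systematic
#' assay offset) cancels exactly.
#'
#' @param train A non-empty [compound_dataset()].
#' @param include_self Include the n zero-delta self-pairs (default TRUE)?
#' @return A \code{pair_set} data.frame with columns \code{first_id,
#'   second_id, first_smiles, second_smiles, delta}, in row-major training
#'   order.
#' @export
cross_merge <- function(train, include_self = TRUE) {
  n <- nrow(train)
  if (n == 0) stop_contract("cannot cross-merge an empty training set")
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  if (!include_self) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]
  }
  structure(data.frame(
    first_id = train$id[i], second_id = train$id[j],
    first_smiles = train$smiles[i], second_smiles = train$smiles[j],
    delta = train$potency[j] - train$potency[i],
    stringsAsFactors = FALSE
  ), class = c("pair_set", "data.frame"), labeled = TRUE)
}

#' Pair the anchor against every pool candidate
#'
#' Builds the prediction-time inputs of the ActiveDelta policy: the current
#' best training compound (the anchor) as \code{first}, each learning-pool
#' molecule as \code{second}, in pool order. No delta labels are attached —
#' pool potencies stay hidden from the policy.
#'
#' @param anchor A single-row record (id, smiles) — see [best_in_train()].
#' @param pool A non-empty [compound_dataset()].
#' @return An unlabeled \code{pair_set} with \code{nrow(pool)} rows.
#' @export
anchor_pairs <- function(anchor, pool) {
  if (nrow(pool) == 0) stop_contract("empty learning pool")
  structure(data.frame(
    first_id = rep(anchor$id[1], nrow(pool)), second_id = pool$id,
    first_smiles = rep(anchor$smiles[1], nrow(pool)),
    second_smiles = pool$smiles,
    delta = NA_real_, stringsAsFactors = FALSE
  ), class = c("pair_set", "data.frame"), labeled = FALSE)
}

#' The most potent compound in a training set
#'
#' Argmax of potency; ties broken by earliest position so the anchor is
#' deterministic.
#'
#' @param train A non-empty [compound_dataset()].
#' @return The single-row record of the best compound.
#' @export
best_in_train <- function(train) {
  if (nrow(train) == 0) stop_contract("empty training set")
  .as_cds(train[which.max(train$potency), , drop = FALSE], train)
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set: %d %s pairs>\n", nrow(x),
              if (isTRUE(attr(x, "labeled"))) "labeled" else "prediction"))
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# Concatenated fingerprints (first then second) for paired models.
pair_features <- function(pairs, kind = "morgan_r2_2048") {
  cbind(fingerprint_matrix(pairs$first_smiles, kind),
        fingerprint_matrix(pairs$second_smiles, kind))
}
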