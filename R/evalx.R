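# Evaluation suite: top-decile hit retrieval, scaffold diversity,
# nearest-neighbor similarity windows, chemical-space embedding with
# jump/stay trajectory counts, and Wilcoxon signed-rank strategy comparison.

#' Top ten percentile most potent compounds
#'
#' The hit set of a reference dataset: the \code{ceil(0.1 N)} molecules with
#' the highest potency. Ties at the threshold break by earliest dataset
#' position so the set size is exact.
#'
#' @param ds A [compound_dataset()] with at least 10 molecules.
#' @return A \code{hit_set}: list with \code{records} (the hit rows),
#'   \code{ids} and \code{threshold} (lowest potency inside the set).
#' @export
top_decile <- function(ds) {
  n <- nrow(ds)
  if (n < 10) stop_contract("top decile needs at least 10 molecules")
  k <- ceiling(0.1 * n)
  ord <- order(-ds$potency, seq_len(n))
  take <- ord[seq_len(k)]
  structure(list(records = as.data.frame(ds[take, , drop = FALSE]),
                 ids = ds$id[take],
                 threshold = min(ds$potency[take])),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set: %d hits, potency >= %.3f>\n", length(x$ids),
              x$threshold))
  invisible(x)
}

#' Hit-retrieval curve of a trajectory
#'
#' Fraction of the hit set held at each iteration t = 0..T; the cold-start
#' molecules count at t = 0. Nondecreasing, in \[0, 1\], and 1 once the pool
#' is exhausted.
#'
#' @param trajectory An \code{al_trajectory}.
#' @param hits A \code{hit_set} from [top_decile()] on the reference
#'   (original training) dataset.
#' @return A \code{retrieval_curve}: numeric vector of length T+1 named by
#'   iteration.
#' @export
retrieval_curve <- function(trajectory, hits) {
  cs_ids <- attr(trajectory, "cold_start")$id
  H <- length(hits$ids)
  acquired_hit <- trajectory$id %in% hits$ids
  curve <- (sum(cs_ids %in% hits$ids) + cumsum(c(0, acquired_hit))) / H
  names(curve) <- 0:nrow(trajectory)
  structure(curve, class = c("retrieval_curve", class(curve)))
}

#' Scaffold diversity of a selection
#'
#' Number of unique Bemis-Murcko scaffolds among the selected molecules.
#' With a hit set given, the count is restricted to selected hits and the
#' fraction is relative to the unique scaffolds among ALL hits. Acyclic
#' molecules (empty scaffold) count as one shared scaffold class.
#'
#' @param selected A data.frame / [compound_dataset()] of selected molecules
#'   (needs \code{id} and \code{smiles}).
#' @param hits Optional \code{hit_set}.
#' @return \code{list(count=, fraction=)}; \code{fraction} is \code{NA}
#'   without a hit set.
#' @export
scaffold_diversity <- function(selected, hits = NULL) {
  scaff <- function(df) {
    if (nrow(df) == 0) return(character(0))
    s <- vapply(df$smiles, murcko_scaffold, character(1), USE.NAMES = FALSE)
    s[!nzchar(s)] <- "(acyclic)"
    s
  }
  sel <- as.data.frame(selected)
  if (is.null(hits)) {
    return(list(count = length(unique(scaff(sel))), fraction = NA_real_))
  }
  sel_hits <- sel[sel$id %in% hits$ids, , drop = FALSE]
  count <- length(unique(scaff(sel_hits)))
  total <- length(unique(scaff(hits$records)))
  list(count = count, fraction = if (total > 0) count / total else NA_real_)
}

#' Mean nearest-neighbor similarity of acquisitions over iteration windows
#'
#' For each acquired molecule, the Tanimoto similarity to its nearest
#' neighbor in the training set as it stood at acquisition time (before the
#' acquisition joined it), averaged over iteration windows — the standard
#' windows are iterations 1-15, 16-30 and 31-45 — for one or more
#' fingerprint kinds. Values near 1 indicate analog-hopping; low values
#' indicate jumps into new chemistry.
#'
#' @param trajectory An \code{al_trajectory} covering the windows.
#' @param windows List of integer iteration vectors.
#' @param kinds Fingerprint kinds (see [fingerprint()]).
#' @return A data.frame with columns \code{window, kind, mean_similarity}.
#' @export
similarity_windows <- function(trajectory,
                               windows = list(`1-15` = 1:15,
                                              `16-30` = 16:30,
                                              `31-45` = 31:45),
                               kinds = c("morgan_r2_2048", "maccs",
                                         "atom_pair")) {
  maxit <- max(unlist(windows))
  if (maxit > nrow(trajectory)) {
    stop_contract("window extends beyond trajectory (", nrow(trajectory),
                  " iterations)")
  }
  cs <- attr(trajectory, "cold_start")
  traj <- as.data.frame(trajectory)
  train_smiles_at <- function(t) c(cs$smiles, traj$smiles[seq_len(t - 1)])
  sims <- lapply(kinds, function(kind) {
    vapply(seq_len(maxit), function(t) {
      ref <- data.frame(smiles = train_smiles_at(t))
      nearest_neighbor_similarity(traj$smiles[t], ref, kind = kind)
    }, numeric(1))
  })
  names(sims) <- kinds
  out <- expand.grid(window = names(windows), kind = kinds,
                     stringsAsFactors = FALSE)
  out$mean_similarity <- mapply(function(w, k) mean(sims[[k]][windows[[w]]]),
                                out$window, out$kind)
  out
}

#' Embed molecules into a 2-D chemical-space map
#'
#' Morgan fingerprints are reduced to 50 principal components, then to two
#' dimensions by t-SNE (the PCA stage is skipped, with a warning, for 50 or
#' fewer molecules). Deterministic given the seed; coordinates are for
#' qualitative trajectory analysis, not quantitative comparison.
#'
#' @param molecules A [compound_dataset()].
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (capped at (n-1)/3).
#' @param max_iter Gradient-descent iterations.
#' @return A \code{trajectory_embedding}: n x 2 coordinate matrix with
#'   rownames = molecule ids and the run parameters as attributes.
#' @export
embed_chemical_space <- function(molecules, seed = 1L, perplexity = 30,
                                 max_iter = 500) {
  X <- as.matrix(fingerprint_matrix(molecules$smiles))
  if (nrow(X) > 50) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    X <- pc$x[, seq_len(min(50L, ncol(pc$x))), drop = FALSE]
  } else {
    warning("50 or fewer molecules: skipping the PCA stage")
  }
  Y <- .tsne(X, seed = seed, perplexity = perplexity, max_iter = max_iter)
  rownames(Y) <- molecules$id
  structure(Y, params = list(seed = seed, perplexity = perplexity,
                             max_iter = max_iter, pca_dims = ncol(X)),
            class = c("trajectory_embedding", class(Y)))
}

#' Cluster a 2-D embedding by density connectivity
#'
#' Single-linkage grouping cut at a fixed fraction of the embedding's
#' diameter: points chained by steps shorter than the cut share a cluster.
#' The parameters are recorded so jump/stay counts are reproducible.
#'
#' @param embedding A \code{trajectory_embedding} (or n x 2 matrix with
#'   rownames).
#' @param cut_fraction Linkage cut as a fraction of the coordinate diameter.
#' @return Integer cluster labels named by molecule id.
#' @export
cluster_embedding <- function(embedding, cut_fraction = 0.08) {
  d <- stats::dist(unclass(embedding))
  h <- stats::hclust(d, method = "single")
  labels <- stats::cutree(h, h = cut_fraction * max(d))
  names(labels) <- rownames(embedding)
  labels
}

#' Count cluster jumps and stays along a trajectory window
#'
#' For consecutive acquisitions within the window: a transition into a
#' different cluster is a jump, one within the same cluster a stay; the two
#' always sum to the number of analyzed transitions (window length - 1).
#'
#' @param labels Named integer cluster labels (see [cluster_embedding()]);
#'   every acquired molecule in the window must be labeled.
#' @param trajectory An \code{al_trajectory}.
#' @param window Integer vector of consecutive iterations (default: all).
#' @return \code{list(jumps=, stays=)}.
#' @export
jump_stay <- function(labels, trajectory, window = seq_len(nrow(trajectory))) {
  ids <- as.data.frame(trajectory)$id[window]
  if (!all(ids %in% names(labels))) {
    stop_contract("unlabeled molecule in trajectory window")
  }
  seq_labels <- unname(labels[ids])
  jumps <- sum(diff(seq_labels) != 0)
  list(jumps = jumps, stays = length(seq_labels) - 1L - jumps)
}

#' Compare two strategies across datasets (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on per-dataset paired values (e.g.
#' hits retrieved at a fixed iteration by two policies). Zero differences
#' are dropped per the standard convention; an all-zero comparison is
#' degenerate and reported with p = 1. Alongside the test the mean, SD and
#' SE of the differences are reported (the convention for text and plots,
#' respectively).
#'
#' @param per_dataset_a,per_dataset_b Equal-length numeric vectors, paired
#'   by dataset.
#' @return A \code{strategy_comparison} list: \code{statistic} (signed-rank
#'   V), \code{p_value}, \code{mean_difference}, \code{sd_difference},
#'   \code{se_difference}, \code{n}, \code{n_nonzero}, \code{degenerate}.
#' @export
compare_strategies <- function(per_dataset_a, per_dataset_b) {
  if (length(per_dataset_a) != length(per_dataset_b)) {
    stop_contract("paired vectors must have equal length")
  }
  d <- per_dataset_a - per_dataset_b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    res <- list(statistic = 0, p_value = 1, degenerate = TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(nz, alternative = "two.sided"))
    res <- list(statistic = unname(wt$statistic),
                p_value = min(1, wt$p.value), degenerate = FALSE)
  }
  structure(c(res, list(
    mean_difference = mean(d), sd_difference = stats::sd(d),
    se_difference = stats::sd(d) / sqrt(length(d)),
    n = length(d), n_nonzero = length(nz))),
    class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: V = %g, p = %.3g%s\n", x$statistic, x$p_value,
    if (x$degenerate) " (degenerate: all differences zero)" else ""))
  cat(sprintf("mean difference %.4g +/- %.4g SD (SE %.4g, n = %d)\n",
              x$mean_difference, x$sd_difference, x$se_difference, x$n))
  invisible(x)
}
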