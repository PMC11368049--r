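# The exploitative active-learning loop. Starting from a random two-compound
# training set, each iteration refits the policy's regressor from scratch,
# scores the learning pool with labels hidden, acquires exactly one molecule
# (without replacement), reveals its true potency, and repeats.
#
# Policies:
#   activedelta    — paired model on the cross-merged training set; the
#                    current best training compound (anchor) is paired with
#                    every pool molecule and the candidate with the highest
#                    predicted improvement is acquired.
#   single_exploit — single-molecule model; the candidate with the highest
#                    predicted absolute potency is acquired.
#   random         — seeded uniform draw (screening baseline).

.POLICIES <- c("activedelta", "single_exploit", "random")

#' Configure an active-learning policy
#'
#' @param policy One of \code{"activedelta"}, \code{"single_exploit"},
#'   \code{"random"}.
#' @param regressor A [regressor_spec()]; its mode must match the policy
#'   (paired for activedelta, single otherwise). Ignored by \code{random}
#'   at acquisition time but still used by [evaluate_on_test()].
#' @param iterations Number of acquisitions (one molecule per iteration).
#' @param repeats Number of repeated runs with distinct cold starts
#'   (default 3, the standard protocol for statistical comparison).
#' @param seeds One integer seed per repeat; defaults to a stream derived
#'   from \code{base_seed}.
#' @param base_seed Base seed used when \code{seeds} is not given.
#' @return A \code{policy_config} list.
#' @export
policy_config <- function(policy = c("activedelta", "single_exploit", "random"),
                          regressor = NULL, iterations = 100L, repeats = 3L,
                          seeds = NULL, base_seed = 1L) {
  policy <- match.arg(policy)
  if (is.null(regressor)) {
    regressor <- regressor_spec(
      "gradient_boosted_trees",
      mode = if (policy == "activedelta") "paired" else "single")
  }
  want <- if (policy == "activedelta") "paired" else "single"
  if (policy != "random" && regressor$mode != want) {
    stop_contract("policy '", policy, "' needs a ", want, "-mode regressor")
  }
  if (!is.null(seeds) && missing(repeats)) repeats <- length(seeds)
  stopifnot(iterations >= 1, repeats >= 1)
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(repeats), function(r) derive_seed(base_seed, r),
                    numeric(1))
  }
  if (length(seeds) != repeats) stop_contract("need one seed per repeat")
  structure(list(policy = policy, regressor = regressor,
                 iterations = as.integer(iterations),
                 repeats = as.integer(repeats), seeds = seeds),
            class = "policy_config")
}

#' Select the next molecule to acquire
#'
#' Refits the policy's model on the current training set and scores the pool
#' with pool labels hidden; ties at the argmax break to the earliest pool
#' position. The chosen molecule's true potency is only revealed by the
#' caller after acquisition.
#'
#' @param policy A [policy_config()].
#' @param train Current training set (labeled).
#' @param pool Non-empty learning pool.
#' @param seed Seed for the random policy's draw (and model refit).
#' @return \code{list(chosen=, score=, anchor=)}; \code{anchor} is the
#'   best-in-train record for activedelta, \code{NULL} otherwise.
#' @export
acquire_next <- function(policy, train, pool, seed = policy$seeds[1]) {
  if (nrow(pool) == 0) stop_contract("learning pool exhausted")
  pool_hidden <- pool
  pool_hidden$potency <- NA_real_  # labels are not visible to the policy
  anchor <- NULL
  if (policy$policy == "random") {
    set.seed(as.integer(seed %% 2147483647))
    idx <- sample.int(nrow(pool), 1L)
    score <- NA_real_
  } else if (policy$policy == "single_exploit") {
    spec <- policy$regressor
    spec$seed <- as.integer(seed %% 2147483647)
    model <- fit_single(spec, train)
    preds <- predict_single(model, pool_hidden)
    idx <- which.max(preds)
    score <- preds[idx]
  } else {
    spec <- policy$regressor
    spec$seed <- as.integer(seed %% 2147483647)
    anchor <- best_in_train(train)
    model <- fit_delta(spec, cross_merge(train))
    preds <- predict_improvement(model, anchor, pool_hidden)
    idx <- which.max(preds)
    score <- preds[idx]
  }
  list(chosen = .as_cds(pool[idx, , drop = FALSE], pool),
       score = score, anchor = anchor)
}

#' Run one exploitative active-learning campaign
#'
#' Cold-starts with two random molecules under the repeat's seed, then runs
#' \code{policy$iterations} rounds of refit + acquire-one. The trajectory is
#' fully determined by \code{(policy, ds, seed)} for deterministic model
#' families.
#'
#' @param policy A [policy_config()].
#' @param ds The original training dataset (cold start + learning pool are
#'   carved out of it).
#' @param repeat_index Which repeat's seed to use (1-based).
#' @param verbose Log one line per iteration?
#' @return An \code{al_trajectory}: a data.frame with one row per iteration
#'   (\code{iteration, id, smiles, potency, score, anchor_id, train_size})
#'   plus attributes \code{cold_start} (the two starting records),
#'   \code{config}, \code{seed} and \code{final_train}.
#' @export
run_active_learning <- function(policy, ds, repeat_index = 1L,
                                verbose = FALSE) {
  seed_r <- policy$seeds[repeat_index]
  if (policy$iterations > nrow(ds) - 2) {
    stop_contract("iteration budget ", policy$iterations,
                  " exceeds pool size ", nrow(ds) - 2)
  }
  cs <- cold_start(ds, seed_r)
  train <- cs$train
  pool <- cs$pool
  rows <- vector("list", policy$iterations)
  for (t in seq_len(policy$iterations)) {
    res <- acquire_next(policy, train, pool, seed = derive_seed(seed_r, t))
    chosen <- res$chosen
    rows[[t]] <- data.frame(
      iteration = t, id = chosen$id, smiles = chosen$smiles,
      potency = chosen$potency,  # true label revealed on acquisition
      score = res$score,
      anchor_id = if (is.null(res$anchor)) NA_character_ else res$anchor$id,
      train_size = nrow(train) + 1L, stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("iter %3d | train %3d | anchor %s | chose %s (%.3f)",
                      t, nrow(train) + 1L,
                      rows[[t]]$anchor_id %||% "-", chosen$id,
                      chosen$potency))
    }
    train <- .as_cds(rbind(as.data.frame(train), as.data.frame(chosen)),
                     train)
    pool <- .as_cds(pool[pool$id != chosen$id, , drop = FALSE], pool)
  }
  traj <- do.call(rbind, rows)
  structure(traj, cold_start = as.data.frame(cs$train), config = policy,
            seed = seed_r, final_train = as.data.frame(train),
            class = c("al_trajectory", "data.frame"))
}

#' @export
print.al_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<al_trajectory: %s, %d iterations, seed %s>\n",
              cfg$policy, nrow(x), format(attr(x, "seed"))))
  cs <- attr(x, "cold_start")
  cat("cold start:", paste(cs$id, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("... and", nrow(x) - 5, "more iterations\n")
  invisible(x)
}

#' @export
summary.al_trajectory <- function(object, ...) {
  cs <- attr(object, "cold_start")
  best <- cummax(c(max(cs$potency), object$potency))
  out <- list(policy = attr(object, "config")$policy,
              iterations = nrow(object),
              best_potency = best[length(best)],
              best_at_start = best[1],
              n_acquired = nrow(object))
  class(out) <- "summary.al_trajectory"
  out
}

#' @export
print.summary.al_trajectory <- function(x, ...) {
  cat(sprintf("Active learning (%s): %d acquisitions\n", x$policy,
              x$iterations))
  cat(sprintf("  best potency: %.3f at cold start -> %.3f after run\n",
              x$best_at_start, x$best_potency))
  invisible(x)
}

#' Plot the best-so-far potency trace of a trajectory
#'
#' @param x An \code{al_trajectory}.
#' @param ... Passed to [plot()].
#' @export
plot.al_trajectory <- function(x, ...) {
  cs <- attr(x, "cold_start")
  best <- cummax(c(max(cs$potency), x$potency))
  plot(0:nrow(x), best, type = "s", xlab = "iteration",
       ylab = "best training potency", ...)
  invisible(x)
}

#' Score an external test set with the model a run has earned
#'
#' Refits the policy's regressor on the cold start plus the first
#' \code{budget} acquisitions of the trajectory and scores the test set.
#' Under activedelta the scores are predicted improvements over the final
#' training-set best (the anchor of the finished run); under the other
#' policies they are absolute potency estimates. Either way the scores rank
#' test molecules for top-decile hit retrieval.
#'
#' @param policy A [policy_config()].
#' @param trajectory An \code{al_trajectory} with at least \code{budget}
#'   acquisitions.
#' @param test A [compound_dataset()].
#' @param budget Number of acquisitions to train on (default: all).
#' @param include_cold_start Include the 2 cold-start molecules in the
#'   training set (default TRUE)?
#' @return Numeric scores, one per test molecule, in test order.
#' @export
evaluate_on_test <- function(policy, trajectory, test,
                             budget = nrow(trajectory),
                             include_cold_start = TRUE) {
  if (budget > nrow(trajectory)) {
    stop_contract("budget exceeds trajectory length")
  }
  acq <- as.data.frame(trajectory)[seq_len(budget),
                                   c("id", "smiles", "potency")]
  if (include_cold_start) {
    acq <- rbind(attr(trajectory, "cold_start")[, c("id", "smiles", "potency")],
                 acq)
  }
  train <- compound_dataset(acq$smiles, acq$potency, id = acq$id,
                            role = "train", canonicalize = FALSE)
  spec <- policy$regressor
  if (policy$policy == "activedelta") {
    model <- fit_delta(spec, cross_merge(train))
    predict_improvement(model, best_in_train(train), test)
  } else {
    if (spec$mode != "single") spec$mode <- "single"
    model <- fit_single(spec, train)
    predict_single(model, test)
  }
}
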