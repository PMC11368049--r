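# Regressor families behind one interface. Fingerprint-based families
# (gradient-boosted trees via xgboost, random forest) work in single-molecule
# mode (features: one Morgan fingerprint -> absolute potency) or paired mode
# (features: concatenated fingerprints of a molecular pair -> potency
# difference). Oracle families expose ground truth for protocol testing, and
# a D-MPNN adapter slot records the settings of the optional two-molecule
# message-passing backend without reimplementing it.

.FAMILIES <- c("gradient_boosted_trees", "random_forest", "dmpnn_adapter",
               "oracle_perfect", "oracle_noisy")

#' Specify a regressor
#'
#' @param family One of \code{"gradient_boosted_trees"} (xgboost),
#'   \code{"random_forest"}, \code{"dmpnn_adapter"} (optional external
#'   two-molecule D-MPNN backend; settings recorded, backend required at fit
#'   time), \code{"oracle_perfect"} or \code{"oracle_noisy"} (ground-truth
#'   lookups for testing the acquisition protocol).
#' @param mode \code{"single"} (molecule -> absolute potency) or
#'   \code{"paired"} (molecule pair -> potency difference).
#' @param hyperparams Named list of overrides. Tree families default to the
#'   library defaults (\code{eta = 0.3}, \code{max_depth = 6},
#'   \code{nrounds = 100}; \code{ntree = 500}). The D-MPNN adapter defaults
#'   to \code{epochs = 5} in paired mode, \code{epochs = 50} in single mode,
#'   \code{aggregation = "sum"}. Oracles take \code{truth} (named numeric
#'   vector of potencies keyed by SMILES) and \code{noise_sd}.
#' @param seed Integer seed controlling all fitting randomness.
#' @return A \code{regressor_spec} list.
#' @export
regressor_spec <- function(family = "gradient_boosted_trees",
                           mode = c("single", "paired"),
                           hyperparams = list(), seed = 1L) {
  family <- match.arg(family, .FAMILIES)
  mode <- match.arg(mode)
  defaults <- switch(family,
    gradient_boosted_trees = list(eta = 0.3, max_depth = 6, nrounds = 100),
    random_forest = list(ntree = 500),
    dmpnn_adapter = list(epochs = if (mode == "paired") 5 else 50,
                         aggregation = "sum"),
    oracle_perfect = list(truth = NULL),
    oracle_noisy = list(truth = NULL, noise_sd = 0.1)
  )
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(family = family, mode = mode, hyperparams = hp,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Fit a single-molecule potency regressor
#'
#' Trains \code{spec$family} to map one molecule's Morgan fingerprint to its
#' absolute potency. Always refit from scratch (the active-learning protocol
#' retrains on the full growing set each round).
#'
#' @param spec A [regressor_spec()] with \code{mode = "single"}.
#' @param train A [compound_dataset()] with at least 2 molecules.
#' @return An \code{ad_model}; \code{x$fit_report} records sizes and wall
#'   time, \code{predict()} and [predict_single()] score new molecules.
#' @export
fit_single <- function(spec, train) {
  if (spec$mode != "single") stop_contract("spec mode must be 'single'")
  if (nrow(train) < 2) stop_contract("need at least 2 training molecules")
  t0 <- proc.time()[["elapsed"]]
  fit <- .fit_family(spec, smiles = train$smiles, y = train$potency,
                     paired = FALSE)
  .ad_model(spec, fit, list(n_train = nrow(train), n_pairs = NA_integer_,
                            wall_time = proc.time()[["elapsed"]] - t0))
}

#' Fit a paired potency-difference (delta) regressor
#'
#' Trains \code{spec$family} on cross-merged pairs to map the concatenated
#' fingerprints of (reference, candidate) to the potency difference
#' candidate minus reference.
#'
#' @param spec A [regressor_spec()] with \code{mode = "paired"}.
#' @param pairs A labeled \code{pair_set} from [cross_merge()].
#' @return An \code{ad_model}; score candidate pairs with
#'   [predict_improvement()].
#' @export
fit_delta <- function(spec, pairs) {
  if (spec$mode != "paired") stop_contract("spec mode must be 'paired'")
  if (nrow(pairs) == 0) stop_contract("empty pair set")
  if (!isTRUE(attr(pairs, "labeled")) || anyNA(pairs$delta)) {
    stop_contract("fit_delta needs labeled pairs from cross_merge()")
  }
  t0 <- proc.time()[["elapsed"]]
  fit <- .fit_family(spec, pairs = pairs, y = pairs$delta, paired = TRUE)
  n_train <- length(unique(c(pairs$first_id, pairs$second_id)))
  .ad_model(spec, fit, list(n_train = n_train, n_pairs = nrow(pairs),
                            wall_time = proc.time()[["elapsed"]] - t0))
}

.ad_model <- function(spec, fit, report) {
  structure(list(spec = spec, fit = fit,
                 training_fingerprint_kind = "morgan_r2_2048",
                 fit_report = c(report,
                                list(hyperparams = spec$hyperparams,
                                     seed = spec$seed))),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model %s/%s: n_train=%d%s, %.2fs>\n",
              x$spec$family, x$spec$mode, x$fit_report$n_train,
              if (!is.na(x$fit_report$n_pairs))
                sprintf(", n_pairs=%d", x$fit_report$n_pairs) else "",
              x$fit_report$wall_time))
  invisible(x)
}

.fit_family <- function(spec, smiles = NULL, pairs = NULL, y, paired) {
  hp <- spec$hyperparams
  switch(spec$family,
    gradient_boosted_trees = {
      X <- if (paired) pair_features(pairs) else fingerprint_matrix(smiles)
      params <- list(objective = "reg:squarederror", nthread = 1,
                     eta = hp$eta, max_depth = hp$max_depth, seed = spec$seed)
      booster <- xgboost::xgb.train(
        params = params, data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = hp$nrounds, verbose = 0)
      list(kind = "xgb", booster = booster)
    },
    random_forest = {
      X <- if (paired) pair_features(pairs) else fingerprint_matrix(smiles)
      set.seed(spec$seed)
      if (stats::var(y) == 0) {
        # degenerate constant-label fit: randomForest refuses 0-variance
        # response in some versions; a constant predictor is exact here
        list(kind = "const", value = y[1])
      } else {
        rf <- randomForest::randomForest(x = as.matrix(X), y = y,
                                         ntree = hp$ntree)
        list(kind = "rf", forest = rf)
      }
    },
    dmpnn_adapter = {
      stop_contract("the optional D-MPNN backend (chemprop) is not ",
                    "installed; adapter defaults: epochs=", hp$epochs,
                    ", aggregation='", hp$aggregation, "'")
    },
    oracle_perfect = ,
    oracle_noisy = {
      truth <- hp$truth
      if (is.null(truth)) {
        if (paired) stop_contract("oracle families need hyperparams$truth")
        truth <- stats::setNames(y, canonical_smiles(smiles))
      } else {
        names(truth) <- canonical_smiles(names(truth))
      }
      list(kind = "oracle", truth = truth,
           noise_sd = if (spec$family == "oracle_noisy") hp$noise_sd else 0)
    }
  )
}

.oracle_lookup <- function(model, smiles) {
  truth <- model$fit$truth
  can <- canonical_smiles(smiles)
  miss <- !(can %in% names(truth))
  if (any(miss)) stop_contract("oracle has no label for: ",
                               paste(utils::head(can[miss], 3), collapse = ", "))
  v <- unname(truth[can])
  sd <- model$fit$noise_sd
  if (sd > 0) {
    # per-molecule noise, deterministic in (spec$seed, molecule) and
    # independent of call order
    v <- v + vapply(can, function(s) {
      set.seed((hash_ints(c(model$spec$seed, utf8ToInt(s)))) %% 2147483647)
      stats::rnorm(1, 0, sd)
    }, numeric(1), USE.NAMES = FALSE)
  }
  v
}

#' Predict absolute potency for pool molecules
#'
#' @param model An \code{ad_model} from [fit_single()].
#' @param pool A [compound_dataset()]; order is preserved.
#' @return Numeric vector of potency estimates, one per pool molecule.
#' @export
predict_single <- function(model, pool) {
  if (model$spec$mode != "single") stop_contract("model is not single-mode")
  .predict_features(model, smiles = pool$smiles)
}

#' Predict potency improvement of pool molecules over an anchor
#'
#' Scores each candidate pair (anchor, pool molecule) with a paired model;
#' the estimate is predicted potency(candidate) minus potency(anchor).
#'
#' @param model An \code{ad_model} from [fit_delta()].
#' @param anchor Single-row record of the reference compound.
#' @param pool A [compound_dataset()]; order is preserved.
#' @return Numeric vector of delta estimates, one per pool molecule.
#' @export
predict_improvement <- function(model, anchor, pool) {
  if (model$spec$mode != "paired") stop_contract("model is not paired-mode")
  pairs <- anchor_pairs(anchor, pool)
  if (model$fit$kind == "oracle") {
    return(.oracle_lookup(model, pairs$second_smiles) -
             .oracle_lookup(model, pairs$first_smiles))
  }
  .predict_features(model, pairs = pairs)
}

#' @export
predict.ad_model <- function(object, newdata, ...) {
  if (object$spec$mode == "single") {
    predict_single(object, newdata)
  } else {
    if (!inherits(newdata, "pair_set")) {
      stop_contract("paired models predict on a pair_set")
    }
    if (object$fit$kind == "oracle") {
      return(.oracle_lookup(object, newdata$second_smiles) -
               .oracle_lookup(object, newdata$first_smiles))
    }
    .predict_features(object, pairs = newdata)
  }
}

.predict_features <- function(model, smiles = NULL, pairs = NULL) {
  switch(model$fit$kind,
    oracle = .oracle_lookup(model, smiles),
    const = rep(model$fit$value,
                if (is.null(pairs)) length(smiles) else nrow(pairs)),
    xgb = {
      X <- if (is.null(pairs)) fingerprint_matrix(smiles) else
        pair_features(pairs)
      stats::predict(model$fit$booster, xgboost::xgb.DMatrix(X))
    },
    rf = {
      X <- if (is.null(pairs)) fingerprint_matrix(smiles) else
        pair_features(pairs)
      unname(stats::predict(model$fit$forest, as.matrix(X)))
    }
  )
}
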