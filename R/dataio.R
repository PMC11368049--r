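# Dataset ingestion, deduplication, splitting and active-learning cold start.
#
# A compound dataset is a plain data.frame (id, smiles, potency, optionally
# split) with class "compound_dataset" and attributes `role` and `name`.
# Potency is always oriented so that LARGER = MORE potent; raw K_i values are
# mapped onto this scale by the loader's log transform (pK_i = -log10 K_i).

#' Construct a compound dataset
#'
#' @param smiles Character vector of SMILES (canonicalized unless
#'   \code{canonicalize = FALSE}).
#' @param potency Numeric potency values, larger = more potent.
#' @param id Stable identifiers; defaults to \code{cmpd_1, cmpd_2, ...}.
#' @param role One of \code{"train"}, \code{"learning"}, \code{"test"}.
#' @param name Dataset label.
#' @param canonicalize Canonicalize SMILES on construction?
#' @return A \code{compound_dataset} data.frame with columns
#'   \code{id, smiles, potency}.
#' @export
compound_dataset <- function(smiles, potency, id = NULL,
                             role = c("learning", "train", "test"),
                             name = "dataset", canonicalize = TRUE) {
  role <- match.arg(role)
  stopifnot(length(smiles) == length(potency))
  if (is.null(id)) {
    id <- if (length(smiles)) paste0("cmpd_", seq_along(smiles)) else
      character(0)
  }
  if (anyDuplicated(id)) stop_contract("ids must be unique within a dataset")
  if (canonicalize && length(smiles)) {
    can <- canonical_smiles(smiles)
    if (anyNA(can)) {
      stop_contract("invalid SMILES: ",
                    paste(utils::head(smiles[is.na(can)], 3), collapse = ", "))
    }
    smiles <- can
  }
  if (length(potency) && any(!is.finite(potency))) {
    stop_contract("potency values must be finite")
  }
  df <- data.frame(id = as.character(id), smiles = as.character(smiles),
                   potency = as.numeric(potency), stringsAsFactors = FALSE)
  structure(df, role = role, name = name,
            class = c("compound_dataset", "data.frame"))
}

#' @export
print.compound_dataset <- function(x, ...) {
  cat(sprintf("<compound_dataset '%s' (%s): %d molecules>\n",
              attr(x, "name"), attr(x, "role"), nrow(x)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat("... and", nrow(x) - 5, "more rows\n")
  }
  invisible(x)
}

.as_cds <- function(df, template, role = NULL, name = NULL) {
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            role = role %||% attr(template, "role"),
            name = name %||% attr(template, "name"),
            class = c("compound_dataset", "data.frame"))
}

#' Load a compound dataset from CSV
#'
#' Reads a CSV with one row per compound, canonicalizes the SMILES, drops
#' unparseable or unlabeled rows (counted in the load report), optionally
#' maps raw K_i-style values onto the internal orientation via
#' \code{potency = -log10(raw)}, and removes duplicate molecules (first
#' occurrence kept, duplicates defined on canonical SMILES).
#'
#' @param path CSV file path (header required).
#' @param smiles_col,potency_col Column names (defaults \code{"SMILES"},
#'   \code{"potency"}).
#' @param log_transform If \code{TRUE}, potency is \code{-log10(raw)} so that
#'   smaller K_i means larger potency; non-positive raw values are dropped
#'   with a warning.
#' @param split_col Optional column with values \code{train}/\code{test}
#'   carrying a precomputed split (kept as a \code{split} column).
#' @param name Dataset label; defaults to the file name.
#' @return A [compound_dataset()]; \code{attr(x, "load_report")} counts input,
#'   invalid-SMILES, missing/non-positive-potency and duplicate rows.
#' @export
load_dataset <- function(path, smiles_col = "SMILES", potency_col = "potency",
                         log_transform = FALSE, split_col = NULL,
                         name = NULL) {
  if (!file.exists(path)) stop_contract("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(smiles_col, potency_col)) {
    if (!col %in% names(raw)) stop_contract("missing column: ", col)
  }
  n_input <- nrow(raw)
  smiles <- as.character(raw[[smiles_col]])
  pot <- suppressWarnings(as.numeric(raw[[potency_col]]))

  can <- if (n_input) canonical_smiles(smiles) else character(0)
  invalid <- is.na(can)
  missing_pot <- !is.finite(pot)
  nonpos <- rep(FALSE, n_input)
  if (log_transform) {
    nonpos <- is.finite(pot) & pot <= 0
    if (any(nonpos)) {
      warning(sum(nonpos),
              " row(s) with non-positive raw value dropped under log transform")
    }
  }
  keep <- !invalid & !missing_pot & !nonpos
  can <- can[keep]
  pot <- pot[keep]
  if (log_transform) pot <- -log10(pot)
  dup <- duplicated(can)

  ds <- compound_dataset(can[!dup], pot[!dup],
                         name = name %||% basename(path),
                         canonicalize = FALSE)
  if (!is.null(split_col) && split_col %in% names(raw)) {
    ds$split <- as.character(raw[[split_col]])[keep][!dup]
  }
  if (nrow(ds) == 0) stop_contract("no valid rows in ", path)
  attr(ds, "load_report") <- list(
    n_input = n_input, n_invalid_smiles = sum(invalid),
    n_missing_potency = sum(missing_pot & !invalid),
    n_nonpositive = sum(nonpos & !invalid & !missing_pot),
    n_duplicates = sum(dup), n_kept = nrow(ds))
  ds
}

#' Write a compound dataset to CSV
#'
#' Round-trips through [load_dataset()] with full numeric precision.
#'
#' @param ds A [compound_dataset()].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds)
  names(df)[names(df) == "smiles"] <- "SMILES"
  df$potency <- format(df$potency, digits = 17, trim = TRUE,
                       scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove duplicate molecules
#'
#' Duplicates are defined on canonical SMILES (chemical identity, not the
#' raw string); the first occurrence is kept, so the operation is
#' deterministic, order-stable and idempotent.
#'
#' @param ds A [compound_dataset()].
#' @return The dataset with duplicates removed.
#' @export
deduplicate <- function(ds) {
  keep <- !duplicated(ds$smiles)
  .as_cds(ds[keep, , drop = FALSE], ds)
}

#' Split specification
#'
#' @param train_fraction Fraction of molecules assigned to training
#'   (default 0.8, the standard 80:20 ratio).
#' @param seed Integer seed for random mode.
#' @param mode \code{"random"} or \code{"precomputed"} (membership read from
#'   the dataset's \code{split} column, as with time-split benchmark files).
#' @return A \code{split_spec} list.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 1L,
                       mode = c("random", "precomputed")) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 mode = mode), class = "split_spec")
}

#' Split a dataset into train and test parts
#'
#' @param ds A [compound_dataset()].
#' @param spec A [split_spec()].
#' @return \code{list(train=, test=)} of compound datasets.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  if (spec$mode == "precomputed") {
    if (is.null(ds$split)) stop_contract("precomputed mode needs a 'split' column")
    tr <- ds$split == "train"
  } else {
    n <- nrow(ds)
    n_train <- round(spec$train_fraction * n)
    set.seed(spec$seed)
    tr <- logical(n)
    tr[sample.int(n, n_train)] <- TRUE
  }
  list(train = .as_cds(ds[tr, , drop = FALSE], ds, role = "train"),
       test = .as_cds(ds[!tr, , drop = FALSE], ds, role = "test"))
}

#' Cold-start an active-learning run
#'
#' Draws exactly two molecules uniformly without replacement as the initial
#' training set; the remainder becomes the learning pool the policy selects
#' from. Deterministic given \code{(ds, seed)}.
#'
#' @param ds A [compound_dataset()] with at least 3 molecules.
#' @param seed Integer seed.
#' @return \code{list(train=, pool=)}; train has 2 rows,
#'   pool has \code{nrow(ds) - 2}.
#' @export
cold_start <- function(ds, seed) {
  if (nrow(ds) < 3) stop_contract("cold start needs at least 3 molecules")
  set.seed(as.integer(seed %% 2147483647))
  pick <- sample.int(nrow(ds), 2L)
  list(train = .as_cds(ds[pick, , drop = FALSE], ds, role = "train"),
       pool = .as_cds(ds[-pick, , drop = FALSE], ds, role = "learning"))
}
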