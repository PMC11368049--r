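# Synthetic SMILES libraries with a learnable potency landscape.
#
# Molecules are assembled from a fixed fragment grammar (ring cores, linkers,
# substituents), so every generated SMILES is valid by construction and the
# library is scaffold-diverse. Potency follows
#   potency(m) = signal . fingerprint(m) + assay_offset + Normal(0, noise_sd)
# with the signal acting on the same Morgan bits the models consume, making
# the landscape learnable by construction. A positive hit_skew concentrates
# extra weight on a few rarer substructure bits so the top decile separates
# into a small, well-defined hit set.

.GRAMMAR <- list(
  prefixes = c("", "C", "CC", "CO", "N", "F", "Cl", "C(C)C"),
  ring1 = c(benzene = "c1ccc(%s)cc1", pyridine = "c1ccc(%s)nc1",
            cyclohexane = "C1CCC(%s)CC1", thiophene = "c1cc(%s)cs1",
            furan = "c1cc(%s)co1", piperidine = "C1CCC(%s)CN1"),
  tails = c("C", "O", "N", "F", "Cl", "C#N", "C(F)(F)F", "C(=O)O", "OC",
            "CC"),
  linkers = c("", "C", "CC", "O", "N", "C(=O)", "C(=O)N", "OC", "C=C"),
  ring2 = c(benzene = "c2ccccc2", pyridine = "c2ccncc2",
            cyclohexane = "C2CCCCC2", furan = "c2ccoc2",
            thiophene = "c2cccs2", naphthalene = "c2ccc3ccccc3c2"),
  n_rings = c(morpholino = "N2CCOCC2", piperidinyl = "N2CCCCC2")
)

# Enumerate the full grammar deterministically (several thousand molecules).
.enumerate_grammar <- function() {
  g <- .GRAMMAR
  xs <- c(g$tails, as.vector(outer(g$linkers, g$ring2, paste0)), g$n_rings)
  smis <- character(0)
  for (pre in g$prefixes) {
    for (r1 in g$ring1) {
      smis <- c(smis, paste0(pre, sprintf(r1, xs)))
    }
  }
  unique(smis)
}

#' Specify a synthetic potency landscape
#'
#' @param library_size Number of molecules to generate (>= 30).
#' @param generator \code{"enumerated_fragments"} (sample the fragment
#'   grammar) or \code{"fixture_list"} (use \code{fixture_smiles} as given).
#' @param n_signal_bits How many Morgan bits carry base signal.
#' @param signal_scale SD of the base signal weights.
#' @param noise_sd Assay noise SD (potency units).
#' @param assay_offset Systematic additive shift (default 6, centering the
#'   landscape on a pK_i-like scale).
#' @param hit_skew Extra weight on a few rarer bits separating the top tail
#'   (0 disables).
#' @param seed Integer seed governing molecule sampling, signal weights and
#'   noise.
#' @param fixture_smiles SMILES vector for \code{generator="fixture_list"}.
#' @return A \code{landscape_spec} list.
#' @export
landscape_spec <- function(library_size = 300L,
                           generator = c("enumerated_fragments",
                                         "fixture_list"),
                           n_signal_bits = 40L, signal_scale = 1,
                           noise_sd = 0.3, assay_offset = 6, hit_skew = 2,
                           seed = 1L, fixture_smiles = NULL) {
  generator <- match.arg(generator)
  stopifnot(library_size >= 30, noise_sd >= 0)
  structure(list(library_size = as.integer(library_size),
                 generator = generator,
                 n_signal_bits = as.integer(n_signal_bits),
                 signal_scale = signal_scale, noise_sd = noise_sd,
                 assay_offset = assay_offset, hit_skew = hit_skew,
                 seed = as.integer(seed), fixture_smiles = fixture_smiles),
            class = "landscape_spec")
}

#' Generate a synthetic compound library
#'
#' Samples (or takes) a duplicate-free set of valid canonical SMILES and
#' assigns potencies from the landscape formula. Deterministic per seed.
#' The fitted signal vector is attached as \code{attr(ds, "signal")} (a
#' named weight vector over Morgan bit indices) together with the spec.
#'
#' @param spec A [landscape_spec()].
#' @return A [compound_dataset()] of \code{library_size} molecules.
#' @export
generate_library <- function(spec) {
  if (spec$generator == "fixture_list") {
    smis <- canonical_smiles(spec$fixture_smiles)
    smis <- unique(smis[!is.na(smis)])
  } else {
    smis <- canonical_smiles(.enumerate_grammar())
    smis <- unique(smis[!is.na(smis)])
  }
  if (length(smis) < spec$library_size) {
    stop_contract("grammar yields only ", length(smis),
                  " molecules; requested ", spec$library_size)
  }
  set.seed(spec$seed)
  # radix sort = C-locale byte order: reproducible across locales/sessions
  smis <- sort(smis, method = "radix")
  pick <- sample.int(length(smis), spec$library_size)
  smis <- smis[pick]

  FP <- fingerprint_matrix(smis)
  freq <- Matrix::colMeans(FP)
  base_pool <- which(freq >= 0.05 & freq <= 0.6)
  skew_pool <- which(freq >= 0.02 & freq <= 0.15)
  n_base <- min(spec$n_signal_bits, length(base_pool))
  w <- numeric(ncol(FP))
  bits <- sample(base_pool, n_base)
  w[bits] <- stats::rnorm(n_base, 0, spec$signal_scale)
  if (spec$hit_skew > 0 && length(skew_pool)) {
    skew_bits <- sample(setdiff(skew_pool, bits),
                        min(3L, length(setdiff(skew_pool, bits))))
    w[skew_bits] <- w[skew_bits] + spec$hit_skew
  }
  potency <- as.numeric(FP %*% w) + spec$assay_offset +
    stats::rnorm(length(smis), 0, spec$noise_sd)
  ds <- compound_dataset(smis, potency, id = paste0("syn_", seq_along(smis)),
                         name = sprintf("synthetic_seed%d", spec$seed),
                         canonicalize = FALSE)
  attr(ds, "signal") <- stats::setNames(w[w != 0], which(w != 0))
  attr(ds, "landscape") <- spec
  ds
}

#' Generate an 80:20 train/test split of a synthetic library
#'
#' @param spec A [landscape_spec()].
#' @param scaffold_disjoint If TRUE, whole Bemis-Murcko scaffold groups are
#'   assigned to one side only, mimicking the harder character of time-based
#'   splits; otherwise the split is random.
#' @return \code{list(train=, test=)}.
#' @export
generate_split <- function(spec, scaffold_disjoint = FALSE) {
  ds <- generate_library(spec)
  if (!scaffold_disjoint) {
    return(split_dataset(ds, split_spec(0.8, seed = derive_seed(spec$seed, 77))))
  }
  scaff <- vapply(ds$smiles, murcko_scaffold, character(1), USE.NAMES = FALSE)
  scaff[!nzchar(scaff)] <- "(acyclic)"
  groups <- split(seq_len(nrow(ds)), scaff)
  groups <- groups[sort(names(groups), method = "radix")]  # locale-stable
  set.seed(as.integer(derive_seed(spec$seed, 78) %% 2147483647))
  ord <- sample(length(groups))
  target <- 0.8 * nrow(ds)
  tr <- logical(nrow(ds))
  count <- 0
  for (gidx in ord) {
    if (count < target) {
      tr[groups[[gidx]]] <- TRUE
      count <- count + length(groups[[gidx]])
    }
  }
  list(train = .as_cds(ds[tr, , drop = FALSE], ds, role = "train"),
       test = .as_cds(ds[!tr, , drop = FALSE], ds, role = "test"))
}
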