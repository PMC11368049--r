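# Molecular fingerprints and Tanimoto similarity.
#
# Morgan (ECFP-style, radius 2, folded to 2048 bits) and Carhart atom-pair
# fingerprints are computed natively from the molecular graph with a fixed
# integer hash, so bit assignments are identical across sessions and
# platforms (no run-dependent hashing). MACCS keys are delegated to Open
# Babel. Bit positions are implementation-defined per kind; only identity,
# determinism and Tanimoto geometry are meaningful, which is all the
# similarity analyses use.

.FP_KINDS <- c(morgan_r2_2048 = 2048L, maccs = 166L, atom_pair = 2048L)

#' Compute a molecular fingerprint
#'
#' @param smiles A single SMILES string.
#' @param kind One of \code{"morgan_r2_2048"} (radial/ECFP, radius 2, 2048
#'   bits — the representation the models consume), \code{"maccs"} (166 MACCS
#'   keys via Open Babel) or \code{"atom_pair"} (Carhart atom pairs folded to
#'   2048 bits).
#' @return An integer 0/1 vector of the kind's fixed width, classed
#'   \code{"ad_fingerprint"}, with attributes \code{kind} and \code{smiles}
#'   (canonical form).
#' @examples
#' \donttest{
#' fp <- fingerprint("CCO", "morgan_r2_2048")
#' length(fp)  # 2048
#' }
#' @export
fingerprint <- function(smiles, kind = c("morgan_r2_2048", "maccs", "atom_pair")) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop_contract("invalid SMILES: ", smiles)
  on_bits <- fingerprint_bits(can, kind)
  width <- .FP_KINDS[[kind]]
  v <- integer(width)
  v[on_bits] <- 1L
  structure(v, kind = kind, smiles = can, class = "ad_fingerprint")
}

#' @export
print.ad_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits on> %s\n", attr(x, "kind"),
              sum(x), length(unclass(x)), attr(x, "smiles")))
  invisible(x)
}

# On-bit indices (1-based), cached per canonical SMILES.
fingerprint_bits <- function(can, kind) {
  cache_fetch(paste0("fp|", kind, "|", can), function() {
    switch(kind,
      morgan_r2_2048 = .morgan_bits(mol_graph(can), radius = 2L, nbits = 2048L),
      atom_pair = .atom_pair_bits(mol_graph(can), nbits = 2048L),
      maccs = .maccs_bits(can)
    )
  })
}

.morgan_bits <- function(g, radius = 2L, nbits = 2048L) {
  n <- g$n
  if (n == 0) return(integer(0))
  z <- .ELEMENT_Z[g$elements]
  z[is.na(z)] <- 0
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(as.integer(z[i]), g$degree[i], g$hcount[i],
                as.integer(g$ring_atom[i])))
  }, numeric(1))
  all_ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- vapply(seq_len(n), function(i) {
      nbr <- g$neighbors[[i]]
      if (is.null(nbr)) return(hash_ints(c(r, inv[i])))
      pairs <- cbind(nbr[, 2], inv[nbr[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_ints(c(r, inv[i], as.numeric(t(pairs[ord, , drop = FALSE]))))
    }, numeric(1))
    inv <- new_inv
    all_ids <- c(all_ids, inv)
  }
  sort(unique(as.integer(all_ids %% nbits) + 1L))
}

.atom_pair_bits <- function(g, nbits = 2048L) {
  n <- g$n
  if (n < 2) return(integer(0))
  z <- .ELEMENT_Z[g$elements]
  z[is.na(z)] <- 0
  atype <- vapply(seq_len(n), function(i) {
    hash_ints(c(as.integer(z[i]), g$degree[i], as.integer(g$ring_atom[i])))
  }, numeric(1))
  D <- .topo_dist(g)
  ids <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- D[i, j]
      if (!is.finite(d)) next
      ids <- c(ids, hash_ints(c(min(atype[i], atype[j]), min(d, 30),
                                max(atype[i], atype[j]))))
    }
  }
  sort(unique(as.integer(ids %% nbits) + 1L))
}

.maccs_bits <- function(can) {
  ref <- ChemmineOB::forEachMol("SMILES", paste0(can, "\tm"), identity)
  fp <- ChemmineOB::fingerprint_OB(ref, "MACCS")
  if (!is.null(dim(fp))) fp <- fp[1, ]
  bits <- as.integer(fp[seq_len(min(166L, length(fp)))])
  which(bits != 0)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over on-bits. Two all-zero fingerprints are
#' defined to have similarity 1 (identical, if featureless, bit sets); this
#' convention keeps nearest-neighbor maxima NaN-free.
#'
#' @param a,b Fingerprints of the same kind (from [fingerprint()]).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb)) {
    stop_contract("fingerprint kind mismatch: ", ka, " vs ", kb)
  }
  av <- as.integer(unclass(a)) != 0L
  bv <- as.integer(unclass(b)) != 0L
  if (length(av) != length(bv)) stop_contract("fingerprint length mismatch")
  un <- sum(av | bv)
  if (un == 0) return(1.0)
  sum(av & bv) / un
}

.tanimoto_sets <- function(bits_a, bits_b) {
  un <- length(union(bits_a, bits_b))
  if (un == 0) return(1.0)
  length(intersect(bits_a, bits_b)) / un
}

#' Nearest-neighbor Tanimoto similarity against a reference set
#'
#' Maximum Tanimoto similarity of \code{query} over all molecules of a
#' reference dataset. If the query is itself a member of the reference, the
#' maximum is 1 unless \code{exclude_self} removes exact (canonical-SMILES)
#' matches first.
#'
#' @param query A SMILES string.
#' @param reference A [compound_dataset()] (non-empty after exclusion).
#' @param kind Fingerprint kind, see [fingerprint()].
#' @param exclude_self Drop reference molecules identical to the query?
#' @return Maximum similarity in \[0, 1\].
#' @export
nearest_neighbor_similarity <- function(query, reference,
                                        kind = "morgan_r2_2048",
                                        exclude_self = FALSE) {
  kind <- match.arg(kind, names(.FP_KINDS))
  ref_smiles <- reference$smiles
  if (length(ref_smiles) == 0) stop_contract("empty reference set")
  qcan <- canonical_smiles(query)
  if (is.na(qcan)) stop_contract("invalid SMILES: ", query)
  if (exclude_self) ref_smiles <- ref_smiles[ref_smiles != qcan]
  if (length(ref_smiles) == 0) {
    stop_contract("reference set empty after self-exclusion")
  }
  qb <- fingerprint_bits(qcan, kind)
  max(vapply(ref_smiles, function(s) {
    .tanimoto_sets(qb, fingerprint_bits(canonical_smiles(s), kind))
  }, numeric(1)))
}

# Sparse n x width 0/1 matrix of fingerprints for model features.
fingerprint_matrix <- function(smiles, kind = "morgan_r2_2048") {
  width <- .FP_KINDS[[kind]]
  cans <- canonical_smiles(smiles)
  if (anyNA(cans)) stop_contract("invalid SMILES in feature input")
  bits <- lapply(cans, fingerprint_bits, kind = kind)
  lens <- lengths(bits)
  Matrix::sparseMatrix(
    i = rep(seq_along(bits), lens),
    j = unlist(bits),
    x = 1,
    dims = c(length(bits), width)
  )
}
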