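# Bemis-Murcko scaffolds: ring systems plus the linkers connecting them,
# with acyclic terminal substituents pruned away. Atoms multiple-bonded to
# the retained framework (e.g. the carbonyl oxygen of an amide linker) are
# kept, matching the common atom-typed framework definition.

#' Bemis-Murcko scaffold of a molecule
#'
#' @param smiles A single valid SMILES string.
#' @return Canonical SMILES of the scaffold, or \code{""} for acyclic
#'   molecules (no ring system). In diversity counts the empty scaffold is
#'   treated as one shared "acyclic" class.
#' @examples
#' \donttest{
#' murcko_scaffold("Cc1ccccc1")  # toluene -> benzene
#' murcko_scaffold("CCO")        # acyclic -> ""
#' }
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop_contract("invalid SMILES: ", smiles)
  cache_fetch(paste0("scaffold|", can), function() .murcko(can))
}

.murcko <- function(can) {
  g <- mol_graph(can)
  if (!any(g$ring_atom)) return("")
  keep <- rep(TRUE, g$n)
  deg <- g$degree
  # iteratively prune terminal non-ring atoms (linkers between rings survive)
  repeat {
    leaf <- which(keep & !g$ring_atom & deg <= 1L)
    if (!length(leaf)) break
    for (u in leaf) {
      keep[u] <- FALSE
      if (!is.null(g$neighbors[[u]])) {
        for (k in seq_len(nrow(g$neighbors[[u]]))) {
          v <- g$neighbors[[u]][k, 1]
          if (keep[v]) deg[v] <- deg[v] - 1L
        }
      }
    }
  }
  # restore atoms attached to the framework by a double/triple bond
  if (nrow(g$bonds)) {
    repeat {
      added <- FALSE
      for (r in seq_len(nrow(g$bonds))) {
        a <- g$bonds[r, 1]; b <- g$bonds[r, 2]; o <- g$bonds[r, 3]
        if (o >= 2 && xor(keep[a], keep[b])) {
          keep[if (keep[a]) b else a] <- TRUE
          added <- TRUE
        }
      }
      if (!added) break
    }
  }
  idx <- which(keep)
  remap <- match(seq_len(g$n), idx)
  bsel <- g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], , drop = FALSE]
  mol <- .molfile(g$elements[idx],
                  cbind(remap[bsel[, 1]], remap[bsel[, 2]], bsel[, 3]))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", mol)),
    error = function(e) ""
  )
  scaff <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(scaff) || !nzchar(scaff)) "" else scaff
}

.molfile <- function(elements, bonds) {
  na <- length(elements)
  nb <- nrow(bonds)
  atoms <- paste(sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elements), collapse = "\n")
  blines <- if (nb) {
    paste(sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3]),
          collapse = "\n")
  } else ""
  paste0("scaffold\n  adlearn\n\n",
         sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", na, nb),
         atoms, "\n",
         if (nzchar(blines)) paste0(blines, "\n") else "",
         "M  END\n$$$$\n")
}
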