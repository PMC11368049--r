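# SMILES canonicalization and molecular-graph extraction. Parsing is
# delegated to Open Babel through ChemmineOB/ChemmineR; this file only turns
# the parsed structure into the light-weight graph the fingerprint and
# scaffold code consume.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical form so that different string
#' renderings of the same molecule (e.g. \code{"CCO"} and \code{"OCC"})
#' compare equal. Unparseable strings map to \code{NA}.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @examples
#' \donttest{
#' canonical_smiles(c("CCO", "OCC"))
#' }
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  key <- paste0("can|", smiles)
  cached <- vapply(key, function(k) {
    v <- .ad_cache[[k]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  hit <- !is.na(cached) | is.na(smiles) | !nzchar(smiles)
  out[!is.na(cached)] <- cached[!is.na(cached)]
  todo <- which(!hit)
  if (length(todo)) {
    res <- .ob_canonical(smiles[todo])
    out[todo] <- res
    for (j in seq_along(todo)) {
      if (!is.na(res[j])) .ad_cache[[key[todo[j]]]] <- res[j]
    }
  }
  out
}

# Open Babel stops emitting output at the first bad input line, so convert in
# blocks and resume after each failure.
.ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  pos <- 1L
  while (pos <= n) {
    block <- seq.int(pos, n)
    input <- paste(paste0(smiles[block], "\tq", block), collapse = "\n")
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input)),
      error = function(e) ""
    )
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    k <- 0L
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      idx <- suppressWarnings(as.integer(sub("^q", "", parts[2])))
      if (is.na(idx)) next
      out[idx] <- parts[1]
      k <- max(k, idx - pos + 1L)
    }
    # the line after the last successful one failed to parse; skip it
    pos <- pos + k + 1L
  }
  out
}

# Standard valences used to infer implicit hydrogen counts from the
# kekulized connection table. Formal charges are not modelled; charged
# species are featurized with this neutral-valence heuristic (deterministic,
# and irrelevant for the shipped fragment grammar which is charge-free).
.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
              I = 1, B = 3, Si = 4, Se = 2)

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

#' @keywords internal
mol_graph <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop_contract("invalid SMILES: ", smiles)
  cache_fetch(paste0("graph|", can), function() .build_graph(can))
}

.build_graph <- function(can) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, "m"))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (is.null(dim(bb)) || nrow(as.matrix(bb)) == 0) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bb <- as.matrix(bb)
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                   as.integer(bb[, 3]))
  }
  # drop explicit hydrogens if present (Open Babel normally leaves them
  # implicit; be safe)
  heavy <- elements != "H"
  if (!all(heavy)) {
    keep <- which(heavy)
    remap <- match(seq_len(n), keep)
    hb <- bonds[, 1] %in% keep & bonds[, 2] %in% keep
    bonds <- bonds[hb, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    elements <- elements[keep]
    n <- length(elements)
  }
  nb <- vector("list", n)
  degree <- integer(n)
  bondsum <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]; o <- bonds[r, 3]
      nb[[a]] <- rbind(nb[[a]], c(b, o, r))
      nb[[b]] <- rbind(nb[[b]], c(a, o, r))
      degree[a] <- degree[a] + 1L
      degree[b] <- degree[b] + 1L
      bondsum[a] <- bondsum[a] + o
      bondsum[b] <- bondsum[b] + o
    }
  }
  val <- .VALENCE[elements]
  val[is.na(val)] <- 4
  hcount <- pmax(0L, as.integer(val) - bondsum)
  ring_bond <- .ring_bonds(n, bonds)
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    rb <- bonds[ring_bond, , drop = FALSE]
    ring_atom[unique(c(rb[, 1], rb[, 2]))] <- TRUE
  }
  list(smiles = can, n = n, elements = elements, bonds = bonds,
       neighbors = nb, degree = degree, hcount = hcount,
       ring_bond = ring_bond, ring_atom = ring_atom)
}

# A bond is in a ring iff it is not a bridge (Tarjan bridge-finding).
.ring_bonds <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0 || n == 0) return(logical(0))
  adj <- vector("list", n)
  for (r in seq_len(m)) {
    adj[[bonds[r, 1]]] <- rbind(adj[[bonds[r, 1]]], c(bonds[r, 2], r))
    adj[[bonds[r, 2]]] <- rbind(adj[[bonds[r, 2]]], c(bonds[r, 1], r))
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  dfs <- function(u, parent_edge) {
    timer <<- timer + 1L
    disc[u] <<- low[u] <<- timer
    if (!is.null(adj[[u]])) {
      for (k in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][k, 1]; e <- adj[[u]][k, 2]
        if (e == parent_edge) next
        if (disc[v] == 0L) {
          dfs(v, e)
          low[u] <<- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[e] <<- TRUE
        } else {
          low[u] <<- min(low[u], disc[v])
        }
      }
    }
  }
  for (s in seq_len(n)) if (disc[s] == 0L) dfs(s, 0L)
  !is_bridge
}

# Topological (bond-count) distance matrix by BFS; Inf between components.
.topo_dist <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    queue <- s; D[s, s] <- 0
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.null(g$neighbors[[u]])) {
        for (k in seq_len(nrow(g$neighbors[[u]]))) {
          v <- g$neighbors[[u]][k, 1]
          if (is.infinite(D[s, v])) {
            D[s, v] <- D[s, u] + 1
            queue <- c(queue, v)
          }
        }
      }
    }
  }
  D
}
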