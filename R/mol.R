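#' Parse SMILES into molecular graphs
#'
#' Converts SMILES strings into light molecular-graph objects used by the
#' fingerprint machinery. Every input is first canonicalised with OpenBabel,
#' so two SMILES spellings of the same molecule (for example atom-order
#' permutations) yield byte-identical graphs and therefore identical
#' fingerprints.
#'
#' @param smiles character vector of SMILES strings.
#' @return A list of `selprof_mol` objects, one per input, each with
#'   components `smiles` (the input), `canonical` (OpenBabel canonical
#'   SMILES), `elements` (heavy-atom element symbols), `aromatic` (logical
#'   per atom), and `bonds` (data frame with columns `i`, `j`, `order`,
#'   `aromatic`; indices are 1-based into `elements`).
#' @details Hydrogens are implicit: only heavy atoms appear in the graph.
#'   Aromaticity is assigned from ring perception on the canonical structure
#'   (`ChemmineR::rings`), so it does not depend on how the input SMILES was
#'   kekulised. Unparsable SMILES raise an error naming the offending input.
#' @examples
#' mols <- parse_smiles(c("CCO", "c1ccccc1"))
#' mols[[2]]$aromatic
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  bad <- !nzchar(smiles) | is.na(smiles)
  if (any(bad)) {
    stop("unparsable SMILES (empty or NA) at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  canon <- canonical_smiles(smiles)
  if (any(!nzchar(canon))) {
    stop("unparsable SMILES: ",
         paste(sprintf("'%s'", smiles[!nzchar(canon)]), collapse = ", "))
  }
  lapply(seq_along(smiles), function(k) {
    .mol_from_canonical(smiles[k], canon[k])
  })
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector.
#' @return Character vector of canonical SMILES; empty string for inputs
#'   OpenBabel cannot parse.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMILES", "CAN", source = s),
      error = function(e) ""
    )
    # OpenBabel appends a title field and newline
    sub("[\t\n ].*$", "", out)
  }, character(1), USE.NAMES = FALSE)
}

# Build a selprof_mol from a canonical SMILES. Single heavy atoms are handled
# directly (a one-atom molblock carries no bond block for ChemmineR to read).
.mol_from_canonical <- function(input, canon) {
  frags <- strsplit(canon, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1 && grepl("^(\\[[^]]+\\]|[A-Za-z][a-z]?)$", canon)) {
    elem <- sub("^\\[([0-9]*)([A-Za-z][a-z]?).*\\]$", "\\2", canon)
    if (!grepl("^\\[", canon)) elem <- canon
    aromatic <- elem %in% c("b", "c", "n", "o", "p", "s")
    elem <- paste0(toupper(substring(elem, 1, 1)), substring(elem, 2))
    return(structure(list(smiles = input, canonical = canon,
                          elements = elem, aromatic = aromatic,
                          bonds = data.frame(i = integer(), j = integer(),
                                             order = integer(),
                                             aromatic = logical())),
                     class = "selprof_mol"))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canon))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(ab) == 0) stop("unparsable SMILES: '", input, "'")
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]), aromatic = FALSE)
  arom_atoms <- rep(FALSE, length(elements))
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE,
                                      inner = FALSE)),
    error = function(e) list(RINGS = list(), AROMATIC = logical())
  )
  if (length(rng$RINGS) > 0 && any(rng$AROMATIC)) {
    for (r in which(rng$AROMATIC)) {
      idx <- as.integer(sub("^[^_]+_", "", rng$RINGS[[r]]))
      arom_atoms[idx] <- TRUE
      m <- length(idx)
      for (k in seq_len(m)) {
        a <- idx[k]; b <- idx[if (k == m) 1 else k + 1]
        hit <- (bonds$i == a & bonds$j == b) | (bonds$i == b & bonds$j == a)
        bonds$aromatic[hit] <- TRUE
      }
    }
  }
  structure(list(smiles = input, canonical = canon, elements = elements,
                 aromatic = arom_atoms, bonds = bonds),
            class = "selprof_mol")
}

#' @export
print.selprof_mol <- function(x, ...) {
  cat("<selprof_mol> ", x$canonical, "\n", sep = "")
  cat("  heavy atoms: ", length(x$elements),
      " (", sum(x$aromatic), " aromatic), bonds: ", nrow(x$bonds),
      "\n", sep = "")
  invisible(x)
}

# OpenBabel molecule references for a SMILES vector; used for SMARTS matching.
.obmol_refs <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

#' Count SMARTS substructure matches
#'
#' @param smiles character vector of SMILES.
#' @param smarts single SMARTS pattern.
#' @param unique_matches count only symmetry-unique matches (default TRUE).
#' @return Integer vector of match counts, one per molecule.
#' @export
smarts_match_count <- function(smiles, smarts, unique_matches = TRUE) {
  stopifnot(length(smarts) == 1, nzchar(smarts))
  validate_smarts(smarts)
  refs <- .obmol_refs(smiles)
  cnt <- ChemmineOB::smartsSearch_OB(refs, smarts,
                                     uniqueMatches = unique_matches)
  as.integer(unname(cnt))
}

#' Validate a SMARTS pattern
#'
#' @param smarts single SMARTS string.
#' @return Invisibly TRUE; errors if the pattern does not compile.
#' @export
validate_smarts <- function(smarts) {
  probe <- tryCatch({
    refs <- .obmol_refs("C")
    ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!isTRUE(probe)) stop("invalid SMARTS pattern: '", smarts, "'")
  invisible(TRUE)
}
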