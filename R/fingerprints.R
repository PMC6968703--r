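#' Molecular fingerprints and Tanimoto similarity
#'
#' Two fingerprint schemes are provided. The `path` scheme enumerates all
#' simple linear paths of 1-7 heavy atoms in the molecular graph, writes each
#' path as a canonical token string over element symbols (lower-case when
#' aromatic) and bond orders, hashes every distinct path with 32-bit FNV-1a
#' and folds the hash onto 1024 bits. The `keys` scheme is the public
#' 166-key MACCS definition: bit k is set when the molecule has strictly
#' more than the key's minimum count of unique matches of SMARTS pattern k.
#'
#' @name fingerprints
NULL

# scheme registry; hash_version is written into matrix sidecars so persisted
# matrices can be tied to the exact bit semantics that produced them.
.fp_schemes <- list(
  path = list(nbits = 1024L, max_path_atoms = 7L, hash = "fnv1a32/xorfold10"),
  keys = list(nbits = 166L)
)

#' @export
fp_hash_version <- function() .fp_schemes$path$hash

.new_fingerprint <- function(bits, scheme) {
  nbits <- .fp_schemes[[scheme]]$nbits
  bits <- sort(unique(as.integer(bits)))
  stopifnot(all(bits >= 0), all(bits < nbits))
  structure(list(scheme = scheme, nbits = nbits, bits = bits),
            class = "selprof_fp")
}

#' @export
print.selprof_fp <- function(x, ...) {
  cat("<selprof_fp scheme=", x$scheme, " nbits=", x$nbits,
      " popcount=", length(x$bits), ">\n", sep = "")
  invisible(x)
}

# ---- path fingerprint -------------------------------------------------------

# 32-bit FNV-1a over the bytes of a string, in exact double arithmetic
# (R has no unsigned 32-bit integer type). Returns a double in [0, 2^32).
.fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, via 16-bit split to stay within exact doubles
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# fold a 32-bit hash to 10 bits by xoring its 10-bit chunks
.fold10 <- function(h) {
  b1 <- h %% 1024
  b2 <- (h %/% 1024) %% 1024
  b3 <- (h %/% 1048576) %% 1024
  b4 <- h %/% 1073741824          # top 2 bits
  Reduce(bitwXor, as.integer(c(b1, b2, b3, b4)))
}

# canonical token strings for all simple linear paths of 1..max_atoms heavy
# atoms. Each path is reported once, in its lexicographically smaller
# direction. Atom token: element symbol, lower-cased when aromatic; bond
# token: "-", "=", "#", "$" by order, ":" when aromatic.
.enumerate_paths <- function(mol, max_atoms = 7L) {
  n <- length(mol$elements)
  atom_tok <- ifelse(mol$aromatic, tolower(mol$elements), mol$elements)
  if (n == 0) return(character())
  if (nrow(mol$bonds) == 0) return(unique(atom_tok))
  bond_sym <- ifelse(mol$bonds$aromatic, ":",
                     c("-", "=", "#", "$")[pmin(mol$bonds$order, 4L)])
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- rbind(adj[[i]], c(j, k))
    adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  out <- character(0)
  # iterative DFS over simple paths rooted at every atom; `toks` alternates
  # atom and bond tokens, so reversing the token vector reverses the path
  for (root in seq_len(n)) {
    stack <- list(list(path = root, toks = atom_tok[root]))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      fwd <- paste(top$toks, collapse = "")
      bwd <- paste(rev(top$toks), collapse = "")
      out <- c(out, if (fwd <= bwd) fwd else bwd)
      if (length(top$path) < max_atoms) {
        last <- top$path[length(top$path)]
        nb <- adj[[last]]
        for (r in seq_len(NROW(nb))) {
          nxt <- nb[r, 1]
          if (!(nxt %in% top$path)) {
            stack[[length(stack) + 1L]] <- list(
              path = c(top$path, nxt),
              toks = c(top$toks, bond_sym[nb[r, 2]], atom_tok[nxt]))
          }
        }
      }
    }
  }
  unique(out)
}

#' Hashed path fingerprint
#'
#' @param smiles a SMILES string, or a `selprof_mol` from [parse_smiles()].
#' @return A `selprof_fp` with scheme `"path"` (1024 bits).
#' @seealso [key_fingerprint()], [tanimoto()]
#' @examples
#' fp <- path_fingerprint("CCO")
#' length(fp$bits)
#' @export
path_fingerprint <- function(smiles) {
  mol <- if (inherits(smiles, "selprof_mol")) smiles else parse_smiles(smiles)[[1]]
  paths <- .enumerate_paths(mol, .fp_schemes$path$max_path_atoms)
  bits <- vapply(paths, function(p) .fold10(.fnv1a32(p)), integer(1))
  .new_fingerprint(bits, "path")
}

# ---- MACCS key fingerprint --------------------------------------------------

.maccs_env <- new.env(parent = emptyenv())

#' The public MACCS 166-key SMARTS table
#'
#' @return Data frame with columns `key`, `smarts`, `min_count`. Keys whose
#'   pattern is `"?"` (isotope, more-than-one-aromatic-ring,
#'   more-than-one-fragment) fall outside single-SMARTS semantics and are
#'   never set, matching the reference OpenBabel implementation.
#' @export
maccs_keys <- function() {
  if (is.null(.maccs_env$tab)) {
    path <- system.file("extdata", "maccs_keys.tsv", package = "selprof")
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]  # '#' opens comments only at line start;
                                    # inside SMARTS it is an atomic number
    tab <- utils::read.delim(text = paste(ln, collapse = "\n"),
                             stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 166)
    .maccs_env$tab <- tab
  }
  .maccs_env$tab
}

#' MACCS structural-key fingerprint
#'
#' @param smiles character vector of SMILES strings.
#' @return For a single SMILES, a `selprof_fp` with scheme `"keys"`; for a
#'   vector, a list of them. Bit k (0-based index k-1) is set when the
#'   molecule has strictly more than `min_count` unique matches of key k's
#'   SMARTS.
#' @details All 166 SMARTS are matched with OpenBabel's SMARTS engine in one
#'   pass over the molecule list, so vector input is much faster than
#'   repeated single calls.
#' @export
key_fingerprint <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  canon <- canonical_smiles(smiles)
  if (any(!nzchar(canon))) {
    stop("unparsable SMILES: ",
         paste(sprintf("'%s'", smiles[!nzchar(canon)]), collapse = ", "))
  }
  tab <- maccs_keys()
  refs <- .obmol_refs(smiles)
  hits <- matrix(FALSE, length(smiles), 166)
  for (r in seq_len(nrow(tab))) {
    if (tab$smarts[r] == "?") next
    cnt <- ChemmineOB::smartsSearch_OB(refs, tab$smarts[r],
                                       uniqueMatches = TRUE)
    hits[, r] <- as.integer(cnt) > tab$min_count[r]
  }
  fps <- lapply(seq_len(nrow(hits)), function(i)
    .new_fingerprint(which(hits[i, ]) - 1L, "keys"))
  if (length(fps) == 1) fps[[1]] else fps
}

# ---- Tanimoto ---------------------------------------------------------------

#' Tanimoto similarity and distance
#'
#' `tanimoto()` computes Ti = |A intersect B| / |A union B| over the set bits
#' of two fingerprints of the same scheme; `tanimoto_distance()` is
#' Td = 1 - Ti. A pair of all-zero fingerprints has Ti = 0 by convention.
#'
#' @param a,b `selprof_fp` objects of the same scheme.
#' @return A number in `[0, 1]`.
#' @examples
#' tanimoto(path_fingerprint("CCO"), path_fingerprint("CCCO"))
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "selprof_fp"), inherits(b, "selprof_fp"))
  if (!identical(a$scheme, b$scheme)) {
    stop("fingerprint scheme mismatch: ", a$scheme, " vs ", b$scheme)
  }
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(a$bits) + length(b$bits) - ni
  if (nu == 0) return(0)
  ni / nu
}

#' @rdname tanimoto
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto(a, b)

# ---- pairwise matrices ------------------------------------------------------

#' Pairwise Tanimoto similarity and distance matrices
#'
#' Builds the N x N Tanimoto similarity (Ti) and distance (Td = 1 - Ti)
#' matrices over a curated ligand table, under either fingerprint scheme.
#'
#' @param entries a `ligand_table` (see [read_bioactivity_table()] /
#'   [curate()]) or a data frame with columns `cid` and `smiles`.
#' @param scheme `"keys"` (default) or `"path"`.
#' @return A list of class `selprof_matrices` with elements `similarity` and
#'   `distance` (symmetric matrices with `dimnames` = CIDs), `ligand_order`
#'   (CID character vector), `scheme`, and `hash_version`.
#' @export
build_matrices <- function(entries, scheme = c("keys", "path")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(entries), all(c("cid", "smiles") %in% names(entries)),
            nrow(entries) >= 2)
  cids <- as.character(entries$cid)
  bad <- !nzchar(canonical_smiles(entries$smiles))
  if (any(bad)) {
    stop("unparsable SMILES for CID(s): ", paste(cids[bad], collapse = ", "))
  }
  fps <- if (scheme == "keys") {
    key_fingerprint(entries$smiles)
  } else {
    mols <- parse_smiles(entries$smiles)
    lapply(mols, path_fingerprint)
  }
  if (inherits(fps, "selprof_fp")) fps <- list(fps)
  n <- length(fps)
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sim[i, j] <- sim[j, i] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  dimnames(sim) <- list(cids, cids)
  dist <- 1 - sim
  diag(dist) <- 0
  structure(list(similarity = sim, distance = dist, ligand_order = cids,
                 scheme = scheme,
                 hash_version = if (scheme == "path") fp_hash_version() else "maccs166"),
            class = "selprof_matrices")
}

#' Condensed (lower-triangle) form of a pairwise matrix
#'
#' @param m a `selprof_matrices` object.
#' @param kind `"distance"` (default, ready for clustering) or `"similarity"`.
#' @return A `stats::dist` object labelled with the ligand order.
#' @export
condensed_form <- function(m, kind = c("distance", "similarity")) {
  kind <- match.arg(kind)
  stats::as.dist(m[[kind]])
}

#' @export
print.selprof_matrices <- function(x, ...) {
  cat("<selprof_matrices> ", length(x$ligand_order), " ligands, scheme=",
      x$scheme, "\n", sep = "")
  invisible(x)
}

#' Persist / restore pairwise matrices
#'
#' Writes the square similarity and distance matrices as CSV plus a JSON
#' sidecar carrying ligand order, scheme and hash version.
#'
#' @param m a `selprof_matrices` object.
#' @param stem output path stem; files `<stem>_similarity.csv`,
#'   `<stem>_distance.csv` and `<stem>.json` are produced.
#' @return `stem`, invisibly.
#' @export
write_matrices <- function(m, stem) {
  utils::write.csv(m$similarity, paste0(stem, "_similarity.csv"))
  utils::write.csv(m$distance, paste0(stem, "_distance.csv"))
  jsonlite::write_json(
    list(ligand_order = m$ligand_order, scheme = m$scheme,
         hash_version = m$hash_version),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_matrices
#' @export
read_matrices <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  rd <- function(suffix) {
    x <- utils::read.csv(paste0(stem, suffix), row.names = 1,
                         check.names = FALSE)
    as.matrix(x)
  }
  structure(list(similarity = rd("_similarity.csv"),
                 distance = rd("_distance.csv"),
                 ligand_order = as.character(meta$ligand_order),
                 scheme = meta$scheme, hash_version = meta$hash_version),
            class = "selprof_matrices")
}
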