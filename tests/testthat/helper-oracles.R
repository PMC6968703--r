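# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the path enumerator is recursive where the
# implementation is an iterative DFS, and the single-linkage oracle is a
# naive O(n^3) merge loop instead of stats::hclust.

# --- brute-force linear path enumerator (canonical token strings) -----------
oracle_paths <- function(mol, max_atoms = 7) {
  n <- length(mol$elements)
  tok <- ifelse(mol$aromatic, tolower(mol$elements), mol$elements)
  if (n == 0) return(character())
  if (nrow(mol$bonds) == 0) return(unique(tok))
  bsym <- ifelse(mol$bonds$aromatic, ":",
                 c("-", "=", "#", "$")[pmin(mol$bonds$order, 4)])
  edge_sym <- function(a, b) {
    hit <- (mol$bonds$i == a & mol$bonds$j == b) |
           (mol$bonds$i == b & mol$bonds$j == a)
    bsym[which(hit)[1]]
  }
  nbrs <- function(a) {
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
  }
  acc <- character(0)
  extend <- function(path) {
    toks <- character(2 * length(path) - 1)
    toks[seq(1, length(toks), by = 2)] <- tok[path]
    if (length(path) > 1) {
      for (k in seq_len(length(path) - 1)) {
        toks[2 * k] <- edge_sym(path[k], path[k + 1])
      }
    }
    fwd <- paste(toks, collapse = "")
    bwd <- paste(rev(toks), collapse = "")
    acc <<- c(acc, min(fwd, bwd))
    if (length(path) < max_atoms) {
      for (nx in setdiff(nbrs(path[length(path)]), path)) extend(c(path, nx))
    }
  }
  for (root in seq_len(n)) extend(root)
  sort(unique(acc))
}

oracle_path_tanimoto <- function(smiles_a, smiles_b) {
  pa <- oracle_paths(selprof::parse_smiles(smiles_a)[[1]])
  pb <- oracle_paths(selprof::parse_smiles(smiles_b)[[1]])
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# --- naive O(n^3) single-linkage --------------------------------------------
oracle_single_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# --- SMILES atom-order permuter ---------------------------------------------
# Rebuilds the V2000 molblock with shuffled atom indices and converts it
# back to SMILES with OpenBabel, giving a chemically identical SMILES whose
# atom order differs from the input.
permute_smiles <- function(smiles, perm_seed) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab); m <- nrow(bb)
  set.seed(perm_seed)
  perm <- sample(n)              # perm[k] = old index placed at new slot k
  inv <- order(perm)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        ab[perm, 1], ab[perm, 2], 0, elem[perm])
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        inv[bb[, 1]], inv[bb[, 2]], bb[, 3])
  block <- c("", " permuted", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
             atom_lines, bond_lines, "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "SMILES",
                                   paste(block, collapse = "\n"))
  sub("[\t\n ].*$", "", out)
}

# --- shared molecule panel ---------------------------------------------------
# 50 structures: the generator's six scaffold families plus assorted drugs
# and decoy chemotypes.
panel_smiles <- function() {
  series <- selprof::generate_scaffold_series(
    selprof::sim_scenario(n_scaffolds = 6, ligands_per_scaffold = 8))
  extras <- c("c1ccccc1", "CC(=O)Nc1nnc(s1)S(N)(=O)=O")
  c(series$smiles, extras)
}

# random synthetic Td matrix (symmetric, zero diagonal, values in [0,1])
random_td_matrix <- function(n) {
  m <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  m
}
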