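test_that("tanimoto arithmetic follows the bit-set definition", {
  fp <- function(bits, scheme = "keys") selprof:::.new_fingerprint(bits, scheme)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(1, 3))), 1 / 3)
  expect_equal(tanimoto(fp(1:5), fp(1:5)), 1)
  expect_equal(tanimoto(fp(1:2), fp(3:4)), 0)
  expect_equal(tanimoto(fp(integer()), fp(integer())), 0)  # all-zero pair
  expect_equal(tanimoto_distance(fp(c(1, 2)), fp(c(1, 3))), 2 / 3)
  expect_error(tanimoto(fp(1), fp(1, "path")), "scheme mismatch")
})

test_that("path fingerprints match a brute-force path enumerator", {
  # hand-checkable cases first
  expect_equal(tanimoto(path_fingerprint("C"), path_fingerprint("C")), 1)
  expect_equal(tanimoto(path_fingerprint("C"), path_fingerprint("O")), 0)
  # CCO vs CCCO: shared {C, O, C-C, C-O, C-C-O} of 7 distinct paths
  expect_equal(tanimoto(path_fingerprint("CCO"), path_fingerprint("CCCO")),
               5 / 7)
  expect_equal(oracle_path_tanimoto("CCO", "CCCO"), 5 / 7)

  # enumerated path sets agree with the independent recursive oracle
  mols <- parse_smiles(c("CCO", "CC(C)C", "c1ccccc1", "Cc1ccccc1",
                         "NS(=O)(=O)c1ccc(F)cc1", "ClCCBr",
                         "CC(=O)Nc1nnc(s1)S(N)(=O)=O", "C1CC1",
                         "OCC(O)CO", "N#Cc1ccc(cc1)S(N)(=O)=O"))
  for (m in mols) {
    expect_equal(sort(selprof:::.enumerate_paths(m, 7L)), oracle_paths(m),
                 info = m$canonical)
  }
})

test_that("the FNV-1a hash matches published test vectors and folds to range", {
  expect_equal(selprof:::.fnv1a32(""), 2166136261)
  expect_equal(selprof:::.fnv1a32("a"), 3826002220)
  expect_equal(selprof:::.fnv1a32("foobar"), 3214735720)
  bits <- vapply(c("C", "C-C", "c:c", "C-N=O"), function(s)
    selprof:::.fold10(selprof:::.fnv1a32(s)), integer(1))
  expect_true(all(bits >= 0 & bits < 1024))
})

test_that("SMILES spelling and atom order do not change the path fingerprint", {
  base <- c("CCO", "CC(C)CO", "c1ccccc1", "Cc1ccccc1O",
            "NS(=O)(=O)c1ccc(F)cc1", "CC(=O)Nc1nnc(s1)S(N)(=O)=O",
            "OCC1CCCCC1", "ClC(Br)CC#N", "COc1ccc(N)cc1",
            "NS(=O)(=O)Oc1ccccc1")
  for (i in seq_along(base)) {
    ref <- path_fingerprint(base[i])
    refk <- key_fingerprint(base[i])
    for (s in 1:20) {
      alt <- permute_smiles(base[i], perm_seed = 1000 * i + s)
      expect_true(nzchar(alt))
      expect_identical(path_fingerprint(alt)$bits, ref$bits,
                       info = paste(base[i], "->", alt))
      expect_identical(key_fingerprint(alt)$bits, refk$bits,
                       info = paste(base[i], "->", alt))
    }
  }
})

test_that("MACCS key fingerprints equal the reference OpenBabel bits", {
  smis <- panel_smiles()
  expect_gte(length(smis), 50)
  fps <- key_fingerprint(smis)
  refs <- ChemmineOB::forEachMol("SMILES", paste(smis, collapse = "\n"),
                                 identity)
  ref <- ChemmineOB::fingerprint_OB(refs, "MACCS")
  for (i in seq_along(smis)) {
    expect_identical(fps[[i]]$bits, which(ref[i, ] == 1) - 1L, info = smis[i])
    expect_true(all(which(ref[i, ] == 1) <= 166))
  }
  # degenerate one-atom molecules do not crash and carry few bits
  expect_lte(length(key_fingerprint("C")$bits), 2)
  expect_lte(length(key_fingerprint("[He]")$bits), 2)
})

test_that("pairwise matrices agree with direct double-loop tanimoto calls", {
  set.seed(7)
  series <- generate_scaffold_series(sim_scenario(n_scaffolds = 3,
                                                  ligands_per_scaffold = 7))
  pick <- series[sample(nrow(series), 20), c("cid", "smiles")]
  for (scheme in c("keys", "path")) {
    m <- build_matrices(pick, scheme = scheme)
    fps <- if (scheme == "keys") key_fingerprint(pick$smiles) else
      lapply(parse_smiles(pick$smiles), path_fingerprint)
    for (i in 1:19) for (j in (i + 1):20) {
      expect_equal(m$similarity[i, j], tanimoto(fps[[i]], fps[[j]]))
    }
    expect_true(isSymmetric(m$similarity))
    expect_equal(m$distance, 1 - m$similarity, ignore_attr = TRUE)
    expect_equal(unname(diag(m$similarity)), rep(1, 20))
    expect_true(all(m$similarity >= 0 & m$similarity <= 1))
  }
})

test_that("matrix construction flags duplicates, bad SMILES, and round-trips", {
  lt <- data.frame(cid = c("A", "B", "C"),
                   smiles = c("CCO", "OCC", "c1ccccc1"))
  m <- build_matrices(lt, scheme = "path")
  expect_equal(m$similarity["A", "B"], 1)   # same molecule, different spelling
  expect_equal(m$distance["A", "B"], 0)
  expect_error(build_matrices(data.frame(cid = c("A", "B"),
                                         smiles = c("CCO", "xyz(")),
               "B"), class = "simpleError")
  stem <- tempfile()
  write_matrices(m, stem)
  back <- read_matrices(stem)
  expect_equal(back$similarity, m$similarity)
  expect_equal(back$ligand_order, m$ligand_order)
  expect_equal(back$hash_version, m$hash_version)
  # condensed form feeds clustering directly
  d <- condensed_form(m)
  expect_s3_class(d, "dist")
  expect_equal(attr(d, "Size"), 3L)
})
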