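test_that("pair-subset selection keeps only dually measured ligands", {
  lt <- ligand_table(
    cid = paste0("L", 1:15),
    smiles = rep("NS(=O)(=O)c1ccccc1", 15),
    ki = data.frame(`hCA IX` = c(rep(5, 10), rep(NA, 5)),
                    `hCA II` = c(rep(50, 12), NA, NA, NA),
                    `hCA XII` = c(rep(4, 9), rep(NA, 6)),
                    check.names = FALSE))
  cfg <- selectivity_config("hCA IX", "hCA II")
  expect_equal(nrow(select_pair_subset(lt, cfg)), 10)
  all_measured <- lt[1:9, ]
  expect_equal(select_pair_subset(all_measured, cfg), all_measured)
  dbl <- selectivity_config("hCA IX", "hCA II",
                            secondary_on_target = "hCA XII")
  expect_equal(select_pair_subset(lt, dbl)$cid, paste0("L", 1:9))
  expect_error(select_pair_subset(lt, selectivity_config("hCA IX", "hCA XIV")),
               "hCA XIV")
  expect_error(select_pair_subset(lt[13:15, ], cfg), "fewer than two")
})

test_that("the Ti-SR table enumerates each unordered pair once", {
  sim <- simulate_bioactivity(sim_scenario(seed = 21, decoy_rate = 0))
  cfg <- selectivity_config("hCA IX", "hCA II")
  entries <- select_pair_subset(curate(sim$records), cfg)
  m <- build_matrices(entries, scheme = "keys")
  pt <- ti_sr_table(entries, m, cfg)
  n <- nrow(entries)
  expect_equal(nrow(pt), n * (n - 1) / 2)
  # direct double-loop recomputation
  sel <- ligand_selectivity(entries, cfg)
  for (r in sample(nrow(pt), 25)) {
    i <- match(pt$cid_a[r], sel$cid); j <- match(pt$cid_b[r], sel$cid)
    expect_equal(pt$ti[r], m$similarity[i, j])
    expect_equal(pt$sr[r], log10(sel$si[i]) - log10(sel$si[j]))
  }
  # identical SI everywhere collapses SR to zero
  flat <- entries
  flat[["hCA IX"]] <- 10; flat[["hCA II"]] <- 10
  expect_equal(ti_sr_table(flat, m, cfg)$sr, rep(0, n * (n - 1) / 2))
})

test_that("the SR envelope narrows with structural similarity on planted data", {
  sim <- simulate_bioactivity(sim_scenario(seed = 31, decoy_rate = 0))
  prof <- selectivity_profile(sim$records,
                              selectivity_config("hCA IX", "hCA II"))
  env <- sr_envelope(prof$pair_table)
  expect_equal(nrow(env), 3)
  expect_equal(sum(env$n), nrow(prof$pair_table))
  hi <- env$max_abs_sr[env$bin == "(0.8,1]"]
  lo <- env$max_abs_sr[env$bin == "[0,0.4]"]
  expect_lte(hi, lo)
  # degenerate inputs: constant-Ti table, empty high bin
  pt <- data.frame(cid_a = "a", cid_b = "b", ti = 0.9, sr = 0)
  env <- sr_envelope(pt)
  expect_equal(env$max_abs_sr[env$bin == "(0.8,1]"], 0)
  expect_equal(env$n[env$bin == "[0,0.4]"], 0)
  expect_true(is.na(env$max_abs_sr[env$bin == "[0,0.4]"]))
})

test_that("cluster scoring counts classes and applies both score formulas", {
  mk_sel <- function(cid, si) data.frame(cid = cid, si = si,
                                         klass = classify(si),
                                         stringsAsFactors = FALSE)
  cids <- sprintf("L%02d", 1:41)
  rep41 <- score_clusters(list(cids), mk_sel(cids, rep(30, 41)))
  expect_equal(rep41$n_on, 41)
  expect_equal(rep41$s_score, 100)
  mixed <- score_clusters(list(paste0("M", 1:10)),
                          mk_sel(paste0("M", 1:10), c(rep(30, 5), rep(0.1, 5))))
  expect_equal(mixed$s_score, 0)
  dbl <- score_clusters(list(cids), mk_sel(cids, rep(30, 41)),
                        mk_sel(cids, rep(273, 41)))
  expect_equal(dbl$double_s_score, 200)
  expect_error(score_clusters(list(c("L01", "GHOST")),
                              mk_sel("L01", 30)), "GHOST")
})

test_that("selective-cluster extraction is strict and sorted", {
  mk_rep <- function(scores) {
    sel <- data.frame(cid = "x", si = 1, klass = "L_ns")
    r <- data.frame(cluster_id = seq_along(scores), s_score = scores)
    r$members <- as.list(rep("x", length(scores)))
    class(r) <- c("cluster_report", "data.frame")
    r
  }
  cfg <- selectivity_config("hCA IX", "hCA II")
  out <- select_selective_clusters(mk_rep(c(100, 71, 70, -100)), cfg)
  expect_equal(out$s_score, c(100, 71))
  cfg0 <- selectivity_config("hCA IX", "hCA II", s_score_cutoff = 0)
  expect_equal(select_selective_clusters(mk_rep(c(-5, 5, 0)), cfg0)$s_score, 5)
  # double mode: strictly above twice the cutoff
  r <- mk_rep(c(100, 80, 60))
  r$s_score_secondary <- c(100, 70, 60)
  r$double_s_score <- r$s_score + r$s_score_secondary
  expect_equal(select_selective_clusters(r, cfg)$double_s_score, c(200, 150))
})

test_that("the full pipeline recovers the planted selective family", {
  sim <- simulate_bioactivity(sim_scenario(seed = 41))
  cfg <- selectivity_config("hCA IX", "hCA II")
  prof <- selectivity_profile(sim$records, cfg)
  truth <- sim$truth
  on_cids <- truth$cid[truth$planted_class == "on_selective"]
  prom_cids <- truth$cid[truth$planted_class == "promiscuous"]
  sel_members <- unlist(prof$selective$members)
  expect_gte(nrow(prof$selective), 1)
  expect_true(any(on_cids %in% sel_members))
  expect_false(any(prom_cids %in% sel_members))
  # count conservation over the cut partition
  expect_equal(sum(lengths(cut_at_height_ratio(prof$dendrogram, prof$cut))),
               nrow(prof$entries))
  # a profile with only non-selective ligands reports nothing
  flat <- simulate_bioactivity(
    sim_scenario(seed = 42, scaffold_classes = rep("promiscuous", 3)))
  prof0 <- selectivity_profile(flat$records, cfg)
  expect_equal(nrow(prof0$selective), 0)
})

test_that("profiles are deterministic and serialise completely", {
  sim <- simulate_bioactivity(sim_scenario(seed = 51))
  cfg <- selectivity_config("hCA IX", "hCA II")
  d1 <- file.path(tempdir(), "p1"); d2 <- file.path(tempdir(), "p2")
  write_profile(selectivity_profile(sim$records, cfg), d1)
  write_profile(selectivity_profile(sim$records, cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_true(file.exists(file.path(d1, "selprof_selective_clusters.csv")))
  expect_true(file.exists(file.path(d1, "selprof_audit.csv")))
})

test_that("double-selectivity mode scores clusters against both on-targets", {
  sc <- sim_scenario(seed = 61, secondary_on_target = "hCA XII")
  sim <- simulate_bioactivity(sc)
  cfg <- selectivity_config("hCA IX", "hCA II",
                            secondary_on_target = "hCA XII")
  prof <- selectivity_profile(sim$records, cfg)
  expect_true(all(c("s_score_secondary", "double_s_score")
                  %in% names(prof$reports)))
  truth <- sim$truth
  on_cl <- vapply(prof$reports$members, function(m)
    all(m %in% truth$cid[truth$planted_class == "on_selective"]), logical(1))
  expect_equal(prof$reports$double_s_score[on_cl], 200)
  expect_true(all(prof$selective$double_s_score > 140))
  expect_null(prof$pair_table)  # SR only defined in single-pair mode
})
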