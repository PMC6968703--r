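test_that("metric and provenance filters keep exactly the configured records", {
  rows <- tiny_bioactivity_rows()[rep(1, 8), ]
  rows$cid <- paste0("C", 1:8)
  rows$metric <- c(rep("Ki", 5), rep("IC50", 3))
  tab <- read_bioactivity_table(write_bioactivity_csv(rows))
  kept <- filter_by_metric(tab, curation_config())
  expect_equal(nrow(kept), 5)
  expect_equal(as.integer(attr(kept, "removed_by_metric")[["IC50"]]), 3)
  expect_warning(filter_by_metric(tab[tab$metric == "IC50", ],
                                  curation_config()), "no records")

  rows$metric <- "Ki"
  rows$pmid <- c(rep("PLAB", 6), "PFOREIGN1", "PFOREIGN2")
  tab <- read_bioactivity_table(write_bioactivity_csv(rows))
  expect_equal(nrow(filter_by_provenance(tab, curation_config())), 8)
  kept <- filter_by_provenance(tab, curation_config(pmid_whitelist = "PLAB"))
  expect_equal(kept$pmid, rep("PLAB", 6))
  expect_warning(
    out <- filter_by_provenance(tab, curation_config(pmid_whitelist = "X")),
    "no records")
  expect_equal(nrow(out), 0)
})

test_that("replicate aggregation averages after outlier removal", {
  expect_equal(aggregate_ki(7), 7)
  expect_equal(aggregate_ki(c(10, 12, 11)), 11)
  # gross x1e4 outlier: modified z on log10 far beyond 3.5, mean of the rest
  expect_equal(aggregate_ki(c(10, 10, 10, 10, 1e5)), 10)
  expect_equal(aggregate_ki(c(5, 7)), 6)
  expect_error(aggregate_ki(numeric(0)), "no replicate")
  expect_error(aggregate_ki(c(1, -2)))
  # alternative rules
  expect_equal(aggregate_ki(c(10, 10, 10, 10, 1e5),
                            curation_config(outlier_rule = "none")), 20008)
  expect_equal(aggregate_ki(c(1, 10, 100),
                            curation_config(outlier_rule = "trim-fraction",
                                            trim_fraction = 0.34)), 10)
  expect_equal(aggregate_ki(c(1, 100),
                            curation_config(mean_type = "geometric")), 10)
})

test_that("aggregation is permutation-invariant and scale-equivariant", {
  set.seed(42)
  for (rep in 1:10) {
    v <- 10^stats::runif(sample(3:8, 1), 0, 3)
    expect_equal(aggregate_ki(sample(v)), aggregate_ki(v))
    c0 <- stats::runif(1, 0.1, 50)
    expect_equal(aggregate_ki(c0 * v), c0 * aggregate_ki(v))
  }
})

test_that("substructure filter keeps sulfonamide-type zinc binders only", {
  lt <- ligand_table(
    cid = c("benzene", "acetazolamide", "sulfamate", "sulfamide", "amide"),
    smiles = c("c1ccccc1", "CC(=O)Nc1nnc(s1)S(N)(=O)=O",
               "NS(=O)(=O)Oc1ccccc1", "NS(=O)(=O)Nc1ccccc1",
               "CC(=O)Nc1ccccc1"),
    ki = data.frame(`hCA IX` = rep(10, 5), check.names = FALSE))
  out <- substructure_filter(lt, curation_config())
  expect_setequal(out$cid, c("acetazolamide", "sulfamate", "sulfamide"))
  # independent check of the default SMARTS with OpenBabel's matcher
  cnt <- smarts_match_count(lt$smiles, "[#16](=[OX1])(=[OX1])[NX3]")
  expect_equal(cnt > 0, lt$cid %in% out$cid)
  expect_error(curation_config(substructure_smarts = "[#16(=="), "invalid SMARTS")
})

test_that("curate applies the stage order and keeps a conserving audit", {
  sim <- simulate_bioactivity(sim_scenario(seed = 11))
  entries <- curate(sim$records)
  audit <- attr(entries, "audit")
  expect_equal(audit$stage,
               c("metric", "provenance", "aggregation", "merge", "substructure"))
  expect_equal(audit$records_in - audit$records_out, audit$removed)
  # stage handoff: each stage consumes what the previous one produced
  expect_equal(audit$records_in[-1], audit$records_out[-nrow(audit)])
  # decoy bookkeeping: wrong-metric records die at the metric stage,
  # non-sulfonamide compounds at the substructure stage
  truth <- sim$truth
  expect_equal(audit$removed[audit$stage == "metric"],
               sum(sim$records$metric != "Ki"))
  expect_equal(audit$removed[audit$stage == "substructure"],
               length(unique(truth$cid[truth$planted_class == "decoy_structure"])))
  core <- truth$cid[truth$scaffold != "decoy"]
  expect_setequal(entries$cid, core)

  # two AIDs for the same (cid, target) with 5 and 7 -> one entry with Ki 6
  rows <- tiny_bioactivity_rows()[c(1, 1), ]
  rows$value_nM <- c(5, 7); rows$aid <- c("A1", "A2")
  ent <- curate(read_bioactivity_table(write_bioactivity_csv(rows)))
  expect_equal(nrow(ent), 1)
  expect_equal(ent[["hCA IX"]], 6)
})

test_that("curation is monotone: no stage invents ligands", {
  sim <- simulate_bioactivity(sim_scenario(seed = 3, decoy_rate = 0.2))
  rec <- sim$records
  r1 <- filter_by_metric(rec, curation_config())
  expect_true(all(r1$cid %in% rec$cid))
  entries <- curate(rec)
  expect_true(all(entries$cid %in% rec$cid))
  # audit conservation at ingestion level too
  expect_equal(nrow(rec),
               attr(entries, "audit")$records_in[1])
})
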