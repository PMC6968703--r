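#' Synthetic bioactivity scenario
#'
#' Describes a simulated structure-selectivity experiment: a handful of
#' sulfonamide scaffold families, each carrying a planted selectivity class,
#' decorated with small R-groups and measured in replicate against the
#' configured isoforms with log-normal noise, occasional outliers and decoy
#' records.
#'
#' @param n_scaffolds number of scaffold families (default 3).
#' @param ligands_per_scaffold ligands enumerated per family (default 8,
#'   maximum 12 - the R-group vocabulary).
#' @param scaffold_classes planted class per scaffold, recycled over
#'   `c("on_selective", "off_selective", "promiscuous")`.
#' @param si_offset planted |log10 SI| for the selective classes (default
#'   1.5, i.e. a true SI of about 31.6 or its reciprocal).
#' @param noise_sd replicate noise standard deviation in log10 Ki units
#'   (default 0.15).
#' @param outlier_rate per-replicate probability of a x100 gross error
#'   (default 0.05).
#' @param decoy_rate decoy records as a fraction of core records (default
#'   0.1); decoys are either sulfonamides reported with a non-Ki metric or
#'   non-sulfonamide compounds with Ki values.
#' @param replicate_counts integer vector the per-(ligand, isoform)
#'   replicate count is drawn from (default `3:6`).
#' @param on_target,off_target,secondary_on_target isoform labels measured
#'   in the scenario (defaults `"hCA IX"` vs `"hCA II"`; the secondary
#'   on-target, e.g. `"hCA XII"`, is only measured when set).
#' @param seed RNG seed; the whole scenario is deterministic given it.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_scaffolds = 3, ligands_per_scaffold = 8,
                         scaffold_classes = NULL, si_offset = 1.5,
                         noise_sd = 0.15, outlier_rate = 0.05,
                         decoy_rate = 0.1, replicate_counts = 3:6,
                         on_target = "hCA IX", off_target = "hCA II",
                         secondary_on_target = NULL, seed = 1) {
  stopifnot(n_scaffolds >= 1, ligands_per_scaffold >= 1,
            ligands_per_scaffold <= 12, noise_sd > 0,
            outlier_rate >= 0, outlier_rate <= 1,
            decoy_rate >= 0, decoy_rate <= 1)
  if (is.null(scaffold_classes)) {
    scaffold_classes <- rep(c("on_selective", "off_selective", "promiscuous"),
                            length.out = n_scaffolds)
  }
  stopifnot(length(scaffold_classes) == n_scaffolds,
            all(scaffold_classes %in%
                  c("on_selective", "off_selective", "promiscuous")))
  structure(list(n_scaffolds = n_scaffolds,
                 ligands_per_scaffold = ligands_per_scaffold,
                 scaffold_classes = scaffold_classes, si_offset = si_offset,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 decoy_rate = decoy_rate, replicate_counts = replicate_counts,
                 on_target = on_target, off_target = off_target,
                 secondary_on_target = secondary_on_target,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# sulfonamide-bearing scaffold templates; `{R}` marks the attachment point.
.sim_templates <- c(
  "NS(=O)(=O)c1ccc({R})cc1",             # benzenesulfonamide
  "NS(=O)(=O)Oc1ccc(NC(=O)N{R})cc1",     # phenyl sulfamate with ureido tail
  "CC(=O)Nc1nnc(s1)S(N)(=O)=O{X}",       # acetazolamide-like (no open valence)
  "NS(=O)(=O)c1ccc(cc1)-c1ccc({R})cc1",  # biphenylsulfonamide
  "NS(=O)(=O)Cc1ccc({R})cc1",            # benzylsulfonamide
  "NS(=O)(=O)c1ccc({R})s1"               # thiophene-2-sulfonamide
)

# R-group vocabulary (kept small so brute-force fingerprint oracles stay
# cheap); all valid as a branch on an aromatic or aliphatic carbon.
.sim_substituents <- c("F", "Cl", "Br", "I", "C", "CC", "CCC", "C(C)C",
                       "OC", "OCC", "C#N", "C(F)(F)F")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Enumerate the scaffold series of a scenario
#'
#' Each scaffold template carries a sulfonamide-type zinc-binding group and
#' an attachment point that is substituted with small R-groups (halogens,
#' alkyl, alkoxy, nitrile, ...). The third template is a fixed bicyclic
#' sulfonamide whose members vary by an N-acyl R-group.
#'
#' @param scenario a [sim_scenario()].
#' @return Data frame `cid, smiles, scaffold, planted_class`, one row per
#'   ligand; all SMILES are guaranteed parsable.
#' @export
generate_scaffold_series <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  rows <- list()
  for (s in seq_len(scenario$n_scaffolds)) {
    tmpl <- .sim_templates[(s - 1) %% length(.sim_templates) + 1]
    subs <- .sim_substituents[seq_len(scenario$ligands_per_scaffold)]
    smiles <- if (grepl("{X}", tmpl, fixed = TRUE)) {
      # closed-valence template: graft the R-group through an amide nitrogen
      core <- sub("{X}", "", tmpl, fixed = TRUE)
      vapply(subs, function(r) sub("CC(=O)N", paste0(r, "C(=O)N"), core,
                                   fixed = TRUE), character(1))
    } else {
      vapply(subs, function(r) sub("{R}", r, tmpl, fixed = TRUE), character(1))
    }
    rows[[s]] <- data.frame(
      cid = sprintf("CID%d%02d", s, seq_along(smiles)),
      smiles = unname(smiles), scaffold = sprintf("scaffold%d", s),
      planted_class = scenario$scaffold_classes[s], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- nzchar(canonical_smiles(out$smiles))
  if (!all(ok)) stop("generator produced unparsable SMILES: ",
                     paste(out$smiles[!ok], collapse = ", "))
  out
}

#' Assign simulated Ki measurements to a scaffold series
#'
#' log10 Ki(ligand, isoform) = scaffold base potency + planted selectivity
#' offset (applied to the on-target(s) of selective scaffolds) + a fixed
#' per-ligand jitter + per-replicate noise. Gross outliers multiply a
#' replicate by 100 at `outlier_rate`; decoy records (wrong assay metric, or
#' a non-sulfonamide structure) are appended at `decoy_rate`.
#'
#' @param series output of [generate_scaffold_series()].
#' @param scenario the same [sim_scenario()].
#' @return A `bioactivity_table` with attribute `truth`: one row per ligand
#'   (including decoys) with its scaffold, planted class and true mean Ki
#'   per isoform (`NA` for decoys).
#' @export
assign_ki <- function(series, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  isoforms <- c(scenario$off_target, scenario$on_target,
                scenario$secondary_on_target)
  .with_seed(scenario$seed, {
    scaffolds <- unique(series$scaffold)
    base <- stats::runif(length(scaffolds), 1, 2)  # 10-100 nM core potency
    names(base) <- scaffolds
    jitter <- stats::rnorm(nrow(series), 0, 0.1)
    offset_of <- function(class, iso) {
      if (iso == scenario$off_target) return(0)
      switch(class, on_selective = -scenario$si_offset,
             off_selective = scenario$si_offset, promiscuous = 0)
    }
    true_log <- sapply(isoforms, function(iso) {
      base[series$scaffold] + jitter +
        vapply(series$planted_class, offset_of, numeric(1), iso = iso)
    })
    true_log <- matrix(true_log, nrow = nrow(series),
                       dimnames = list(series$cid, isoforms))
    recs <- list(); aid <- 0L
    for (i in seq_len(nrow(series))) {
      for (iso in isoforms) {
        k <- sample(scenario$replicate_counts, 1)
        logv <- true_log[i, iso] + stats::rnorm(k, 0, scenario$noise_sd)
        val <- 10^logv
        out <- stats::runif(k) < scenario$outlier_rate
        val[out] <- val[out] * 100
        aid <- aid + k
        recs[[length(recs) + 1L]] <- data.frame(
          cid = series$cid[i], smiles = series$smiles[i], target = iso,
          metric = "Ki", value_nM = val,
          aid = sprintf("AID%05d", seq(aid - k + 1, aid)),
          pmid = "PMID_CORE", stringsAsFactors = FALSE)
      }
    }
    core <- do.call(rbind, recs)
    truth <- data.frame(series,
                        as.data.frame(10^true_log, check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
    # decoys: half wrong-metric sulfonamides, half Ki-measured non-sulfonamides
    n_decoy <- round(scenario$decoy_rate * nrow(core))
    if (n_decoy > 0) {
      drec <- list(); d <- 0L
      while (Reduce(`+`, lapply(drec, nrow), 0) < n_decoy) {
        d <- d + 1L
        sub <- .sim_substituents[(d - 1) %% length(.sim_substituents) + 1]
        if (d %% 2 == 1) {
          smi <- sub("{R}", sub, "CNS(=O)(=O)c1ccc({R})cc1", fixed = TRUE)
          metric <- "IC50"; kind <- "decoy_metric"
        } else {
          smi <- sub("{R}", sub, "OC(=O)c1ccc({R})cc1", fixed = TRUE)
          metric <- "Ki"; kind <- "decoy_structure"
        }
        val <- 10^stats::runif(2, 1, 3)
        aid <- aid + 2L
        drec[[d]] <- data.frame(
          cid = sprintf("DEC%03d", d), smiles = smi,
          target = sample(isoforms, 1), metric = metric, value_nM = val,
          aid = sprintf("AID%05d", seq(aid - 1, aid)), pmid = "PMID_CORE",
          kind = kind, stringsAsFactors = FALSE)
      }
      decoys <- do.call(rbind, drec)
      decoys <- decoys[seq_len(n_decoy), , drop = FALSE]
      dt <- unique(decoys[, c("cid", "smiles", "kind")])
      dtr <- data.frame(cid = dt$cid, smiles = dt$smiles, scaffold = "decoy",
                        planted_class = dt$kind, stringsAsFactors = FALSE)
      for (iso in isoforms) dtr[[iso]] <- NA_real_
      truth <- rbind(truth, dtr)
      core <- rbind(core, decoys[, names(core)])
    }
    class(core) <- c("bioactivity_table", "data.frame")
    attr(core, "truth") <- truth
    core
  })
}

#' Simulate a complete bioactivity fixture
#'
#' @param scenario a [sim_scenario()].
#' @return List with `records` (a `bioactivity_table`) and `truth` (the
#'   ground-truth sidecar data frame).
#' @export
simulate_bioactivity <- function(scenario = sim_scenario()) {
  series <- generate_scaffold_series(scenario)
  records <- assign_ki(series, scenario)
  list(records = records, truth = attr(records, "truth"))
}

#' Write a simulated fixture and its ground truth
#'
#' @param sim output of [simulate_bioactivity()] (or a `bioactivity_table`
#'   with a `truth` attribute).
#' @param path CSV path for the bioactivity table; the ground truth is
#'   written next to it as `<path minus .csv>_truth.csv`.
#' @return Character vector `c(records = path, truth = truth_path)`,
#'   invisibly.
#' @export
write_fixture <- function(sim, path) {
  if (inherits(sim, "bioactivity_table")) {
    sim <- list(records = sim, truth = attr(sim, "truth"))
  }
  write.csv(sim$records, path, row.names = FALSE, na = "")
  tpath <- sub("\\.csv$", "", path)
  tpath <- paste0(tpath, "_truth.csv")
  write.csv(sim$truth, tpath, row.names = FALSE, na = "")
  invisible(c(records = path, truth = tpath))
}
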