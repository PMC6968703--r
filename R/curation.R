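#' Curation configuration
#'
#' Controls the four curation stages applied to a raw bioactivity table:
#' assay-metric filtering, publication-provenance filtering, replicate
#' aggregation with outlier removal, and zinc-binding-group substructure
#' filtering.
#'
#' @param metric_keep character vector of assay metrics to retain
#'   (default `"Ki"`).
#' @param pmid_whitelist optional character vector of publication IDs; when
#'   given, only records from these publications survive. NULL disables the
#'   provenance filter.
#' @param outlier_rule `"modified-z"` (default), `"trim-fraction"` or
#'   `"none"`.
#' @param outlier_zmax modified z-score threshold on log10(Ki) (default 3.5).
#' @param trim_fraction fraction trimmed from each tail under the
#'   `"trim-fraction"` rule (default 0.1).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` averaging of
#'   the surviving replicate values.
#' @param substructure_smarts SMARTS the curated ligands must match; the
#'   default `[#16](=[OX1])(=[OX1])[NX3]` covers primary/secondary
#'   sulfonamides and also sulfamates and sulfamides, the classical
#'   zinc-binding groups.
#' @param min_value_nM,max_value_nM optional sanity bounds on single
#'   measurements (nM).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(metric_keep = "Ki", pmid_whitelist = NULL,
                            outlier_rule = c("modified-z", "trim-fraction", "none"),
                            outlier_zmax = 3.5, trim_fraction = 0.1,
                            mean_type = c("arithmetic", "geometric"),
                            substructure_smarts = "[#16](=[OX1])(=[OX1])[NX3]",
                            min_value_nM = NULL, max_value_nM = NULL) {
  outlier_rule <- match.arg(outlier_rule)
  mean_type <- match.arg(mean_type)
  stopifnot(outlier_zmax > 0, trim_fraction >= 0, trim_fraction < 0.5,
            all(metric_keep %in% .metrics))
  validate_smarts(substructure_smarts)
  structure(list(metric_keep = metric_keep, pmid_whitelist = pmid_whitelist,
                 outlier_rule = outlier_rule, outlier_zmax = outlier_zmax,
                 trim_fraction = trim_fraction, mean_type = mean_type,
                 substructure_smarts = substructure_smarts,
                 min_value_nM = min_value_nM, max_value_nM = max_value_nM),
            class = "curation_config")
}

#' Filter records by assay metric
#'
#' Retains only measurements whose metric (Ki, IC50, ...) is in
#' `config$metric_keep`; different assay metrics are not comparable, so the
#' default keeps Ki only.
#'
#' @param records a `bioactivity_table`.
#' @param config a [curation_config()].
#' @return The filtered `bioactivity_table`; removed-per-metric counts in
#'   attribute `removed_by_metric`.
#' @export
filter_by_metric <- function(records, config = curation_config()) {
  keep <- records$metric %in% config$metric_keep
  removed <- table(records$metric[!keep])
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no records left after metric filter")
  attr(out, "removed_by_metric") <- removed
  out
}

#' Filter records by publication provenance
#'
#' When a PMID whitelist is configured, keeps only measurements published in
#' those papers (typically: a single laboratory, to minimise inter-assay
#' bias). Without a whitelist this is a pass-through.
#'
#' @inheritParams filter_by_metric
#' @return The filtered `bioactivity_table`.
#' @export
filter_by_provenance <- function(records, config = curation_config()) {
  if (is.null(config$pmid_whitelist)) return(records)
  keep <- records$pmid %in% config$pmid_whitelist
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no records left after provenance filter")
  out
}

# modified z-score on log10 values: 0.6745 (x - median) / MAD. With MAD = 0
# (all replicates equal up to the outliers), fall back to mean absolute
# deviation as is conventional for this statistic.
.modified_z <- function(logv) {
  med <- stats::median(logv)
  mad0 <- stats::median(abs(logv - med))
  if (mad0 > 0) return(0.6745 * (logv - med) / mad0)
  meanad <- mean(abs(logv - med))
  if (meanad == 0) return(rep(0, length(logv)))
  (logv - med) / (1.253314 * meanad)
}

#' Aggregate replicate Ki measurements
#'
#' Averages the replicate Ki values of one (compound, isoform) pair after
#' outlier removal. The default rule flags replicates whose modified z-score
#' on log10(Ki) exceeds `outlier_zmax` (log scale, because Ki error is
#' multiplicative), then takes the arithmetic mean of the surviving raw nM
#' values. If outlier removal would discard everything, the median of the
#' original values is returned instead.
#'
#' @param values positive numeric vector of replicate Ki values (nM).
#' @param config a [curation_config()].
#' @return A single mean Ki in nM.
#' @examples
#' aggregate_ki(c(10, 12, 11))
#' aggregate_ki(c(10, 10, 10, 10, 1e5))  # the outlier is dropped
#' @export
aggregate_ki <- function(values, config = curation_config()) {
  if (length(values) == 0) stop("no replicate values to aggregate")
  stopifnot(all(values > 0))
  keep <- switch(config$outlier_rule,
    "none" = rep(TRUE, length(values)),
    "modified-z" = abs(.modified_z(log10(values))) <= config$outlier_zmax,
    "trim-fraction" = {
      k <- floor(config$trim_fraction * length(values))
      rk <- rank(values, ties.method = "first")
      rk > k & rk <= length(values) - k
    })
  if (!any(keep)) return(stats::median(values))
  v <- values[keep]
  if (config$mean_type == "geometric") exp(mean(log(v))) else mean(v)
}

#' Zinc-binding-group substructure filter
#'
#' Keeps only ligands whose structure matches the configured SMARTS pattern
#' (by default the sulfonamide S(=O)(=O)N motif, which also covers sulfamate
#' and sulfamide zinc-binding groups). Ligands whose SMILES cannot be parsed
#' are removed with a diagnostic rather than erroring.
#'
#' @param entries a `ligand_table`.
#' @param config a [curation_config()].
#' @return The filtered `ligand_table`; attribute `unparsable` lists CIDs
#'   whose SMILES failed to parse.
#' @export
substructure_filter <- function(entries, config = curation_config()) {
  canon <- canonical_smiles(entries$smiles)
  parsable <- nzchar(canon)
  matched <- rep(FALSE, nrow(entries))
  if (any(parsable)) {
    cnt <- smarts_match_count(entries$smiles[parsable],
                              config$substructure_smarts)
    matched[parsable] <- cnt > 0
  }
  out <- entries[matched, , drop = FALSE]
  attr(out, "unparsable") <- entries$cid[!parsable]
  class(out) <- class(entries)
  out
}

#' Curate a raw bioactivity table into a ligand table
#'
#' Runs the full curation pipeline in a fixed order: metric filter,
#' provenance filter, per-(compound, isoform) replicate aggregation, merge
#' of the per-isoform means into one wide row per compound, and finally the
#' zinc-binding-group substructure filter. SMILES are canonicalised in the
#' merged table; compounds whose records carry conflicting SMILES are kept
#' (first record wins) and flagged in the audit rather than silently
#' resolved.
#'
#' @param records a `bioactivity_table` from [read_bioactivity_table()].
#' @param config a [curation_config()].
#' @return A `ligand_table` with attributes `audit` (data frame
#'   `stage, records_in, records_out, removed` counting survivors of every
#'   stage) and `smiles_conflicts` (CIDs with conflicting SMILES spellings
#'   across records, after canonicalisation).
#' @export
curate <- function(records, config = curation_config()) {
  audit <- list()
  note <- function(stage, n_in, n_out) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, records_in = n_in, records_out = n_out,
      removed = n_in - n_out, stringsAsFactors = FALSE)
  }
  n0 <- nrow(records)
  r1 <- filter_by_metric(records, config); note("metric", n0, nrow(r1))
  r2 <- filter_by_provenance(r1, config); note("provenance", nrow(r1), nrow(r2))
  if (!is.null(config$min_value_nM)) r2 <- r2[r2$value_nM >= config$min_value_nM, ]
  if (!is.null(config$max_value_nM)) r2 <- r2[r2$value_nM <= config$max_value_nM, ]
  if (nrow(r2) == 0) stop("no records survive curation filters")

  # replicate aggregation per (cid, target), in order of first appearance
  key <- factor(paste(r2$cid, r2$target, sep = "\x1f"),
                levels = unique(paste(r2$cid, r2$target, sep = "\x1f")))
  agg <- vapply(split(r2$value_nM, key), aggregate_ki, numeric(1),
                config = config)
  first <- r2[!duplicated(key), c("cid", "target", "smiles")]
  agg_tab <- data.frame(cid = first$cid, target = first$target,
                        smiles = first$smiles, ki = unname(agg),
                        stringsAsFactors = FALSE)
  note("aggregation", nrow(r2), nrow(agg_tab))

  # canonicalise SMILES and detect conflicting structures per CID
  agg_tab$canonical <- canonical_smiles(agg_tab$smiles)
  conflicts <- unique(agg_tab$cid[ave(agg_tab$canonical, agg_tab$cid,
                                      FUN = function(x) length(unique(x))) > 1])
  # merge per CID into wide form
  cids <- unique(agg_tab$cid)
  isoforms <- unique(agg_tab$target)
  ki <- matrix(NA_real_, length(cids), length(isoforms),
               dimnames = list(cids, isoforms))
  ki[cbind(match(agg_tab$cid, cids), match(agg_tab$target, isoforms))] <-
    agg_tab$ki
  smiles <- agg_tab$canonical[match(cids, agg_tab$cid)]
  entries <- ligand_table(cids, smiles,
                          as.data.frame(ki, check.names = FALSE))
  note("merge", nrow(agg_tab), nrow(entries))

  out <- substructure_filter(entries, config)
  note("substructure", nrow(entries), nrow(out))

  attr(out, "audit") <- do.call(rbind, audit)
  attr(out, "smiles_conflicts") <- conflicts
  out
}

#' Write a curation audit log
#'
#' @param entries a curated `ligand_table` (with an `audit` attribute).
#' @param path output CSV path.
#' @export
write_audit <- function(entries, path) {
  audit <- attr(entries, "audit")
  if (is.null(audit)) stop("no audit attribute on this table")
  write.csv(audit, path, row.names = FALSE)
  invisible(path)
}
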