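#' @importFrom utils read.csv write.csv read.delim
NULL

.metrics <- c("Ki", "IC50", "Kd", "Km", "EC50")
.required_cols <- c("cid", "smiles", "target", "metric", "value_nM", "aid")

#' Read a bioactivity table
#'
#' Ingests a CSV/TSV of raw assay measurements in the schema
#' `cid, smiles, target, metric, value_nM, aid[, pmid][, units]`. Each row is
#' one measurement of one compound against one isoform. Malformed rows
#' (missing compound ID, SMILES, target or value; non-positive or unparsable
#' value; unknown metric) are rejected individually and reported in the
#' `diagnostics` attribute, so that
#' `nrow(result) + nrow(attr(result, "diagnostics"))` always equals the
#' data-row count of the file.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`; default guessed from the extension.
#' @param column_map optional named character vector mapping the canonical
#'   column names to the names actually used in the file, e.g.
#'   `c(cid = "CID", value_nM = "ki_nm")`.
#' @param strict if TRUE, any rejected row is promoted to an error.
#' @return A data frame of class `bioactivity_table` with character columns
#'   `cid`, `smiles`, `target`, `metric`, `aid`, `pmid` (NA when absent) and
#'   numeric `value_nM` (nanomolar). Attribute `diagnostics` is a data frame
#'   `(row, reason)` of rejected rows.
#' @details When a `units` column is present (values `nM`, `uM`/`µM`, `M`),
#'   values are converted to nM at ingestion; absent units mean nM.
#' @export
read_bioactivity_table <- function(path, format = c("guess", "csv", "tsv"),
                                   column_map = NULL, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  raw <- if (format == "tsv") {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      hit <- match(column_map[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("bioactivity table schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  val <- suppressWarnings(as.numeric(raw$value_nM))
  if ("units" %in% names(raw)) {
    u <- tolower(trimws(raw$units))
    fac <- ifelse(u %in% c("", "nm", NA), 1,
                  ifelse(u %in% c("um", "µm"), 1e3,
                         ifelse(u == "mm", 1e6, ifelse(u == "m", 1e9, NA))))
    val <- val * fac
  }
  reason <- rep(NA_character_, n)
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  reason[blank(raw$cid)]    <- "missing cid"
  reason[is.na(reason) & blank(raw$smiles)] <- "missing smiles"
  reason[is.na(reason) & blank(raw$target)] <- "missing target"
  reason[is.na(reason) & !(raw$metric %in% .metrics)] <-
    "unknown metric"
  reason[is.na(reason) & is.na(val)] <- "unparsable value_nM"
  reason[is.na(reason) & val <= 0] <- "non-positive value_nM"
  diagnostics <- data.frame(row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE)
  if (strict && nrow(diagnostics) > 0) {
    stop("rejected ", nrow(diagnostics), " row(s) in strict mode; first: row ",
         diagnostics$row[1], " (", diagnostics$reason[1], ")")
  }
  keep <- is.na(reason)
  out <- data.frame(
    cid = as.character(raw$cid[keep]),
    smiles = as.character(raw$smiles[keep]),
    target = as.character(raw$target[keep]),
    metric = as.character(raw$metric[keep]),
    value_nM = val[keep],
    aid = as.character(raw$aid[keep]),
    pmid = if ("pmid" %in% names(raw)) as.character(raw$pmid[keep]) else NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bioactivity_table", "data.frame")
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Construct a curated ligand table
#'
#' @param cid character vector of compound IDs (unique).
#' @param smiles character vector of canonical SMILES.
#' @param ki a data frame or matrix of Ki values in nM, one column per
#'   isoform label, NA where unmeasured.
#' @return A `ligand_table`: data frame with columns `cid`, `smiles`, then
#'   one numeric Ki column per isoform.
#' @export
ligand_table <- function(cid, smiles, ki) {
  cid <- as.character(cid)
  if (anyDuplicated(cid)) {
    stop("duplicate CID(s) in ligand table: ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))
  }
  ki <- as.data.frame(ki, check.names = FALSE)
  stopifnot(length(cid) == length(smiles), nrow(ki) == length(cid))
  bad <- vapply(ki, function(col) any(!is.na(col) & col <= 0), logical(1))
  if (any(bad)) stop("non-positive Ki in column(s): ",
                     paste(names(ki)[bad], collapse = ", "))
  out <- cbind(data.frame(cid = cid, smiles = as.character(smiles),
                          stringsAsFactors = FALSE), ki)
  class(out) <- c("ligand_table", "data.frame")
  out
}

#' @export
print.ligand_table <- function(x, ...) {
  iso <- setdiff(names(x), c("cid", "smiles"))
  cat("<ligand_table> ", nrow(x), " ligands, ", length(iso),
      " isoform column(s)\n", sep = "")
  NextMethod()
}

.isoform_cols <- function(entries) setdiff(names(entries), c("cid", "smiles"))

#' Write / read a curated ligand table
#'
#' Wide-format CSV: `cid`, `smiles`, then one Ki column (nM) per isoform,
#' empty cells where a ligand has no measurement. `read_ligand_table()`
#' restores an identical `ligand_table`.
#'
#' @param entries a `ligand_table`.
#' @param path output CSV path.
#' @param isoforms optional character vector forcing the isoform column set
#'   and order (absent isoforms become all-empty columns).
#' @return `path` invisibly (write); a `ligand_table` (read).
#' @export
write_ligand_table <- function(entries, path, isoforms = NULL) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0)
  if (anyDuplicated(entries$cid)) stop("duplicate CID(s) in ligand table")
  have <- .isoform_cols(entries)
  if (is.null(isoforms)) isoforms <- have
  out <- entries[, c("cid", "smiles"), drop = FALSE]
  for (iso in isoforms) {
    out[[iso]] <- if (iso %in% have) entries[[iso]] else NA_real_
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ligand_table
#' @export
read_ligand_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("cid", "smiles") %in% names(raw)))
  iso <- setdiff(names(raw), c("cid", "smiles"))
  ki <- raw[, iso, drop = FALSE]
  ki[] <- lapply(ki, as.numeric)
  ligand_table(as.character(raw$cid), raw$smiles, ki)
}

#' Write a cluster selectivity report
#'
#' Long-format CSV with one row per cluster member: `cluster_id`, `cid`,
#' `smiles`, Ki for the on- and off-target, per-ligand SI and class, and the
#' cluster-level selectivity score(s). Rows are sorted by descending cluster
#' S_score (double S_score in double-selectivity mode), then cluster id.
#'
#' @param reports a `cluster_report` data frame from [score_clusters()].
#' @param entries the `ligand_table` the clusters were built from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(reports, entries, path) {
  stopifnot(inherits(reports, "cluster_report"))
  cfg <- attr(reports, "config")
  double_mode <- !is.null(cfg$secondary_on_target)
  rows <- list()
  for (k in seq_len(nrow(reports))) {
    members <- reports$members[[k]]
    miss <- setdiff(members, entries$cid)
    if (length(miss)) {
      stop("cluster report member CID(s) not in ligand table: ",
           paste(miss, collapse = ", "))
    }
    e <- entries[match(members, entries$cid), , drop = FALSE]
    si <- selectivity_index(e[[cfg$off_target]], e[[cfg$on_target]])
    row <- data.frame(
      cluster_id = reports$cluster_id[k], cid = e$cid, smiles = e$smiles,
      ki_on = e[[cfg$on_target]], ki_off = e[[cfg$off_target]],
      si = si, class = classify(si, cfg),
      s_score = reports$s_score[k], stringsAsFactors = FALSE)
    if (double_mode) {
      si2 <- selectivity_index(e[[cfg$off_target]],
                               e[[cfg$secondary_on_target]])
      row$ki_on2 <- e[[cfg$secondary_on_target]]
      row$si2 <- si2
      row$class2 <- classify(si2, cfg)
      row$s_score2 <- reports$s_score_secondary[k]
      row$double_s_score <- reports$double_s_score[k]
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  key <- if (double_mode) out$double_s_score else out$s_score
  out <- out[order(-key, out$cluster_id), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
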