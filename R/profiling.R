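#' Restrict a ligand table to the target pair
#'
#' Keeps only ligands measured against both the on- and off-target (and the
#' secondary on-target in double-selectivity mode); a selectivity index is
#' undefined without both Ki values.
#'
#' @param entries a `ligand_table`.
#' @param config a [selectivity_config()].
#' @return The reduced `ligand_table`.
#' @export
select_pair_subset <- function(entries, config) {
  need <- c(config$on_target, config$off_target, config$secondary_on_target)
  miss <- setdiff(need, names(entries))
  if (length(miss)) {
    stop("ligand table has no Ki column for isoform(s): ",
         paste(miss, collapse = ", "))
  }
  keep <- Reduce(`&`, lapply(need, function(t) !is.na(entries[[t]])))
  out <- entries[keep, , drop = FALSE]
  if (nrow(out) < 2) {
    stop("fewer than two ligands have Ki for all of: ",
         paste(need, collapse = ", "))
  }
  class(out) <- class(entries)
  out
}

#' Per-ligand selectivity for a target pair
#'
#' @param entries a `ligand_table` restricted to the pair (see
#'   [select_pair_subset()]).
#' @param config a [selectivity_config()].
#' @param secondary compute SI against `secondary_on_target` instead of
#'   `on_target`.
#' @return Data frame `cid, si, klass`.
#' @export
ligand_selectivity <- function(entries, config, secondary = FALSE) {
  on <- if (secondary) config$secondary_on_target else config$on_target
  si <- selectivity_index(entries[[config$off_target]], entries[[on]])
  data.frame(cid = entries$cid, si = si, klass = classify(si, config),
             stringsAsFactors = FALSE)
}

#' Pairwise Ti-SR table
#'
#' One row per unordered ligand pair: the Tanimoto similarity of the two
#' structures and the selectivity ratio of the two ligands. Plotting SR
#' against Ti reveals whether structurally similar ligands share a
#' selectivity profile (a funnel towards SR = 0 at high Ti).
#'
#' @param entries a `ligand_table` restricted to the pair.
#' @param matrices a `selprof_matrices` over the same ligands.
#' @param config a [selectivity_config()].
#' @return Data frame `cid_a, cid_b, ti, sr` with `n(n-1)/2` rows.
#' @export
ti_sr_table <- function(entries, matrices, config) {
  stopifnot(identical(as.character(entries$cid), matrices$ligand_order))
  sel <- ligand_selectivity(entries, config)
  n <- nrow(entries)
  idx <- which(upper.tri(matrices$similarity), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    cid_a = sel$cid[idx[, 1]], cid_b = sel$cid[idx[, 2]],
    ti = matrices$similarity[idx],
    sr = selectivity_ratio(sel$si[idx[, 1]], sel$si[idx[, 2]]),
    stringsAsFactors = FALSE)
}

#' Summarise the SR envelope across Ti bins
#'
#' @param pair_table output of [ti_sr_table()].
#' @param bins Ti bin edges; bins are closed on the right. Default
#'   `c(0, 0.4, 0.8, 1)`.
#' @return Data frame with one row per bin: pair count, max |SR| and the
#'   central 95% SR range (NA for empty bins).
#' @export
sr_envelope <- function(pair_table, bins = c(0, 0.4, 0.8, 1)) {
  stopifnot(nrow(pair_table) > 0)
  cut_ix <- cut(pair_table$ti, breaks = bins, include.lowest = TRUE,
                right = TRUE)
  out <- lapply(levels(cut_ix), function(lv) {
    sr <- pair_table$sr[cut_ix == lv & !is.na(cut_ix)]
    if (length(sr) == 0) {
      data.frame(bin = lv, n = 0L, max_abs_sr = NA_real_,
                 sr_lo = NA_real_, sr_hi = NA_real_)
    } else {
      q <- stats::quantile(sr, c(0.025, 0.975), names = FALSE)
      data.frame(bin = lv, n = length(sr), max_abs_sr = max(abs(sr)),
                 sr_lo = q[1], sr_hi = q[2])
    }
  })
  do.call(rbind, out)
}

#' Score clusters by member selectivity
#'
#' Counts each cluster's `L_on`, `L_off` and `L_ns` members and computes its
#' selectivity score; in double-selectivity mode also the score against the
#' secondary on-target and their sum (double S_score).
#'
#' @param clusters list of member-CID vectors (from [cut_at_height_ratio()]
#'   / [filter_clusters()]).
#' @param selectivities data frame `cid, si, klass` from
#'   [ligand_selectivity()].
#' @param secondary_selectivities optional second such data frame (double
#'   mode).
#' @param config a [selectivity_config()]; stored on the result for report
#'   writing.
#' @return A data frame of class `cluster_report`: `cluster_id`, `members`
#'   (list column), `n_on`, `n_off`, `n_ns`, `s_score`, and in double mode
#'   `n_on2`, `n_off2`, `n_ns2`, `s_score_secondary`, `double_s_score`.
#' @export
score_clusters <- function(clusters, selectivities,
                           secondary_selectivities = NULL, config = NULL) {
  counts_of <- function(members, sel) {
    ix <- match(members, sel$cid)
    if (anyNA(ix)) {
      stop("no selectivity index for CID(s): ",
           paste(members[is.na(ix)], collapse = ", "))
    }
    k <- sel$klass[ix]
    c(n_on = sum(k == "L_on"), n_off = sum(k == "L_off"),
      n_ns = sum(k == "L_ns"))
  }
  rows <- lapply(seq_along(clusters), function(i) {
    ct <- counts_of(clusters[[i]], selectivities)
    row <- data.frame(cluster_id = i, n_on = ct[["n_on"]],
                      n_off = ct[["n_off"]], n_ns = ct[["n_ns"]],
                      s_score = s_score(ct[["n_on"]], ct[["n_off"]], ct[["n_ns"]]))
    if (!is.null(secondary_selectivities)) {
      ct2 <- counts_of(clusters[[i]], secondary_selectivities)
      row$n_on2 <- ct2[["n_on"]]; row$n_off2 <- ct2[["n_off"]]
      row$n_ns2 <- ct2[["n_ns"]]
      row$s_score_secondary <- s_score(ct2[["n_on"]], ct2[["n_off"]], ct2[["n_ns"]])
      row$double_s_score <- double_s_score(row$s_score, row$s_score_secondary)
    }
    row
  })
  out <- do.call(rbind, rows)
  out$members <- unname(clusters)
  out <- out[, c("cluster_id", "members",
                 setdiff(names(out), c("cluster_id", "members")))]
  class(out) <- c("cluster_report", "data.frame")
  attr(out, "config") <- config
  out
}

#' Select on-target-selective clusters
#'
#' Keeps clusters whose S_score is strictly above the configured cutoff
#' (default 70); in double-selectivity mode the criterion is
#' double S_score strictly above twice the cutoff. The result is sorted by
#' descending score.
#'
#' @param reports a `cluster_report`.
#' @param config a [selectivity_config()].
#' @return The filtered, sorted `cluster_report`.
#' @export
select_selective_clusters <- function(reports, config) {
  double_mode <- "double_s_score" %in% names(reports)
  if (double_mode) {
    keep <- reports$double_s_score > 2 * config$s_score_cutoff
    out <- reports[keep, , drop = FALSE]
    out <- out[order(-out$double_s_score, out$cluster_id), , drop = FALSE]
  } else {
    keep <- reports$s_score > config$s_score_cutoff
    out <- reports[keep, , drop = FALSE]
    out <- out[order(-out$s_score, out$cluster_id), , drop = FALSE]
  }
  class(out) <- class(reports)
  attr(out, "config") <- attr(reports, "config")
  out
}

#' Run a full selectivity-profile analysis
#'
#' End-to-end pipeline: curate the raw bioactivity table, restrict to
#' ligands measured against every target of interest, fingerprint the
#' structures, build Tanimoto similarity/distance matrices, cluster by
#' single linkage, cut the dendrogram, score every retained cluster, and
#' extract the on-target-selective ones. Deterministic given identical
#' inputs and configuration.
#'
#' @param x a raw `bioactivity_table`, a path to one, or an already curated
#'   `ligand_table`.
#' @param config a [selectivity_config()] naming on- and off-target.
#' @param curation a [curation_config()]; ignored when `x` is already
#'   curated.
#' @param cut a [cut_config()].
#' @param scheme fingerprint scheme, `"keys"` (default) or `"path"`.
#' @param pair_table compute the Ti-SR pair table (single-pair mode only);
#'   default TRUE.
#' @return An object of class `selprof` with components `entries` (the
#'   analysis subset), `matrices`, `dendrogram`, `clusters` (all clusters
#'   passing the size filter), `reports` (scored clusters),
#'   `selective` (clusters above the score cutoff), `selectivities`
#'   (per-ligand SI and class), `pair_table`, `envelope`, `audit`, and the
#'   three configuration objects.
#' @examples
#' \donttest{
#' fx <- simulate_bioactivity(sim_scenario(seed = 1))
#' prof <- selectivity_profile(fx$records,
#'                             selectivity_config("hCA IX", "hCA II"))
#' summary(prof)
#' }
#' @export
selectivity_profile <- function(x, config,
                                curation = curation_config(),
                                cut = cut_config(),
                                scheme = c("keys", "path"),
                                pair_table = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(config, "selectivity_config"))
  if (is.character(x)) x <- read_bioactivity_table(x)
  entries <- if (inherits(x, "ligand_table")) x else curate(x, curation)
  audit <- attr(entries, "audit")
  subset <- select_pair_subset(entries, config)
  sel <- ligand_selectivity(subset, config)
  sel2 <- if (!is.null(config$secondary_on_target)) {
    ligand_selectivity(subset, config, secondary = TRUE)
  }
  mats <- build_matrices(subset, scheme = scheme)
  dend <- single_linkage(mats)
  clusters <- filter_clusters(cut_at_height_ratio(dend, cut), cut)
  reports <- score_clusters(clusters, sel, sel2, config = config)
  selective <- select_selective_clusters(reports, config)
  pt <- env <- NULL
  if (pair_table && is.null(config$secondary_on_target)) {
    pt <- ti_sr_table(subset, mats, config)
    env <- sr_envelope(pt)
  }
  structure(list(entries = subset, matrices = mats, dendrogram = dend,
                 clusters = clusters, reports = reports,
                 selective = selective, selectivities = sel,
                 selectivities_secondary = sel2,
                 pair_table = pt, envelope = env, audit = audit,
                 config = config, curation = curation, cut = cut,
                 scheme = scheme),
            class = "selprof")
}

#' @export
print.selprof <- function(x, ...) {
  cfg <- x$config
  cat("Selectivity profile: on-target ", cfg$on_target,
      if (!is.null(cfg$secondary_on_target))
        paste0(" + ", cfg$secondary_on_target),
      " vs off-target ", cfg$off_target, "\n", sep = "")
  cat("  ", nrow(x$entries), " ligands, scheme=", x$scheme,
      ", ", length(x$clusters), " cluster(s) of size >= ",
      x$cut$min_cluster_size, ", ", nrow(x$selective),
      " selective (cutoff ", cfg$s_score_cutoff, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.selprof <- function(object, ...) {
  x <- object
  tab <- table(factor(x$selectivities$klass,
                      levels = c("L_on", "L_off", "L_ns")))
  rep <- as.data.frame(x$reports)
  rep$size <- vapply(rep$members, length, integer(1))
  rep$members <- NULL
  out <- list(config = x$config, class_counts = tab, clusters = rep,
              selective_ids = x$selective$cluster_id, audit = x$audit)
  class(out) <- "summary.selprof"
  out
}

#' @export
print.summary.selprof <- function(x, ...) {
  cat("Ligand classes:\n"); print(x$class_counts)
  cat("\nClusters:\n"); print(x$clusters, row.names = FALSE)
  cat("\nSelective cluster ids:",
      if (length(x$selective_ids)) paste(x$selective_ids, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$audit)) { cat("\nCuration audit:\n"); print(x$audit, row.names = FALSE) }
  invisible(x)
}

#' @export
plot.selprof <- function(x, which = c("ti_sr", "dendrogram", "s_score"), ...) {
  which <- match.arg(which)
  if (which == "ti_sr") {
    if (is.null(x$pair_table)) stop("no pair table in this profile")
    plot(x$pair_table$ti, x$pair_table$sr, xlab = "Tanimoto similarity (Ti)",
         ylab = "Selectivity ratio (SR)", pch = 16,
         col = grDevices::adjustcolor("steelblue", 0.5), ...)
    graphics::abline(h = 0, lty = 2)
  } else if (which == "dendrogram") {
    plot(x$dendrogram, labels = FALSE, main = "Single-linkage dendrogram",
         xlab = "", sub = "", ...)
    graphics::abline(h = x$cut$height_ratio * max(x$dendrogram$height),
                     col = "red", lty = 2)
  } else {
    graphics::hist(x$reports$s_score, breaks = seq(-100, 100, by = 20),
                   xlab = "S_score", main = "Cluster S_score distribution", ...)
  }
  invisible(x)
}

#' Write all result files of a profile
#'
#' @param x a `selprof` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"selprof"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_profile <- function(x, dir, prefix = "selprof") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  files <- character()
  write_cluster_report(x$selective, x$entries, p("selective_clusters.csv"))
  files <- c(files, p("selective_clusters.csv"))
  write_cluster_report(x$reports, x$entries, p("all_clusters.csv"))
  files <- c(files, p("all_clusters.csv"))
  if (!is.null(x$pair_table)) {
    write.csv(x$pair_table, p("pair_table.csv"), row.names = FALSE)
    files <- c(files, p("pair_table.csv"))
  }
  if (!is.null(x$audit)) {
    write.csv(x$audit, p("audit.csv"), row.names = FALSE)
    files <- c(files, p("audit.csv"))
  }
  invisible(files)
}
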