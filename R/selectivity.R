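#' Selectivity analysis configuration
#'
#' @param on_target isoform label of the on-target (e.g. `"hCA IX"`).
#' @param off_target isoform label of the off-target (e.g. `"hCA II"`).
#' @param si_on_threshold SI above which a ligand is on-target selective
#'   (`L_on`); default 5.
#' @param si_off_threshold SI below which a ligand is off-target selective
#'   (`L_off`); default 0.2.
#' @param s_score_cutoff clusters with S_score strictly above this are
#'   reported as selective; default 70.
#' @param secondary_on_target optional second on-target label; switches the
#'   pipeline into double-selectivity mode.
#' @return A list of class `selectivity_config`.
#' @export
selectivity_config <- function(on_target, off_target,
                               si_on_threshold = 5, si_off_threshold = 0.2,
                               s_score_cutoff = 70,
                               secondary_on_target = NULL) {
  stopifnot(is.character(on_target), is.character(off_target),
            on_target != off_target,
            si_off_threshold < si_on_threshold)
  if (!is.null(secondary_on_target)) {
    stopifnot(secondary_on_target != off_target,
              secondary_on_target != on_target)
  }
  structure(list(on_target = on_target, off_target = off_target,
                 si_on_threshold = si_on_threshold,
                 si_off_threshold = si_off_threshold,
                 s_score_cutoff = s_score_cutoff,
                 secondary_on_target = secondary_on_target),
            class = "selectivity_config")
}

#' Selectivity index
#'
#' SI = Ki(off-target) / Ki(on-target). A ligand ten-fold more potent
#' against the on-target than the off-target has SI = 10.
#'
#' @param ki_off,ki_on Ki values in nM (vectorised; must be positive).
#' @return Numeric vector of SI values.
#' @examples
#' selectivity_index(51, 58)   # a non-selective ligand
#' selectivity_index(546, 2)   # a strongly on-selective one
#' @export
selectivity_index <- function(ki_off, ki_on) {
  if (any(!is.na(ki_off) & ki_off <= 0) || any(!is.na(ki_on) & ki_on <= 0)) {
    stop("Ki values must be positive")
  }
  ki_off / ki_on
}

#' Classify ligands by selectivity index
#'
#' Partitions ligands into `L_on` (SI strictly above the on threshold),
#' `L_off` (SI strictly below the off threshold) and `L_ns` otherwise.
#' Boundary values sit in `L_ns`: both inequalities are strict.
#'
#' @param si numeric vector of selectivity indices (positive).
#' @param config a [selectivity_config()] (or any list with
#'   `si_on_threshold` and `si_off_threshold`).
#' @return Character vector over `c("L_on", "L_off", "L_ns")`.
#' @export
classify <- function(si, config = selectivity_config("on", "off")) {
  stopifnot(all(is.na(si) | si > 0))
  out <- rep("L_ns", length(si))
  out[si > config$si_on_threshold] <- "L_on"
  out[si < config$si_off_threshold] <- "L_off"
  out[is.na(si)] <- NA_character_
  out
}

#' Selectivity ratio of a ligand pair
#'
#' SR = log10(SI_a) - log10(SI_b): the difference of two ligands'
#' selectivity indices on a base-10 log scale. SR = 0 means identical
#' selectivity profiles; |SR| = 2 means a hundred-fold difference.
#' Antisymmetric: `selectivity_ratio(a, b) == -selectivity_ratio(b, a)`.
#'
#' @param si_a,si_b positive SI values (vectorised).
#' @return Numeric vector of SR values.
#' @export
selectivity_ratio <- function(si_a, si_b) {
  stopifnot(all(si_a > 0), all(si_b > 0))
  log10(si_a) - log10(si_b)
}

#' Cluster selectivity score
#'
#' S_score = 100 (L_on - L_off) / (L_on + L_off + L_ns), ranging from +100
#' (cluster populated only by on-target-selective ligands) to -100 (only
#' off-target-selective ligands).
#'
#' @param n_on,n_off,n_ns non-negative member counts per class (vectorised).
#' @return Numeric vector in `[-100, 100]`.
#' @examples
#' s_score(41, 0, 0)  # a purely on-selective cluster
#' s_score(9, 1, 0)
#' @export
s_score <- function(n_on, n_off, n_ns) {
  stopifnot(all(n_on >= 0), all(n_off >= 0), all(n_ns >= 0))
  tot <- n_on + n_off + n_ns
  if (any(tot == 0)) stop("empty cluster: counts sum to zero")
  100 * (n_on - n_off) / tot
}

#' Double selectivity score
#'
#' Sum of the two S_scores a cluster obtains against two different
#' on-targets sharing one off-target; +200 means the cluster is purely
#' selective for both on-targets.
#'
#' @param s1,s2 S_score values in `[-100, 100]`.
#' @return `s1 + s2`, in `[-200, 200]`.
#' @export
double_s_score <- function(s1, s2) {
  stopifnot(all(abs(s1) <= 100), all(abs(s2) <= 100))
  s1 + s2
}
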