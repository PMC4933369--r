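#' Percentage of query records overlapping a target track
#'
#' `100 * |intersect_u(query, target)| / |query|`: counting is
#' record-based on the query side, so one query record overlapping
#' several target records counts once.
#'
#' @param query,target `interval_collection`s with shared chromosome
#'   naming.
#' @return A percentage in \[0, 100\].
#' @export
percentage_overlap <- function(query, target) {
  if (nrow(query) == 0) stop("query collection is empty")
  100 * nrow(intersect_u(query, target)) / nrow(query)
}

#' Remove shared regions before comparison
#'
#' When comparing an external enhancer set against the BMP peaks'
#' insulator overlap, regions of the external set that themselves
#' overlap the BMP peaks are removed first, so the comparison set is
#' disjoint from the peaks being characterized.
#'
#' @param other The external `interval_collection`.
#' @param bmp The BMP peak `interval_collection`.
#' @return `other` minus its records overlapping `bmp`.
#' @export
exclusive_prep <- function(other, bmp) {
  subtract_u(other, bmp)
}

#' Percentage of records overlapping at least one of several tracks
#'
#' Merges the target tracks (concatenate + merge, so sources cannot be
#' double-counted) and reports the percentage of query records
#' overlapping the union.  Adding a target can never decrease the
#' result.
#'
#' @param query An `interval_collection`.
#' @param targets A non-empty list of `interval_collection`s.
#' @return A percentage in \[0, 100\].
#' @export
at_least_one <- function(query, targets) {
  stopifnot(is.list(targets), length(targets) >= 1)
  percentage_overlap(query, merge_factor_datasets(targets))
}

#' Classify candidate phantom peaks by DamID evidence
#'
#' Dual-bound peaks (e.g. pMad peaks also bound by BEAF-32) that
#' intersect a published phantom-peak list are candidate artefacts of
#' antibody-based ChIP.  Candidates present in the antibody-free DamID
#' profile for the same factor are reassigned as real; the remainder
#' stay potential phantom peaks.  The two classes partition the
#' candidates exactly.
#'
#' @param dual_bound Peaks bound by both the study factor and the
#'   co-binding factor.
#' @param phantom_list Published phantom-peak intervals.
#' @param damid DamID intervals for the co-binding factor.
#' @return An object of class `phantom_classification` with elements
#'   `candidates`, `real`, `phantom` (all `interval_collection`s) and
#'   `pct_phantom` (percentage of dual-bound peaks remaining phantom).
#' @export
phantom_classify <- function(dual_bound, phantom_list, damid) {
  if (nrow(dual_bound) == 0) stop("dual_bound collection is empty")
  candidates <- intersect_u(dual_bound, phantom_list)
  real <- intersect_u(candidates, damid)
  phantom <- subtract_u(candidates, damid)
  structure(
    list(candidates = candidates, real = real, phantom = phantom,
         pct_phantom = 100 * nrow(phantom) / nrow(dual_bound)),
    class = "phantom_classification")
}

#' @export
print.phantom_classification <- function(x, ...) {
  cat("phantom-peak classification:", nrow(x$candidates), "candidates;",
      nrow(x$real), "reassigned real by DamID;",
      nrow(x$phantom), "remain potential phantom peaks",
      sprintf("(%.1f%% of dual-bound peaks)\n", x$pct_phantom))
  invisible(x)
}

#' Overlap percentage matrix
#'
#' Convenience wrapper building the query-by-target matrix of
#' [percentage_overlap()] values used to compare peak sets against
#' panels of insulator/pioneer-factor tracks.
#'
#' @param queries Named list of query `interval_collection`s.
#' @param targets Named list of target `interval_collection`s.
#' @return A numeric matrix of percentages, queries in rows.
#' @export
overlap_matrix <- function(queries, targets) {
  stopifnot(is.list(queries), is.list(targets))
  out <- matrix(NA_real_, nrow = length(queries), ncol = length(targets),
                dimnames = list(names(queries), names(targets)))
  for (i in seq_along(queries))
    for (j in seq_along(targets))
      out[i, j] <- percentage_overlap(queries[[i]], targets[[j]])
  out
}
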