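#' Replicate-reproducible peaks
#'
#' A binding region is accepted only when called in both biological
#' replicates (at least 1 bp overlap).  By default the first replicate's
#' coordinates are retained; `coords = "intersection"` reports the
#' intersected spans instead.
#'
#' @param rep1,rep2 Peak `interval_collection`s called at the same
#'   stringency.
#' @param coords Which coordinates survive: `"rep1"` (default) or
#'   `"intersection"`.
#' @return An `interval_collection` of reproducible peaks.
#' @export
reproducible_peaks <- function(rep1, rep2, coords = c("rep1", "intersection")) {
  coords <- match.arg(coords)
  out <- intersect_u(rep1, rep2)
  if (coords == "rep1" || nrow(out) == 0) return(out)
  g1 <- as_gr(out)
  g2 <- as_gr(rep2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  pi <- GenomicRanges::pintersect(g1[S4Vectors::queryHits(hits)],
                                  g2[S4Vectors::subjectHits(hits)])
  res <- out[S4Vectors::queryHits(hits), , drop = FALSE]
  res$start <- GenomicRanges::start(pi) - 1L
  res$end <- GenomicRanges::end(pi)
  if (!is.null(res$summit))
    res$summit <- pmin(pmax(res$summit, res$start), res$end - 1L)
  interval_collection(as.data.frame(res), name = attr(rep1, "collection_name"))
}

#' Refine peak coordinates by stringency
#'
#' Where a region was called at both the loose (p < 1e-4) and strict
#' (p < 1e-5) cutoffs, the higher-resolution strict coordinates replace
#' the loose ones; a loose peak overlapped by several strict peaks is
#' replaced by all of them, and loose peaks with no strict counterpart
#' are kept unchanged.  Strict peaks overlapping no loose peak trigger a
#' warning (they indicate mismatched inputs) and are ignored.
#'
#' @param loose Peaks called at the looser cutoff.
#' @param strict Peaks called at the stricter cutoff.
#' @return The refined `interval_collection`.
#' @export
stringency_refine <- function(loose, strict) {
  if (nrow(strict) == 0) return(loose)
  if (nrow(loose) == 0) return(loose)
  hits <- GenomicRanges::findOverlaps(as_gr(loose), as_gr(strict))
  orphan <- setdiff(seq_len(nrow(strict)), S4Vectors::subjectHits(hits))
  if (length(orphan) > 0)
    warning(length(orphan), " strict peak(s) overlap no loose peak; ignored")
  refined_loose <- unique(S4Vectors::queryHits(hits))
  used_strict <- sort(unique(S4Vectors::subjectHits(hits)))
  kept <- loose[setdiff(seq_len(nrow(loose)), refined_loose), , drop = FALSE]
  repl <- strict[used_strict, , drop = FALSE]
  common <- intersect(names(kept), names(repl))
  out <- rbind(as.data.frame(kept)[common], as.data.frame(repl)[common])
  interval_collection(out, name = attr(loose, "collection_name"))
}

#' Combine two time points for one factor
#'
#' Late-time-point coordinates take precedence: output is every late
#' record plus the early records with no late overlap.  Each record is
#' labelled (column `timepoints`) with the time point(s) that
#' contributed it; no coordinates are invented.
#'
#' @param early,late Peak `interval_collection`s for the same factor.
#' @param labels Length-2 character vector naming the two time points.
#' @return An `interval_collection` with a `timepoints` column.
#' @export
combine_timepoints <- function(early, late, labels = c("early", "late")) {
  stopifnot(length(labels) == 2)
  keep_early <- subtract_u(early, late)
  shared_late <- intersect_u(late, early)
  le <- as.data.frame(late)
  le$timepoints <- rep(labels[2], nrow(le))
  if (nrow(shared_late) > 0) {
    hit <- paste(le$chrom, le$start, le$end) %in%
      paste(shared_late$chrom, shared_late$start, shared_late$end)
    le$timepoints[hit] <- paste(labels, collapse = ",")
  }
  ke <- as.data.frame(keep_early)
  if (nrow(ke) > 0) ke$timepoints <- labels[1]
  common <- intersect(names(le), names(ke))
  out <- if (nrow(ke) > 0) rbind(le[common], ke[common]) else le
  interval_collection(out, name = attr(late, "collection_name"))
}

#' Combine pMad and Brk peaks across time points
#'
#' Builds the combined BMP-responsive peak list with coordinate
#' precedence pMad 3-3.5 h > Brk 3-3.5 h > pMad 2-2.5 h > Brk 2-2.5 h:
#' each set contributes only records not overlapping an already-retained
#' higher-precedence record, so chains of overlapping peaks collapse
#' onto the highest-precedence coordinates.  Logical columns `pMad2`,
#' `pMad3`, `Brk2`, `Brk3` flag which input sets overlap each retained
#' record.
#'
#' @param pmad_early,pmad_late,brk_early,brk_late Peak collections for
#'   the two factors at 2-2.5 h ("early") and 3-3.5 h ("late").
#' @return The combined `interval_collection` with factor flags.
#' @export
combine_bmp <- function(pmad_early, pmad_late, brk_early, brk_late) {
  sets <- list(pmad_late, brk_late, pmad_early, brk_early)
  keep_cols <- c("chrom", "start", "end", "name", "summit")
  out <- NULL
  for (s in sets) {
    s <- as.data.frame(s)[intersect(keep_cols, names(s))]
    add <- if (is.null(out) || nrow(out) == 0) s else {
      as.data.frame(subtract_u(interval_collection(s), interval_collection(out)))
    }
    for (col in setdiff(keep_cols, names(add))) add[[col]] <- if (nrow(add)) NA else logical(0)
    out <- if (is.null(out)) add[keep_cols] else rbind(out, add[keep_cols])
  }
  res <- interval_collection(out, name = "BMP")
  flags <- list(pMad2 = pmad_early, pMad3 = pmad_late,
                Brk2 = brk_early, Brk3 = brk_late)
  for (nm in names(flags)) {
    res[[nm]] <- seq_len(nrow(res)) %in%
      match_overlapping(res, flags[[nm]])
  }
  res
}

match_overlapping <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(integer(0))
  unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(as_gr(a), as_gr(b))))
}

#' Concatenate and merge several interval sets
#'
#' Where several experiments exist for one factor, their interval files
#' are concatenated and merged into one disjoint track before overlap
#' analysis, so a factor cannot be double-counted.
#'
#' @param collections A list of `interval_collection`s.
#' @param name Optional name of the merged track.
#' @return A merged, disjoint `interval_collection`.
#' @export
merge_factor_datasets <- function(collections, name = NULL) {
  stopifnot(is.list(collections), length(collections) >= 1)
  base <- c("chrom", "start", "end")
  cat_df <- do.call(rbind, lapply(collections, function(x) as.data.frame(x)[base]))
  merge_intervals(interval_collection(cat_df, name = name))
}

#' Read-track normalization factors
#'
#' Per-sample scaling factors for browser read tracks: the mean of all
#' per-sample median read values divided by each sample's median, so
#' that applying `factors[i]` equalizes the medians exactly.
#'
#' @param sample_medians Positive per-sample median read values.
#' @return An object of class `norm_factors` with elements
#'   `sample_medians` and `factors`.
#' @examples
#' normalization_factors(c(10, 20, 30))$factors  # 2, 1, 2/3
#' @export
normalization_factors <- function(sample_medians) {
  if (length(sample_medians) == 0 || any(!is.finite(sample_medians)) ||
      any(sample_medians <= 0))
    stop("sample medians must be positive and finite")
  structure(
    list(sample_medians = sample_medians,
         factors = mean(sample_medians) / sample_medians),
    class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("normalization factors (mean of medians / per-sample median):\n")
  print(data.frame(median = x$sample_medians, factor = x$factors))
  invisible(x)
}
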