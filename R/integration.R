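#' Pair genes with nearby peak summits ("gene to peak")
#'
#' Lists every (peak, gene) pair on the same chromosome whose TSS lies
#' within `d` bases of the peak summit (boundary inclusive).  Distances
#' are signed as `tss - summit`, so a negative distance places the gene
#' upstream of the summit in chromosome coordinates.
#'
#' @param peaks An `interval_collection` of peaks (summits taken from the
#'   `summit` column, falling back to interval midpoints).
#' @param genes A gene-record data frame (see [read_gene_table()]).
#' @param d Window half-width in bp.
#' @return A data frame with columns `peak_id`, `gene_id`, `distance`.
#' @export
gene_to_peak <- function(peaks, genes, d) {
  stopifnot(d > 0)
  ids <- peak_ids(peaks)
  sm <- summits(peaks)
  out <- vector("list", length(unique(peaks$chrom)))
  k <- 0L
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(pi) == 0 || length(gi) == 0) next
    dist <- outer(sm[pi], genes$tss[gi], function(s, t) t - s)
    hit <- which(abs(dist) <= d, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    k <- k + 1L
    out[[k]] <- data.frame(
      peak_id = ids[pi[hit[, 1]]],
      gene_id = genes$gene_id[gi[hit[, 2]]],
      distance = dist[hit],
      stringsAsFactors = FALSE)
  }
  if (k == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer()))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$peak_id, res$gene_id), , drop = FALSE]
}

peak_ids <- function(peaks) {
  if (!is.null(peaks$name) && !anyNA(peaks$name) && !any(duplicated(peaks$name)))
    return(as.character(peaks$name))
  paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
}

#' Pair peak summits with nearby differentially expressed genes
#' ("peak to gene")
#'
#' The reciprocal of [gene_to_peak()], restricted to differentially
#' expressed genes (`de_status` `up`/`down`) or to a caller-supplied
#' gene subset.
#'
#' @inheritParams gene_to_peak
#' @param gene_subset Optional character vector of `gene_id`s to use
#'   instead of the DE set.
#' @return A data frame with columns `peak_id`, `gene_id`, `distance`.
#' @export
peak_to_gene <- function(peaks, genes, d, gene_subset = NULL) {
  sel <- if (is.null(gene_subset)) genes$de_status %in% c("up", "down")
         else genes$gene_id %in% gene_subset
  gene_to_peak(peaks, genes[sel, , drop = FALSE], d)
}

#' Test association between peaks and differential expression
#'
#' Classifies every gene as "near" (>= 1 peak summit within `d` of its
#' TSS; genes on chromosomes absent from the peak set count as not near)
#' and tabulates near/not-near against DE/non-DE.  Significance that DE
#' genes lie closer to peaks than non-DE genes is assessed by Pearson's
#' chi-square on the 2x2 table (df = 1, no continuity correction) and a
#' one-sided upper-tail binomial test of the DE near-count against the
#' non-DE near-rate.  Also reports the fraction of peaks with at least
#' one DE gene in the window.
#'
#' @inheritParams gene_to_peak
#' @return An object of class `association_result`.
#' @export
association_test <- function(peaks, genes, d) {
  de <- genes$de_status %in% c("up", "down")
  tot_de <- sum(de)
  tot_nonde <- sum(!de)
  if (tot_de < 1 || tot_nonde < 1)
    stop("need at least one DE and one non-DE gene")
  pairs <- gene_to_peak(peaks, genes, d)
  near_genes <- unique(pairs$gene_id)
  near <- genes$gene_id %in% near_genes
  near_de <- sum(near & de)
  near_nonde <- sum(near & !de)
  tab <- matrix(c(near_de, tot_de - near_de,
                  near_nonde, tot_nonde - near_nonde),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("de", "non_de"), c("near", "not_near")))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  degenerate <- near_nonde == 0
  binom_p <- if (degenerate) {
    if (near_de > 0) 0 else 1
  } else {
    stats::pbinom(near_de - 1, tot_de, near_nonde / tot_nonde,
                  lower.tail = FALSE)
  }
  frac <- if (nrow(peaks) == 0) NA_real_ else {
    de_genes <- genes[de, , drop = FALSE]
    de_pairs <- gene_to_peak(peaks, de_genes, d)
    length(unique(de_pairs$peak_id)) / nrow(peaks)
  }
  structure(
    list(distance = d, table = tab,
         near_de = near_de, near_nonde = near_nonde,
         tot_de = tot_de, tot_nonde = tot_nonde,
         chi2_stat = unname(chi$statistic), chi2_p = chi$p.value,
         binom_p = binom_p, degenerate_null = degenerate,
         frac_peaks_with_de = frac),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Peak-gene association at d =", x$distance, "bp\n")
  print(x$table)
  cat(sprintf("chi-square = %.3f (p = %.3g), one-sided binomial p = %.3g%s\n",
              x$chi2_stat, x$chi2_p, x$binom_p,
              if (x$degenerate_null) " [degenerate null]" else ""))
  cat(sprintf("%.1f%% of peaks have a DE gene within %d bp\n",
              100 * x$frac_peaks_with_de, x$distance))
  invisible(x)
}

#' Proximity fractions over a set of distance windows
#'
#' For each window half-width: the percentage of peaks with at least one
#' DE gene within the window, and the percentage of DE genes with at
#' least one summit within the window.  Both are non-decreasing in the
#' distance.
#'
#' @inheritParams gene_to_peak
#' @param distances Ascending positive window half-widths in bp.
#' @param gene_subset Optional character vector of `gene_id`s defining
#'   the gene set (defaults to the DE genes).
#' @return A data frame with columns `distance`, `pct_peaks_with_gene`,
#'   `pct_genes_with_peak`.
#' @export
proximity_fractions <- function(peaks, genes,
                                distances = c(5000L, 10000L, 20000L, 40000L),
                                gene_subset = NULL) {
  stopifnot(all(distances > 0), !is.unsorted(distances))
  sel <- if (is.null(gene_subset)) genes$de_status %in% c("up", "down")
         else genes$gene_id %in% gene_subset
  gset <- genes[sel, , drop = FALSE]
  res <- lapply(distances, function(d) {
    pairs <- gene_to_peak(peaks, gset, d)
    data.frame(
      distance = d,
      pct_peaks_with_gene =
        if (nrow(peaks) == 0) NA_real_
        else 100 * length(unique(pairs$peak_id)) / nrow(peaks),
      pct_genes_with_peak =
        if (nrow(gset) == 0) 0
        else 100 * length(unique(pairs$gene_id)) / nrow(gset))
  })
  do.call(rbind, res)
}
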