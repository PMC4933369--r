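#' Motif consensus
#'
#' A named IUPAC nucleotide consensus (e.g. the Zld sites CAGGTAG and
#' CAGGTAA, or Mad/Med/Brk consensus strings supplied by the user).
#'
#' @param name Motif name.
#' @param consensus Non-empty IUPAC string.
#' @return An object of class `motif_consensus`.
#' @export
motif_consensus <- function(name, consensus) {
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(consensus, "")[[1]], iupac)
  if (length(bad) > 0)
    stop("non-IUPAC character(s) in consensus: ", paste(bad, collapse = ", "))
  structure(list(name = name, consensus = consensus),
            class = "motif_consensus")
}

as_motif <- function(motif) {
  if (inherits(motif, "motif_consensus")) return(motif)
  motif_consensus(as.character(motif), as.character(motif))
}

#' Extract summit-centred sequence windows
#'
#' One 250 bp window per peak (125 bp either side of the summit,
#' half-open `[summit - 125, summit + 125)`), uppercase.  Peaks whose
#' window would run off the chromosome end are skipped with a warning.
#'
#' @param peaks An `interval_collection` (summits from the `summit`
#'   column, midpoint fallback).
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file;
#'   sequence names must match the peak chromosome names.
#' @param flank Bases either side of the summit (default 125).
#' @return Named character vector of window sequences (names are peak
#'   ids).
#' @export
extract_summit_windows <- function(peaks, genome, flank = 125L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr) > 0)
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  sm <- summits(peaks)
  len <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  ok <- sm - flank >= 0 & sm + flank <= len
  if (any(!ok))
    warning(sum(!ok), " peak(s) skipped: summit window off chromosome end")
  idx <- which(ok)
  out <- character(length(idx))
  for (i in seq_along(idx)) {
    j <- idx[i]
    out[i] <- as.character(Biostrings::subseq(
      genome[[peaks$chrom[j]]], start = sm[j] - flank + 1L, width = 2L * flank))
  }
  names(out) <- peak_ids(peaks)[idx]
  toupper(out)
}

#' Scan sequences for an IUPAC consensus on both strands
#'
#' TRUE where the consensus matches at any offset on either strand.
#' IUPAC ambiguity codes in the consensus expand; `N` in the *sequence*
#' matches nothing.
#'
#' @param seqs Character vector of sequences over A/C/G/T/N.
#' @param motif A [motif_consensus()] or plain consensus string.
#' @return Logical vector, one element per sequence.
#' @export
motif_hits <- function(seqs, motif) {
  motif <- as_motif(motif)
  subj <- Biostrings::DNAStringSet(toupper(seqs))
  pat <- Biostrings::DNAString(motif$consensus)
  fwd <- Biostrings::vcountPattern(pat, subj, fixed = "subject")
  rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subj,
                                   fixed = "subject")
  (fwd + rev) > 0
}

#' @rdname motif_hits
#' @param seq A single sequence.
#' @export
scan_motif <- function(seq, motif) {
  stopifnot(length(seq) == 1)
  motif_hits(seq, motif)[[1]]
}

#' Motif enrichment against control regions
#'
#' Computes the percentage of test and control windows containing the
#' motif (binary per window: at least one match on either strand), their
#' ratio, and a two-tailed Fisher's exact p-value on the 2x2
#' with/without-motif by test/control table.  A ratio of 1 means no
#' enrichment relative to the control set; the control set is typically
#' windows from housekeeping enhancers.
#'
#' @param test_windows,control_windows Non-empty character vectors of
#'   sequences (e.g. from [extract_summit_windows()]).
#' @param motif A [motif_consensus()] or consensus string.
#' @return An object of class `enrichment_result` with fields `motif`,
#'   `pct_test`, `pct_control`, `ratio` (Inf with `infinite_ratio = TRUE`
#'   when the control percentage is 0), `fisher_p`, and the counts.
#' @export
enrichment <- function(test_windows, control_windows, motif) {
  if (length(test_windows) == 0 || length(control_windows) == 0)
    stop("test and control window lists must be non-empty")
  motif <- as_motif(motif)
  ht <- motif_hits(test_windows, motif)
  hc <- motif_hits(control_windows, motif)
  n_test <- length(ht); n_control <- length(hc)
  with_test <- sum(ht); with_control <- sum(hc)
  pct_test <- 100 * with_test / n_test
  pct_control <- 100 * with_control / n_control
  tab <- matrix(c(with_test, n_test - with_test,
                  with_control, n_control - with_control),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("test", "control"),
                                c("with_motif", "without_motif")))
  fisher_p <- stats::fisher.test(tab)$p.value
  structure(
    list(motif = motif$name,
         pct_test = pct_test, pct_control = pct_control,
         ratio = if (pct_control > 0) pct_test / pct_control
                 else if (pct_test > 0) Inf else NaN,
         infinite_ratio = pct_control == 0 && pct_test > 0,
         fisher_p = fisher_p, table = tab,
         n_test = n_test, n_control = n_control),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "motif %s: %.1f%% of %d test vs %.1f%% of %d control windows (ratio %.2f%s), Fisher p = %.3g\n",
    x$motif, x$pct_test, x$n_test, x$pct_control, x$n_control,
    if (is.finite(x$ratio)) x$ratio else Inf,
    if (x$infinite_ratio) ", control empty" else "",
    x$fisher_p))
  invisible(x)
}
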