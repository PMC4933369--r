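#' Interval collections
#'
#' The package's universal coordinate unit is a BED-convention genomic
#' interval: 0-based start, half-open end, on a named chromosome.  An
#' `interval_collection` is a data frame with required columns `chrom`,
#' `start`, `end`, kept position-sorted by `(chrom, start)`.  Optional
#' columns carry peak metadata: `name`, `summit` (0-based base position,
#' `start <= summit < end`), `source` (factor/time-point label) and
#' `stringency` (`"p4"` for a 1e-4 peak-calling cutoff, `"p5"` for 1e-5).
#' Any further columns (e.g. overlap annotations from supplementary
#' tables) are retained untouched.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param name Optional collection name, stored as an attribute.
#' @return An object of class `interval_collection` (a sorted data frame).
#' @examples
#' interval_collection(data.frame(chrom = "chr2L", start = 100L, end = 200L))
#' @export
interval_collection <- function(x, name = NULL) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("interval_collection", "data.frame"),
            collection_name = name %||% attr(x, "collection_name"))
}

validate_intervals <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("start/end must not be NA")
  if (any(x$start < 0))
    stop("start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad) > 0)
    stop("end <= start for record(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (!is.null(x$summit)) {
    s <- x$summit
    bad <- which(!is.na(s) & (s < x$start | s >= x$end))
    if (length(bad) > 0)
      stop("summit outside [start, end) for record(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.interval_collection <- function(x, ...) {
  nm <- attr(x, "collection_name")
  cat("interval_collection", if (!is.null(nm)) paste0("'", nm, "'") else "",
      "with", nrow(x), "records on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

# GRanges bridge: BED [start, end) maps to 1-based closed [start+1, end].
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Summits of a peak collection
#'
#' Returns the 0-based summit positions, falling back to the interval
#' midpoint `floor((start + end) / 2)` where no explicit summit is
#' recorded (peak callers do not always report one).
#'
#' @param x An `interval_collection`.
#' @return Integer vector of 0-based summit positions.
#' @export
summits <- function(x) {
  mid <- as.integer(floor((x$start + x$end) / 2))
  if (is.null(x$summit)) return(mid)
  out <- as.integer(x$summit)
  out[is.na(out)] <- mid[is.na(out)]
  out
}

#' Normalize chromosome naming
#'
#' Mismatched `chr` prefixes between peak and track files are the most
#' common silent failure in interval work; this strips or adds the
#' prefix uniformly.
#'
#' @param x An `interval_collection`.
#' @param style `"chr"` to ensure the prefix, `"nochr"` to strip it,
#'   `"keep"` to leave names untouched.
#' @return The collection with renamed chromosomes.
#' @export
normalize_chrom <- function(x, style = c("keep", "chr", "nochr")) {
  style <- match.arg(style)
  if (style == "keep") return(x)
  ch <- sub("^chr", "", x$chrom)
  if (style == "chr") ch <- paste0("chr", ch)
  x$chrom <- ch
  interval_collection(as.data.frame(x), name = attr(x, "collection_name"))
}

#' Read a BED file
#'
#' Parses 3+ column tab-separated BED: `chrom`, `start`, `end`, optional
#' `name` (column 4) and optional 0-based `summit` position (column 5).
#' Coordinates are kept verbatim in BED convention (0-based, half-open).
#'
#' @param path Path to an existing BED file.
#' @param name Optional collection name.
#' @return An `interval_collection`.
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(interval_collection(
      data.frame(chrom = character(), start = integer(), end = integer()),
      name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (any(is.na(starts)) || any(is.na(ends)))
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1],
         ": non-integer coordinate")
  bad <- which(ends <= starts)
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], ": end <= start")
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = starts, end = ends,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4)) df$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5)) {
    sm <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    if (any(is.na(sm)))
      stop("malformed BED line ", which(is.na(sm))[1], ": non-integer summit")
    df$summit <- sm
  }
  interval_collection(df, name = name %||% basename(path))
}

#' Write a BED file
#'
#' Writes `chrom`, `start`, `end` plus `name` and `summit` columns when
#' present, tab-separated, so that `read_bed()` round-trips exactly.
#'
#' @param x An `interval_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(x$summit)) cols <- c(cols, "name", "summit")
  else if (!is.null(x$name)) cols <- c(cols, "name")
  df <- as.data.frame(x)
  if (is.null(df$name) && "name" %in% cols)
    df$name <- sprintf("region_%04d", seq_len(nrow(df)))
  lines <- do.call(paste, c(unname(df[cols]), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with a header; required columns `gene_id`, `chrom`,
#' `tss` (0-based transcription start position), `strand` (`+`/`-`) and
#' `de_status` (`up`, `down` or `not_de`); optional `adj_p` with the
#' differential-expression adjusted p-value.  Genes called `up`/`down`
#' must satisfy the study's cutoff adj_p < 0.03 when `adj_p` is present.
#'
#' @param path Path to the TSV file.
#' @return A data frame of gene records.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  req <- c("gene_id", "chrom", "tss", "strand", "de_status")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("gene table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$tss <- as.integer(df$tss)
  bad <- setdiff(unique(df$de_status), c("up", "down", "not_de"))
  if (length(bad) > 0)
    stop("unknown de_status value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad) > 0)
    stop("unknown strand value(s): ", paste(bad, collapse = ", "))
  if (!is.null(df$adj_p)) {
    de <- df$de_status %in% c("up", "down") & !is.na(df$adj_p)
    if (any(df$adj_p[de] >= 0.03))
      stop("gene(s) labelled differentially expressed with adj_p >= 0.03")
  }
  df
}

#' Write a gene table
#' @param genes Gene-record data frame (see [read_gene_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Records of one collection overlapping another
#'
#' The interval-algebra workhorse: returns the subset of `a`'s records
#' sharing at least one base with any record of `b` (each reported once,
#' order preserved), the behaviour of `bedtools intersect -u`.
#'
#' @param a,b `interval_collection`s on the same chromosome naming.
#' @return The overlapping subset of `a`.
#' @examples
#' a <- interval_collection(data.frame(chrom = "chr2L", start = 100L, end = 200L))
#' b <- interval_collection(data.frame(chrom = "chr2L", start = 199L, end = 300L))
#' nrow(intersect_u(a, b))  # 1: one shared base
#' @export
intersect_u <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(as_gr(a), as_gr(b))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  a[keep, , drop = FALSE]
}

#' Records of one collection NOT overlapping another
#'
#' Complement of [intersect_u()]: `a` minus its records sharing any base
#' with `b`.
#'
#' @inheritParams intersect_u
#' @return The non-overlapping subset of `a`.
#' @export
subtract_u <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  hits <- GenomicRanges::findOverlaps(as_gr(a), as_gr(b))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) return(a)
  a[-drop, , drop = FALSE]
}

#' Merge overlapping and book-ended intervals
#'
#' Unions overlapping or directly adjacent (book-ended, distance 0)
#' records on the same chromosome into disjoint, sorted intervals —
#' the default behaviour of `bedtools merge`.  Metadata columns are
#' dropped; the operation is idempotent.
#'
#' @param a An `interval_collection`.
#' @return A disjoint, sorted `interval_collection`.
#' @export
merge_intervals <- function(a) {
  if (nrow(a) == 0)
    return(interval_collection(
      data.frame(chrom = character(), start = integer(), end = integer()),
      name = attr(a, "collection_name")))
  red <- GenomicRanges::reduce(as_gr(a))  # min.gapwidth = 1 joins book-ended
  interval_collection(
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               stringsAsFactors = FALSE),
    name = attr(a, "collection_name"))
}

#' Total bases covered by a collection
#' @param a An `interval_collection`.
#' @return Number of distinct bases covered (after merging).
#' @export
covered_bases <- function(a) {
  m <- merge_intervals(a)
  sum(as.numeric(m$end - m$start))
}
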