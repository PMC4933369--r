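#' Read a supplementary workbook sheet
#'
#' Supplementary peak and gene lists are distributed as XLSX workbooks
#' with one sheet per factor/time point.  The `peaks` schema expects
#' columns `chrom`, `start`, `end` with optional `name`, `summit`,
#' `source`, `stringency`; any remaining columns (typically yes/no
#' overlap annotations against other datasets) are retained, with
#' character yes/no or 1/0 columns coerced to logical.  The `genes`
#' schema expects the [read_gene_table()] columns.  Browser-style
#' workbook coordinates are 1-based inclusive and are converted to the
#' package's 0-based half-open convention on read (set
#' `one_based = FALSE` for workbooks already in BED convention).
#'
#' @param path Path to the workbook.
#' @param sheet Sheet name.
#' @param schema `"peaks"` or `"genes"`.
#' @param exclude Character vector of `name`/`gene_id` values to drop
#'   (e.g. transgene artefacts flagged in the published tables).
#' @param one_based Are workbook coordinates 1-based inclusive?
#' @return An `interval_collection` (peaks) or gene-record data frame.
#' @export
read_supplementary_xlsx <- function(path, sheet, schema = c("peaks", "genes"),
                                    exclude = NULL, one_based = TRUE) {
  schema <- match.arg(schema)
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading XLSX workbooks requires the 'readxl' package")
  if (!file.exists(path)) stop("file not found: ", path)
  sheets <- readxl::excel_sheets(path)
  if (!sheet %in% sheets)
    stop("unknown sheet '", sheet, "'; available sheets: ",
         paste(sheets, collapse = ", "))
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                      stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (schema == "genes") {
    genes <- validate_gene_table(df)
    if (!is.null(exclude)) genes <- genes[!genes$gene_id %in% exclude, , drop = FALSE]
    rownames(genes) <- NULL
    return(genes)
  }
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("sheet '", sheet, "' missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (one_based) df$start <- df$start - 1L
  if (!is.null(df$summit)) {
    df$summit <- as.integer(df$summit)
    if (one_based) df$summit <- df$summit - 1L
  }
  if (!is.null(exclude) && !is.null(df$name))
    df <- df[!df$name %in% exclude, , drop = FALSE]
  known <- c("chrom", "start", "end", "name", "summit", "source", "stringency")
  for (col in setdiff(names(df), known)) {
    v <- df[[col]]
    if (is.character(v) && all(tolower(v) %in% c("yes", "no", "y", "n", "1", "0", NA)))
      df[[col]] <- tolower(v) %in% c("yes", "y", "1")
    else if (is.numeric(v) && all(v %in% c(0, 1, NA)))
      df[[col]] <- v == 1
  }
  interval_collection(df, name = sheet)
}
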