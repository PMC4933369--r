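#' Build a run manifest
#'
#' A validated description of an end-to-end run: the simulation config
#' (or registry of input files), the association distance windows, the
#' motif to test, and an optional output directory for the JSON report.
#'
#' @param config A [sim_config()] (synthetic run) — its `seed` drives
#'   every stage.
#' @param distances Association window half-widths in bp.
#' @param motif A [motif_consensus()] or consensus string for the
#'   enrichment stage.
#' @param inputs Optional named character vector of input file paths
#'   (e.g. externally supplied BED/TSV files); every registered path
#'   must exist before any stage runs.
#' @param output_dir Optional directory for the serialized report.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(config = sim_config(),
                         distances = c(5000L, 10000L, 20000L, 40000L),
                         motif = motif_consensus("Zld", "CAGGTAG"),
                         inputs = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), all(distances > 0),
            !is.unsorted(distances))
  structure(list(config = config, distances = as.integer(distances),
                 motif = as_motif(motif), inputs = inputs,
                 output_dir = output_dir,
                 version = as.character(utils::packageVersion("bmpchip"))),
            class = "run_manifest")
}

#' Run the synthetic analysis pipeline end to end
#'
#' Executes the stages in dependency order — simulate genes/peaks,
#' replicate reproducibility, gene-peak association at every configured
#' distance, proximity fractions, track overlap, phantom-peak
#' classification, and motif enrichment — logging record counts per
#' stage.  Fails before any stage runs if a registered input file is
#' missing.  With a fixed config seed the report is bit-for-bit
#' reproducible.
#'
#' @param manifest A [run_manifest()].
#' @return An object of class `pipeline_report`: a list with `stages`
#'   (per-stage record counts), `association` (one
#'   [association_test()] result per distance), `proximity`
#'   (the [proximity_fractions()] table), `track_overlap_pct`,
#'   `phantom` ([phantom_classify()] result), `motif`
#'   ([enrichment()] result) and `truth` (generator bookkeeping).
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!is.null(manifest$inputs)) {
    absent <- manifest$inputs[!file.exists(manifest$inputs)]
    if (length(absent) > 0)
      stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  cfg <- manifest$config
  stages <- list()

  sim <- simulate_genes_and_peaks(cfg)
  stages$simulate <- c(genes = nrow(sim$genes),
                       peaks_rep1 = nrow(sim$peaks_rep1),
                       peaks_rep2 = nrow(sim$peaks_rep2))

  peaks <- reproducible_peaks(sim$peaks_rep1, sim$peaks_rep2)
  stages$reproducible_peaks <- c(peaks = nrow(peaks))

  association <- lapply(manifest$distances, function(d)
    association_test(peaks, sim$genes, d))
  names(association) <- paste0("d", manifest$distances)
  proximity <- proximity_fractions(peaks, sim$genes, manifest$distances)
  stages$integration <- c(distances = length(manifest$distances),
                          pairs_at_max = nrow(gene_to_peak(
                            peaks, sim$genes, max(manifest$distances))))

  track <- simulate_track(cfg, peaks, seed = cfg$seed + 2L)
  track_overlap_pct <- percentage_overlap(peaks, track)
  stages$track_overlap <- c(track_records = nrow(track))

  phantom_list <- simulate_track(cfg, peaks, overlap_fraction = 0.3,
                                 seed = cfg$seed + 4L)
  damid <- simulate_track(cfg, peaks, overlap_fraction = 0.5,
                          seed = cfg$seed + 5L)
  dual <- intersect_u(peaks, track)
  phantom <- if (nrow(dual) > 0)
    phantom_classify(dual, phantom_list, damid) else NULL
  stages$phantom <- c(dual_bound = nrow(dual),
                      candidates = if (is.null(phantom)) 0L
                                   else nrow(phantom$candidates))

  mw <- simulate_motif_windows(cfg, manifest$motif, seed = cfg$seed + 3L)
  motif <- enrichment(mw$test, mw$control, manifest$motif)
  stages$motif <- c(test_windows = length(mw$test),
                    control_windows = length(mw$control))

  report <- structure(
    list(seed = cfg$seed, stages = stages, association = association,
         proximity = proximity, track_overlap_pct = track_overlap_pct,
         phantom = phantom, motif = motif,
         truth = sim$truth[c("base_rate", "p_near")]),
    class = "pipeline_report")
  if (!is.null(manifest$output_dir)) {
    dir.create(manifest$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_list(report),
                         file.path(manifest$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_list <- function(report) {
  list(seed = report$seed,
       stages = report$stages,
       association = lapply(report$association, function(a)
         list(distance = a$distance, near_de = a$near_de,
              near_nonde = a$near_nonde, tot_de = a$tot_de,
              tot_nonde = a$tot_nonde, chi2_stat = a$chi2_stat,
              chi2_p = a$chi2_p, binom_p = a$binom_p,
              frac_peaks_with_de = a$frac_peaks_with_de)),
       proximity = report$proximity,
       track_overlap_pct = report$track_overlap_pct,
       pct_phantom = if (is.null(report$phantom)) NULL
                     else report$phantom$pct_phantom,
       motif = list(motif = report$motif$motif,
                    pct_test = report$motif$pct_test,
                    pct_control = report$motif$pct_control,
                    ratio = report$motif$ratio,
                    fisher_p = report$motif$fisher_p),
       truth = report$truth)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed", x$seed, ")\n")
  for (st in names(x$stages))
    cat("  ", st, ": ",
        paste(names(x$stages[[st]]), x$stages[[st]], sep = "=",
              collapse = ", "), "\n", sep = "")
  cat("proximity fractions:\n")
  print(x$proximity)
  cat(sprintf("track overlap: %.1f%%; motif ratio %.2f (Fisher p = %.3g)\n",
              x$track_overlap_pct, x$motif$ratio, x$motif$fisher_p))
  invisible(x)
}

#' Recompute supplementary-table summaries from coordinates
#'
#' Given the published peak workbooks (or equivalent in-memory
#' collections), recomputes from coordinates alone the per-sheet peak
#' counts, the pairwise pMad/Brk overlap counts at each time point, the
#' time-point retention fractions (share of early peaks still bound
#' late), and — when a gene table is supplied — the proximity fractions
#' of the combined peak set, reporting computed against expected values
#' side by side.
#'
#' @param peak_sets Named list of four `interval_collection`s:
#'   `pMad_early`, `pMad_late`, `Brk_early`, `Brk_late`.  Alternatively
#'   supply `s2_path` + sheet names to read them from a workbook.
#' @param gene_table Optional gene-record data frame (or `s1_path`).
#' @param s1_path,s2_path Optional workbook paths parsed with
#'   [read_supplementary_xlsx()].
#' @param sheets Sheet names in `s2_path`, in the `peak_sets` order.
#' @param exclude Gene ids to exclude from the S1 list (transgene
#'   artefacts).
#' @param expected Optional named numeric vector of expected values to
#'   display beside the computed ones.
#' @param distances Distances for the proximity fractions.
#' @return A data frame with columns `quantity`, `computed` and (when
#'   given) `expected`.
#' @export
reproduce_supplementary <- function(peak_sets = NULL, gene_table = NULL,
                                    s1_path = NULL, s2_path = NULL,
                                    sheets = c("pMad_2-2.5h", "pMad_3-3.5h",
                                               "Brk_2-2.5h", "Brk_3-3.5h"),
                                    exclude = c("w", "tkv"),
                                    expected = NULL,
                                    distances = c(5000L, 10000L, 20000L,
                                                  40000L)) {
  if (is.null(peak_sets)) {
    if (is.null(s2_path)) stop("supply peak_sets or s2_path")
    peak_sets <- lapply(sheets, function(sh)
      read_supplementary_xlsx(s2_path, sh, schema = "peaks"))
    names(peak_sets) <- c("pMad_early", "pMad_late", "Brk_early", "Brk_late")
  }
  req <- c("pMad_early", "pMad_late", "Brk_early", "Brk_late")
  missing_sets <- setdiff(req, names(peak_sets))
  if (length(missing_sets) > 0)
    stop("peak_sets missing: ", paste(missing_sets, collapse = ", "))
  if (is.null(gene_table) && !is.null(s1_path))
    gene_table <- read_supplementary_xlsx(s1_path, "genes", schema = "genes",
                                          exclude = exclude)
  pm2 <- peak_sets$pMad_early; pm3 <- peak_sets$pMad_late
  bk2 <- peak_sets$Brk_early; bk3 <- peak_sets$Brk_late
  vals <- c(
    n_pMad_early = nrow(pm2), n_pMad_late = nrow(pm3),
    n_Brk_early = nrow(bk2), n_Brk_late = nrow(bk3),
    pMad_Brk_overlap_early = nrow(intersect_u(pm2, bk2)),
    pMad_Brk_overlap_late = nrow(intersect_u(pm3, bk3)),
    pMad_retention = nrow(intersect_u(pm2, pm3)) / max(1, nrow(pm2)),
    Brk_retention = nrow(intersect_u(bk2, bk3)) / max(1, nrow(bk2)))
  bmp <- combine_bmp(pm2, pm3, bk2, bk3)
  vals <- c(vals, n_bmp_combined = nrow(bmp))
  if (!is.null(gene_table)) {
    de <- gene_table$de_status
    vals <- c(vals,
              n_de_genes = sum(de %in% c("up", "down")),
              n_up = sum(de == "up"), n_down = sum(de == "down"))
    prox <- proximity_fractions(bmp, gene_table, distances)
    pv <- prox$pct_peaks_with_gene
    names(pv) <- paste0("pct_peaks_with_de_gene_", prox$distance)
    vals <- c(vals, pv)
  }
  out <- data.frame(quantity = names(vals), computed = unname(vals),
                    stringsAsFactors = FALSE)
  if (!is.null(expected))
    out$expected <- unname(expected[out$quantity])
  out
}
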