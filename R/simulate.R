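#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults describe a
#' small but realistic regulatory-genomics instance: a 2 x 5 Mb genome,
#' 2000 genes of which 15% are differentially expressed (about 300,
#' matching the scale of an embryonic DE gene list), 300 peaks, a
#' three-fold excess of DE genes within 5 kb of a summit, replicate
#' summit jitter of 30 bp with 5% dropout, motif plant rates of 0.4
#' (test) vs 0.1 (control), 60% planted track overlap and 43% GC (the
#' Drosophila euchromatic value).
#'
#' @param seed Integer RNG seed; all generators are byte-deterministic
#'   given the seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bp (recycled to
#'   `n_chrom`).
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes labelled differentially
#'   expressed.
#' @param n_peaks Number of peaks.
#' @param proximity_effect Multiplier >= 1: how much likelier a DE gene
#'   is to lie within `d0` of a summit than chance.
#' @param d0 Proximity window half-width in bp.
#' @param peak_width Peak interval width in bp.
#' @param replicate_jitter_sd Gaussian summit jitter (bp) applied to
#'   replicate 2.
#' @param replicate_dropout Probability a replicate-1 peak is absent
#'   from replicate 2.
#' @param motif_rate_test,motif_rate_control Motif plant rates for test
#'   and control windows.
#' @param track_overlap_fraction Fraction of reference records a
#'   simulated track overlaps.
#' @param track_width Width of simulated track intervals in bp.
#' @param gc_content GC fraction of simulated sequence.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_lengths = 5e6,
                       n_genes = 2000L, de_fraction = 0.15, n_peaks = 300L,
                       proximity_effect = 3, d0 = 5000L, peak_width = 400L,
                       replicate_jitter_sd = 30, replicate_dropout = 0.05,
                       motif_rate_test = 0.4, motif_rate_control = 0.1,
                       track_overlap_fraction = 0.6, track_width = 300L,
                       gc_content = 0.43) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_lengths = as.integer(rep_len(chrom_lengths, n_chrom)),
              n_genes = as.integer(n_genes), de_fraction = de_fraction,
              n_peaks = as.integer(n_peaks),
              proximity_effect = proximity_effect, d0 = as.integer(d0),
              peak_width = as.integer(peak_width),
              replicate_jitter_sd = replicate_jitter_sd,
              replicate_dropout = replicate_dropout,
              motif_rate_test = motif_rate_test,
              motif_rate_control = motif_rate_control,
              track_overlap_fraction = track_overlap_fraction,
              track_width = as.integer(track_width),
              gc_content = gc_content)
  props <- c(cfg$de_fraction, cfg$replicate_dropout, cfg$motif_rate_test,
             cfg$motif_rate_control, cfg$track_overlap_fraction,
             cfg$gc_content)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (cfg$proximity_effect < 1) stop("proximity_effect must be >= 1")
  structure(cfg, class = "sim_config")
}

cfg_chroms <- function(cfg) {
  stats::setNames(cfg$chrom_lengths, paste0("chr", seq_len(cfg$n_chrom)))
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content.  Sets the RNG seed from
#' the config, so repeated calls are byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param path Optional FASTA output path.
#' @return A [Biostrings::DNAStringSet] named chr1..chrN.
#' @export
simulate_genome <- function(cfg, path = NULL) {
  set.seed(cfg$seed)
  gc <- cfg$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(cfg$chrom_lengths, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(cfg_chroms(cfg))
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path)
  genome
}

#' Chromosome-size table of a genome
#' @param genome A [Biostrings::DNAStringSet].
#' @return Data frame with columns `chrom`, `length`.
#' @export
chrom_sizes <- function(genome) {
  data.frame(chrom = names(genome), length = Biostrings::width(genome),
             stringsAsFactors = FALSE)
}

# Sample n independent uniform 0-based positions within a set of
# intervals (data frame chrom/start/end), weighting intervals by width.
sample_positions <- function(iv, n) {
  if (n == 0) return(list(chrom = character(0), pos = integer(0)))
  w <- iv$end - iv$start
  idx <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  pos <- iv$start[idx] + floor(stats::runif(n) * w[idx])
  list(chrom = iv$chrom[idx], pos = as.integer(pos))
}

# Complement of a merged interval set within the chromosomes of `sizes`
# (named length vector).
complement_intervals <- function(merged, sizes) {
  out <- list()
  for (ch in names(sizes)) {
    iv <- merged[merged$chrom == ch, , drop = FALSE]
    starts <- c(0L, iv$end)
    ends <- c(iv$start, sizes[[ch]])
    keep <- ends > starts
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Simulate a gene table and replicate peak sets
#'
#' Peak summits are placed uniformly; non-DE gene TSSs are uniform over
#' the genome.  Each DE gene is placed, with probability
#' `min(1, proximity_effect * base_rate)`, uniformly *inside* the merged
#' summit +/- d0 windows and otherwise uniformly in their complement,
#' where `base_rate` is the fraction of the genome those windows cover —
#' so at `proximity_effect = 1` DE and non-DE geometry are statistically
#' indistinguishable, and the DE/non-DE near-rate ratio approaches the
#' configured effect.  Replicate 2 derives from replicate 1 by Gaussian
#' summit jitter and Bernoulli dropout.  DE labels are assigned before
#' placement: labels cause geometry, the causal direction the
#' association test assumes.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genes` (gene-record data frame),
#'   `peaks_rep1`, `peaks_rep2` (`interval_collection`s) and `truth`
#'   (list with `base_rate`, `p_near`, and the planted near indicator).
#' @export
simulate_genes_and_peaks <- function(cfg) {
  set.seed(cfg$seed + 1L)
  sizes <- cfg_chroms(cfg)
  half <- cfg$peak_width %/% 2L
  margin <- cfg$peak_width + 1000L
  genome_iv <- data.frame(chrom = names(sizes), start = 0L,
                          end = unname(sizes), stringsAsFactors = FALSE)
  place_iv <- data.frame(chrom = names(sizes), start = margin,
                         end = unname(sizes) - margin, stringsAsFactors = FALSE)
  if (any(place_iv$end <= place_iv$start))
    stop("chromosomes too short for peak placement")
  ps <- sample_positions(place_iv, cfg$n_peaks)
  rep1 <- interval_collection(data.frame(
    chrom = ps$chrom, start = ps$pos - half, end = ps$pos + half,
    name = sprintf("peak_%04d", seq_len(cfg$n_peaks)),
    summit = ps$pos, source = "sim_rep1", stringency = "p4",
    stringsAsFactors = FALSE), name = "rep1")

  keep <- stats::runif(cfg$n_peaks) >= cfg$replicate_dropout
  jit <- as.integer(round(stats::rnorm(cfg$n_peaks, 0, cfg$replicate_jitter_sd)))
  r2 <- as.data.frame(rep1)[keep, , drop = FALSE]
  j <- jit[keep]
  r2$start <- pmax(0L, r2$start + j)
  r2$end <- r2$end + j
  r2$summit <- pmin(pmax(r2$summit + j, r2$start), r2$end - 1L)
  r2$source <- "sim_rep2"
  rep2 <- interval_collection(r2, name = "rep2")

  windows <- merge_intervals(interval_collection(data.frame(
    chrom = rep1$chrom,
    start = pmax(0L, rep1$summit - cfg$d0),
    end = pmin(sizes[rep1$chrom], rep1$summit + cfg$d0 + 1L),
    stringsAsFactors = FALSE)))
  total <- sum(as.numeric(sizes))
  base_rate <- covered_bases(windows) / total
  if (base_rate >= 1)
    stop("proximity windows cover the whole genome; placement infeasible")
  comp <- complement_intervals(windows, sizes)
  p_near <- min(1, cfg$proximity_effect * base_rate)

  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de <- c(rep(TRUE, n_de), rep(FALSE, cfg$n_genes - n_de))
  near <- rep(FALSE, cfg$n_genes)
  near[de] <- stats::runif(n_de) < p_near
  chrom <- character(cfg$n_genes); pos <- integer(cfg$n_genes)
  in_win <- sample_positions(as.data.frame(windows), sum(near))
  chrom[near] <- in_win$chrom; pos[near] <- in_win$pos
  out_win <- sample_positions(comp, sum(de & !near))
  chrom[de & !near] <- out_win$chrom; pos[de & !near] <- out_win$pos
  unif <- sample_positions(genome_iv, sum(!de))
  chrom[!de] <- unif$chrom; pos[!de] <- unif$pos

  de_dir <- sample(c("up", "down"), n_de, replace = TRUE, prob = c(1, 2) / 3)
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(cfg$n_genes)),
    chrom = chrom, tss = pos,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    de_status = ifelse(de, c(de_dir, rep("", cfg$n_genes - n_de)), "not_de"),
    adj_p = ifelse(de, stats::runif(cfg$n_genes, 0, 0.0299),
                   stats::runif(cfg$n_genes, 0.03, 1)),
    stringsAsFactors = FALSE)
  list(genes = genes, peaks_rep1 = rep1, peaks_rep2 = rep2,
       truth = list(base_rate = base_rate, p_near = p_near,
                    planted_near = near, de = de))
}

#' Simulate an overlap track against a reference collection
#'
#' Each reference record is overlapped independently with probability
#' `overlap_fraction` (one track interval anchored uniformly within the
#' record); decoy intervals are then placed in positions guaranteed not
#' to touch the reference, so the measured record-level overlap of the
#' reference against the track is Binomial(n, fraction)/n.
#'
#' @param cfg A [sim_config()].
#' @param reference An `interval_collection` (e.g. a peak set).
#' @param overlap_fraction Fraction of reference records to overlap
#'   (default from `cfg`).
#' @param n_decoys Number of non-overlapping decoy intervals.
#' @param seed RNG seed (default derived from `cfg$seed`; vary it to
#'   draw independent tracks for different factors).
#' @return An `interval_collection`.
#' @export
simulate_track <- function(cfg, reference,
                           overlap_fraction = cfg$track_overlap_fraction,
                           n_decoys = nrow(reference),
                           seed = cfg$seed + 2L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  set.seed(seed)
  sizes <- cfg_chroms(cfg)
  w <- cfg$track_width
  sel <- which(stats::runif(nrow(reference)) < overlap_fraction)
  parts <- list()
  if (length(sel) > 0) {
    # one anchor per selected record, uniform inside it, so the track
    # interval is guaranteed to overlap that record
    rw <- reference$end[sel] - reference$start[sel]
    anchor <- reference$start[sel] + as.integer(floor(stats::runif(length(sel)) * rw))
    parts$hit <- data.frame(chrom = reference$chrom[sel],
                            start = pmax(0L, anchor - w %/% 2L),
                            end = anchor + w %/% 2L + 1L,
                            stringsAsFactors = FALSE)
  }
  if (n_decoys > 0) {
    buffered <- merge_intervals(interval_collection(data.frame(
      chrom = reference$chrom,
      start = pmax(0L, reference$start - w - 1L),
      end = reference$end + w + 1L, stringsAsFactors = FALSE)))
    gaps <- complement_intervals(buffered, sizes)
    gaps <- gaps[gaps$end - gaps$start > w, , drop = FALSE]
    if (nrow(gaps) == 0) stop("no room for decoy intervals")
    gaps$end <- gaps$end - w  # so a decoy starting here fits entirely
    dp <- sample_positions(gaps, n_decoys)
    parts$decoy <- data.frame(chrom = dp$chrom, start = dp$pos,
                              end = dp$pos + w, stringsAsFactors = FALSE)
  }
  if (length(parts) == 0)
    return(interval_collection(data.frame(
      chrom = character(), start = integer(), end = integer()),
      name = "track"))
  interval_collection(do.call(rbind, unname(parts)), name = "track")
}

iupac_sets <- function() strsplit(Biostrings::IUPAC_CODE_MAP, "")

instantiate_consensus <- function(consensus) {
  sets <- iupac_sets()[strsplit(toupper(consensus), "")[[1]]]
  paste(vapply(sets, function(s) s[sample.int(length(s), 1)], character(1)),
        collapse = "")
}

#' Simulate motif test/control window sets
#'
#' Random windows at the configured GC content, with one instantiation
#' of the consensus planted at a uniform offset with probability
#' `motif_rate_test` (test windows) or `motif_rate_control` (control
#' windows).
#'
#' @param cfg A [sim_config()].
#' @param motif A [motif_consensus()] or consensus string.
#' @param n_test,n_control Window counts.
#' @param width Window width in bp (default 250, the summit-window
#'   convention).
#' @param seed RNG seed (default derived from `cfg$seed`).
#' @return List with character vectors `test`, `control` and logical
#'   plant indicators `planted_test`, `planted_control`.
#' @export
simulate_motif_windows <- function(cfg, motif, n_test = 200L,
                                   n_control = 200L, width = 250L,
                                   seed = cfg$seed + 3L) {
  set.seed(seed)
  motif <- as_motif(motif)
  k <- nchar(motif$consensus)
  stopifnot(width >= k)
  gc <- cfg$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  gen <- function(n, rate) {
    planted <- stats::runif(n) < rate
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(names(p), width, replace = TRUE, prob = p)
      if (planted[i]) {
        at <- sample.int(width - k + 1L, 1)
        s[at:(at + k - 1L)] <- strsplit(instantiate_consensus(motif$consensus),
                                        "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    list(seqs = seqs, planted = planted)
  }
  te <- gen(n_test, cfg$motif_rate_test)
  co <- gen(n_control, cfg$motif_rate_control)
  list(test = te$seqs, control = co$seqs,
       planted_test = te$planted, planted_control = co$planted)
}
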