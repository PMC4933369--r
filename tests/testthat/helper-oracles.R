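# Independent brute-force oracles for interval algebra, motif scanning
# and Fisher's exact test.  These deliberately avoid the package's own
# code paths (and GenomicRanges) so they can serve as ground truth.

rand_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000L,
                           max_w = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  interval_collection(data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + w, stringsAsFactors = FALSE))
}

# indices of records in `a` sharing >= 1 base with any record of `b`
# (half-open arithmetic, all-pairs scan)
brute_overlap_idx <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  which(hit)
}

# number of distinct covered bases, by explicit per-base enumeration
brute_covered_bases <- function(a) {
  total <- 0L
  for (ch in unique(a$chrom)) {
    iv <- a[a$chrom == ch, , drop = FALSE]
    bases <- unique(unlist(Map(function(s, e) seq.int(s, e - 1L),
                               iv$start, iv$end)))
    total <- total + length(bases)
  }
  total
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

iupac_regex <- function(consensus) {
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

revcomp_consensus <- function(consensus) {
  paste(rev(unname(IUPAC_COMPLEMENT[strsplit(toupper(consensus), "")[[1]]])),
        collapse = "")
}

# regex-expansion oracle for both-strand IUPAC scanning; N in the
# sequence matches nothing because the character classes above contain
# only A/C/G/T
oracle_scan <- function(seq, consensus) {
  grepl(iupac_regex(consensus), seq) |
    grepl(iupac_regex(revcomp_consensus(consensus)), seq)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# two-tailed Fisher's exact p by exhaustive hypergeometric enumeration
# over all tables with the observed margins
fisher_enum <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

rand_genes <- function(n, chroms = c("chrA", "chrB"), max_pos = 100000L,
                       de_frac = 0.3) {
  de <- runif(n) < de_frac
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = sample.int(max_pos, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    de_status = ifelse(de, sample(c("up", "down"), n, replace = TRUE),
                       "not_de"),
    adj_p = ifelse(de, runif(n, 0, 0.0299), runif(n, 0.03, 1)),
    stringsAsFactors = FALSE)
}

# all (peak, gene) pairs with |tss - summit| <= d, by explicit loops
brute_pairs <- function(peaks, genes, d) {
  sm <- summits(peaks)
  ids <- if (!is.null(peaks$name)) peaks$name
         else paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] == genes$chrom[j] &&
          abs(genes$tss[j] - sm[i]) <= d)
        out[[length(out) + 1]] <- data.frame(
          peak_id = ids[i], gene_id = genes$gene_id[j],
          distance = genes$tss[j] - sm[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer()))
  res <- do.call(rbind, out)
  res[order(res$peak_id, res$gene_id), , drop = FALSE]
}

expect_same_pairs <- function(got, want) {
  key <- function(df) sort(paste(df$peak_id, df$gene_id, df$distance))
  expect_identical(key(got), key(want))
}
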