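test_that("BED parsing preserves half-open coordinates and rejects bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2L\t100\t200", path)
  x <- read_bed(path)
  expect_equal(nrow(x), 1)
  expect_identical(x$chrom, "chr2L")
  expect_identical(x$start, 100L)
  expect_identical(x$end, 200L)

  writeLines("chr2L\t200\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr2L\t100\t200", "chr2L\t5"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr2L\tabc\t200", path)
  expect_error(read_bed(path), "non-integer")
})

test_that("BED files round-trip byte-identically through write and read", {
  set.seed(42)
  for (rep in 1:20) {
    x <- rand_intervals(sample(1:30, 1))
    x$name <- sprintf("r%03d", seq_len(nrow(x)))
    x$summit <- x$start + floor((x$end - x$start) / 2)
    p1 <- withr::local_tempfile(fileext = ".bed")
    p2 <- withr::local_tempfile(fileext = ".bed")
    write_bed(x, p1)
    y <- read_bed(p1)
    expect_equal(as.data.frame(y)[c("chrom", "start", "end", "name", "summit")],
                 as.data.frame(x)[c("chrom", "start", "end", "name", "summit")])
    write_bed(y, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("gene tables validate de_status, strand and required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  g <- data.frame(gene_id = "g1", chrom = "chr2L", tss = 5000L, strand = "+",
                  de_status = "up", adj_p = 0.001)
  write_gene_table(g, path)
  got <- read_gene_table(path)
  expect_identical(got$de_status, "up")
  expect_identical(got$tss, 5000L)

  g2 <- g; g2$de_status <- "maybe"
  write_gene_table(g2, path)
  expect_error(read_gene_table(path), "maybe")

  g3 <- g[, setdiff(names(g), c("tss", "strand"))]
  utils::write.table(g3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(path), "tss, strand")

  # DE label inconsistent with the adjusted-p cutoff
  g4 <- g; g4$adj_p <- 0.5
  write_gene_table(g4, path)
  expect_error(read_gene_table(path), "adj_p")
})

test_that("gene tables round-trip with de_status counts preserved", {
  set.seed(7)
  g <- rand_genes(100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g, path)
  got <- read_gene_table(path)
  expect_equal(nrow(got), 100)
  expect_identical(table(got$de_status), table(g$de_status))
})

test_that("intersect_u reports >=1 bp overlaps once each under half-open semantics", {
  a <- interval_collection(data.frame(chrom = "chr2L", start = 100L, end = 200L))
  b1 <- interval_collection(data.frame(chrom = "chr2L", start = 199L, end = 300L))
  b2 <- interval_collection(data.frame(chrom = "chr2L", start = 200L, end = 300L))
  expect_equal(nrow(intersect_u(a, b1)), 1)  # one shared base
  expect_equal(nrow(intersect_u(a, b2)), 0)  # book-ended: no shared base
  expect_equal(nrow(intersect_u(a, a[integer(0), ])), 0)

  set.seed(11)
  for (rep in 1:40) {
    x <- rand_intervals(sample(5:40, 1))
    y <- rand_intervals(sample(5:40, 1))
    got <- intersect_u(x, y)
    want <- x[brute_overlap_idx(x, y), , drop = FALSE]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
    expect_lte(nrow(got), nrow(x))  # subset invariant
  }
})

test_that("merge unions overlapping and book-ended records, idempotently", {
  x <- interval_collection(data.frame(chrom = "chr2L",
                                      start = c(100L, 150L), end = c(200L, 250L)))
  m <- merge_intervals(x)
  expect_equal(as.data.frame(m),
               data.frame(chrom = "chr2L", start = 100L, end = 250L),
               ignore_attr = TRUE)
  disjoint <- interval_collection(data.frame(
    chrom = "chr2L", start = c(0L, 500L), end = c(100L, 600L)))
  expect_equal(as.data.frame(merge_intervals(disjoint)),
               as.data.frame(disjoint), ignore_attr = TRUE)
  # book-ended records join (merge distance 0)
  be <- interval_collection(data.frame(chrom = "chr2L",
                                       start = c(100L, 200L), end = c(200L, 300L)))
  expect_equal(nrow(merge_intervals(be)), 1)

  set.seed(13)
  for (rep in 1:25) {
    x <- rand_intervals(sample(5:100, 1), max_pos = 5000L, max_w = 300L)
    m <- merge_intervals(x)
    expect_identical(as.data.frame(merge_intervals(m)), as.data.frame(m))
    # disjointness: within chromosome, next start exceeds previous end
    for (ch in unique(m$chrom)) {
      iv <- m[m$chrom == ch, ]
      if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    }
    expect_equal(covered_bases(m), brute_covered_bases(x))
  }
})

test_that("subtract_u partitions a collection against a second track", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rand_intervals(sample(5:40, 1))
    y <- rand_intervals(sample(5:40, 1))
    expect_equal(nrow(subtract_u(x, y)) + nrow(intersect_u(x, y)), nrow(x))
  }
})

test_that("summits fall back to interval midpoints and chrom naming can be normalized", {
  x <- interval_collection(data.frame(chrom = "2L", start = 100L, end = 201L))
  expect_identical(summits(x), 150L)
  x2 <- normalize_chrom(x, "chr")
  expect_identical(x2$chrom, "chr2L")
  expect_identical(normalize_chrom(x2, "nochr")$chrom, "2L")
  # summit invariant enforced
  expect_error(interval_collection(
    data.frame(chrom = "c", start = 100L, end = 200L, summit = 300L)),
    "summit")
})
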