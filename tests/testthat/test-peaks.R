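iv <- function(start, end, chrom = "chr2L", ...) {
  interval_collection(data.frame(chrom = chrom, start = as.integer(start),
                                 end = as.integer(end), ...,
                                 stringsAsFactors = FALSE))
}

test_that("reproducible peaks keep replicate-1 coordinates of overlapping calls", {
  expect_equal(as.data.frame(reproducible_peaks(iv(100, 200), iv(150, 250))),
               as.data.frame(iv(100, 200)), ignore_attr = TRUE)
  expect_equal(nrow(reproducible_peaks(iv(100, 200), iv(300, 400))), 0)

  set.seed(19)
  for (rep in 1:20) {
    r1 <- rand_intervals(sample(5:40, 1))
    r2 <- rand_intervals(sample(5:40, 1))
    expect_identical(as.data.frame(reproducible_peaks(r1, r2)),
                     as.data.frame(intersect_u(r1, r2)))
  }
  # intersection-span mode returns spans contained in both replicates
  got <- reproducible_peaks(iv(100, 200), iv(150, 250), coords = "intersection")
  expect_equal(got$start, 150L)
  expect_equal(got$end, 200L)
})

test_that("stringency refinement swaps in strict coordinates where available", {
  expect_equal(as.data.frame(stringency_refine(iv(100, 400), iv(200, 300))),
               as.data.frame(iv(200, 300)), ignore_attr = TRUE)
  empty <- iv(1, 2)[integer(0), ]
  expect_equal(as.data.frame(stringency_refine(iv(100, 400), empty)),
               as.data.frame(iv(100, 400)), ignore_attr = TRUE)
  # several strict peaks inside one loose peak: all strict emitted,
  # loose dropped
  got <- stringency_refine(iv(100, 400), iv(c(120, 250), c(180, 330)))
  expect_equal(as.data.frame(got)[c("start", "end")],
               data.frame(start = c(120L, 250L), end = c(180L, 330L)),
               ignore_attr = TRUE)
  # loose peak without strict support is retained alongside refinements
  got <- stringency_refine(iv(c(100, 1000), c(400, 1400)), iv(200, 300))
  expect_setequal(got$start, c(200L, 1000L))
  # strict peak with no loose counterpart warns
  expect_warning(stringency_refine(iv(100, 400), iv(5000, 5100)),
                 "strict peak")
  # refinement never enlarges coverage when strict peaks are sub-intervals
  set.seed(23)
  for (rep in 1:15) {
    loose <- rand_intervals(20, max_pos = 50000L, max_w = 400L)
    pick <- sample(nrow(loose), 8)
    strict <- loose[pick, ]
    strict$start <- strict$start + 5L
    strict$end <- pmax(strict$start + 1L, strict$end - 5L)
    strict <- interval_collection(as.data.frame(strict))
    out <- suppressWarnings(stringency_refine(loose, strict))
    expect_lte(covered_bases(out), covered_bases(loose))
  }
})

test_that("time-point combination keeps late coordinates and labels contributors", {
  got <- combine_timepoints(iv(100, 200), iv(150, 260),
                            labels = c("2-2.5h", "3-3.5h"))
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 150L)
  expect_identical(got$timepoints, "2-2.5h,3-3.5h")

  empty <- iv(1, 2)[integer(0), ]
  got <- combine_timepoints(iv(100, 200), empty)
  expect_equal(got$start, 100L)
  expect_identical(got$timepoints, "early")

  set.seed(29)
  for (rep in 1:20) {
    early <- rand_intervals(sample(5:40, 1))
    late <- rand_intervals(sample(5:40, 1))
    got <- combine_timepoints(early, late)
    n_early_only <- nrow(early) - length(brute_overlap_idx(early, late))
    expect_equal(nrow(got), nrow(late) + n_early_only)
    # precedence consistency: every output span exists in an input
    inputs <- c(paste(early$chrom, early$start, early$end),
                paste(late$chrom, late$start, late$end))
    expect_true(all(paste(got$chrom, got$start, got$end) %in% inputs))
  }
})

test_that("BMP combination follows pMad3 > Brk3 > pMad2 > Brk2 precedence", {
  empty <- iv(1, 2)[integer(0), ]
  # one pMad-late peak overlapping one Brk-late peak: pMad-late wins
  got <- combine_bmp(pmad_early = empty, pmad_late = iv(100, 200),
                     brk_early = empty, brk_late = iv(150, 250))
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100L)
  expect_true(got$pMad3 && got$Brk3)
  expect_false(got$pMad2 || got$Brk2)

  got <- combine_bmp(iv(1000, 1100), iv(100, 200), iv(3000, 3100),
                     iv(5000, 5100))
  expect_equal(nrow(got), 4)

  # chained overlap collapses onto the highest-precedence coordinates
  got <- combine_bmp(pmad_early = iv(90, 160), pmad_late = iv(150, 250),
                     brk_early = empty, brk_late = iv(240, 320))
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 150L)
})

test_that("factor datasets merge to a disjoint union", {
  a <- iv(100, 200)
  expect_equal(as.data.frame(merge_factor_datasets(list(a, a))),
               as.data.frame(merge_intervals(a)), ignore_attr = TRUE)
  got <- merge_factor_datasets(list(iv(100, 200), iv(150, 300)))
  expect_equal(as.data.frame(got),
               data.frame(chrom = "chr2L", start = 100L, end = 300L),
               ignore_attr = TRUE)
  set.seed(31)
  for (rep in 1:15) {
    sets <- replicate(3, rand_intervals(sample(5:30, 1)), simplify = FALSE)
    got <- merge_factor_datasets(sets)
    cat_df <- do.call(rbind, lapply(sets, function(x)
      as.data.frame(x)[c("chrom", "start", "end")]))
    want <- merge_intervals(interval_collection(cat_df))
    expect_identical(as.data.frame(got), as.data.frame(want))
  }
})

test_that("normalization factors equalize per-sample medians exactly", {
  nf <- normalization_factors(c(10, 20, 30))
  expect_equal(nf$factors, c(2, 1, 2 / 3))
  expect_equal(normalization_factors(c(7, 7, 7))$factors, c(1, 1, 1))
  set.seed(37)
  m <- runif(8, 0.5, 50)
  nf <- normalization_factors(m)
  expect_equal(nf$factors * m, rep(mean(m), 8))  # medians equalized
  expect_error(normalization_factors(c(10, 0)), "positive")
  expect_error(normalization_factors(c(10, -3)), "positive")
})
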