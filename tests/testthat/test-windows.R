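# Window scan, candidate selection, merging and refinement.

constant_aln <- function(n, L) {
  as_alignment(setNames(rep(strrep("A", L), n), paste0("s", seq_len(n))))
}

# plant a singleton SNP (one sample C on an A background) at 0-based columns
plant_snps <- function(aln, cols0) {
  cols0 <- unique(as.integer(cols0))
  mat <- unclass(aln)
  for (j in cols0) mat[1 + (j %% 2), j + 1] <- "C"
  as_alignment(apply(mat, 1, paste, collapse = ""), ids = rownames(mat))
}

test_that("windows tile the alignment with a true-length tail", {
  aln <- constant_aln(4, 1250)
  w <- scan_windows(aln, 500)
  expect_equal(w$start, c(0, 500, 1000))
  expect_equal(w$end, c(500, 1000, 1250))
  expect_equal(w$snp_count, c(0, 0, 0))
  # window larger than alignment: one window over everything
  w1 <- scan_windows(aln, 5000)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(0, 1250))
  expect_error(scan_windows(aln, 0), "domain")
})

test_that("planted SNPs land in the right window", {
  aln <- plant_snps(constant_aln(6, 1500), seq(500, 999, length.out = 30))
  w <- scan_windows(aln, 500)
  expect_equal(w$snp_count, c(0, 30, 0))
  expect_equal(w$variability, c(0, 0.06, 0))
})

test_that("window SNP counts sum to the total variable-column count", {
  set.seed(11)
  for (i in 1:15) {
    aln <- random_alignment(sample(4:10, 1), sample(30:400, 1))
    ws <- sample(c(7, 50, 500), 1)
    w <- scan_windows(aln, ws)
    expect_equal(sum(w$snp_count), sum(classify_columns(aln)$variable))
    expect_true(all(w$variability >= 0 & w$variability <= 1))
  }
})

test_that("masked fraction counts cells, not columns", {
  aln <- as_alignment(c(a = strrep("A", 100), b = strrep("A", 100),
                        c = paste0(strrep("N", 40), strrep("A", 60)),
                        d = strrep("A", 100)))
  w <- scan_windows(aln, 50)
  expect_equal(w$masked_fraction, c(40 / 200, 0))
})

test_that("candidate thresholds are strict on both sides", {
  w <- data.frame(
    start = c(0, 500, 1000), end = c(500, 1000, 1500),
    snp_count = c(25, 26, 124),
    variability = c(25, 26, 124) / 500,
    masked_fraction = c(0, 0, 0.10)
  )
  sel <- select_candidates(w)
  expect_equal(sel$start, 500)      # exactly 5% rejected; 10% masked rejected
  expect_equal(nrow(select_candidates(w, max_masked = 0.2)), 2L)
})

test_that("lowering the variability threshold never drops a window", {
  set.seed(3)
  aln <- random_alignment(8, 600, p_missing = 0.01)
  w <- scan_windows(aln, 50)
  for (thr in c(0.3, 0.2, 0.1, 0.05, 0)) {
    sel_hi <- select_candidates(w, min_variability = thr + 0.05)
    sel_lo <- select_candidates(w, min_variability = thr)
    expect_true(all(sel_hi$start %in% sel_lo$start))
  }
})

test_that("adjacent candidate windows merge into one barcode region", {
  two <- data.frame(start = c(500, 1000), end = c(1000, 1500),
                    snp_count = 30, variability = 0.06, masked_fraction = 0)
  m <- merge_candidates(two)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(500, 1500))
  expect_equal(m$source, "window-merge")

  four <- data.frame(start = seq(0, 1500, 500), end = seq(500, 2000, 500),
                     snp_count = 30, variability = 0.06, masked_fraction = 0)
  m4 <- merge_candidates(four)
  expect_equal(m4$end - m4$start, 2000)

  gap <- data.frame(start = c(0, 1000), end = c(500, 1500),
                    snp_count = 30, variability = 0.06, masked_fraction = 0)
  m2 <- merge_candidates(gap)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$end - m2$start, c(500, 500))

  expect_equal(nrow(merge_candidates(two[0, ])), 0L)
})

test_that("merged region lengths conserve selected window footprint", {
  set.seed(19)
  for (i in 1:10) {
    n_win <- sample(3:12, 1)
    starts <- sort(sample(seq(0, 10000, 500), n_win))
    sel <- data.frame(start = starts, end = starts + 500,
                      snp_count = 30, variability = 0.06,
                      masked_fraction = 0)
    m <- merge_candidates(sel)
    expect_equal(sum(m$end - m$start), 500 * n_win)
  }
})

test_that("refinement trims low-variability flanks down to the variable core", {
  # 2000-bp region, variable columns only inside [600, 1390)
  core <- as.integer(seq(600, 1389, length.out = 40))
  aln <- plant_snps(constant_aln(6, 2000), core)
  r <- refine_region(aln, barcode_region("big", 0, 2000))
  expect_equal(r$source, "refined")
  expect_equal(c(r$start, r$end), c(600, 1400))  # sub-window resolution

  # uniformly variable region comes back unchanged
  dense <- plant_snps(constant_aln(6, 300), seq(0, 299, by = 10))
  r2 <- refine_region(dense, barcode_region("flat", 0, 300))
  expect_equal(c(r2$start, r2$end), c(0, 300))

  # no variation: single best sub-window plus warning
  expect_warning(
    r3 <- refine_region(constant_aln(4, 500), barcode_region("dead", 0, 500)),
    "best sub-window")
  expect_equal(r3$end - r3$start, 50)
})

test_that("refinement validates its interval", {
  aln <- constant_aln(4, 100)
  expect_error(refine_region(aln, barcode_region("x", 0, 200)), "interval")
  expect_error(refine_region(aln, barcode_region("x", 0, 30), subwindow = 50),
               "domain")
})

test_that("BED output round-trips regions in 0-based half-open coordinates", {
  aln <- plant_snps(constant_aln(4, 600), c(100, 150, 480))
  regions <- rbind(barcode_region("alpha", 100, 200),
                   barcode_region("beta", 450, 600))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, path, aln = aln)
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw$V2, c(100, 450))            # BED is 0-based on disk
  expect_equal(raw$V5, c(2, 1))                # score = SNP count
  back <- read_bed(path)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$name, regions$name)
})

test_that("density table export matches the scan", {
  aln <- plant_snps(constant_aln(4, 300), c(10, 260))
  w <- scan_windows(aln, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_density(w, path)
  tab <- read.delim(path)
  expect_equal(tab$start_0based, w$start)
  expect_equal(tab$snp_count, w$snp_count)
})
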