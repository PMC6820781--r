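cfg <- test_locus()

test_that("constructed reads anchor with full coverage and exact interval", {
  read <- paste0(cfg$left_flank, strrep("TTTTA", 20), cfg$right_flank)
  loc <- locate_expansion(read, cfg)
  expect_equal(loc$orientation, "plus")
  expect_equal(loc$coverage, "full")
  # interval is exactly the 100-base repeat stretch (0-based half-open)
  expect_equal(loc$interval,
               c(nchar(cfg$left_flank), nchar(cfg$left_flank) + 100L))
})

test_that("reverse-complement reads normalize to the same interval", {
  read <- paste0(cfg$left_flank, strrep("TTTTA", 20), cfg$right_flank)
  loc <- locate_expansion(famex:::revcomp(read), cfg)
  expect_equal(loc$orientation, "minus")
  expect_equal(loc$coverage, "full")
  expect_equal(loc$interval,
               c(nchar(cfg$left_flank), nchar(cfg$left_flank) + 100L))
})

test_that("one-sided reads yield partial coverage", {
  left_only <- paste0(cfg$left_flank, strrep("TTTTA", 2000))
  loc <- locate_expansion(left_only, cfg)
  expect_equal(loc$coverage, "left_partial")
  dr <- decompose_read(left_only, cfg)
  expect_equal(dr$coverage, "left_partial")
  expect_equal(dr$units_exact[["total"]], 2000L)
  right_only <- paste0(strrep("TTTCA", 500), cfg$right_flank)
  expect_equal(locate_expansion(right_only, cfg)$coverage, "right_partial")
})

test_that("a read without any anchor raises locus-not-found", {
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_error(locate_expansion(junk, cfg), "locus not found")
  expect_error(locate_expansion("ACGT", cfg), "min_anchor_len")
})

test_that("5'/3' TTTTA assignment splits around the first TTTCA", {
  read <- paste0(cfg$left_flank, strrep("TTTTA", 30), strrep("TTTCA", 40),
                 strrep("TTTTA", 10), cfg$right_flank)
  dr <- decompose_read(read, cfg)
  expect_equal(unname(dr$units_exact[c("TTTTA_5p", "TTTCA", "TTTTA_3p")]),
               c(30L, 40L, 10L))
  # per-class kb excludes gaps; total includes the whole span
  expect_equal(dr$size_kb[["TTTCA"]], 40 * 5 / 1000)
  expect_equal(dr$size_kb[["total"]], (30 + 40 + 10) * 5 / 1000)
  # no TTTCA: everything is 5'
  dr2 <- decompose_read(paste0(cfg$left_flank, strrep("TTTTA", 25),
                               cfg$right_flank), cfg)
  expect_equal(dr2$units_exact[["TTTTA_5p"]], 25L)
  expect_equal(dr2$units_exact[["TTTTA_3p"]], 0L)
})

test_that("summarize_reads averages full reads and flags empty input", {
  mk <- function(u5, uc) {
    decompose_read(paste0(cfg$left_flank, strrep("TTTTA", u5),
                          strrep("TTTCA", uc), cfg$right_flank), cfg)
  }
  # spans 4,000 and 6,000 bases -> mean 5.00 kb
  s <- summarize_reads(list(mk(500, 300), mk(700, 500)))
  expect_equal(s$mean_size_kb[["total"]], 5.0)
  expect_equal(s$n_included, 2L)
  # partial reads are excluded from means by default
  partial <- decompose_read(paste0(cfg$left_flank, strrep("TTTTA", 1200)),
                            cfg)
  s2 <- summarize_reads(list(mk(500, 300), partial))
  expect_equal(s2$n_reads, 2L)
  expect_equal(s2$n_included, 1L)
  expect_equal(s2$mean_size_kb[["total"]], 4.0)
  s3 <- summarize_reads(list(partial))
  expect_true(s3$undefined)
  expect_equal(s3$n_included, 0L)
})

test_that("summaries are strand invariant", {
  read <- paste0(cfg$left_flank, strrep("TTTTA", 100), strrep("TTTCA", 80),
                 cfg$right_flank)
  a <- decompose_read(read, cfg)
  b <- decompose_read(famex:::revcomp(read), cfg)
  expect_equal(a$units_exact, b$units_exact)
  expect_equal(a$size_kb, b$size_kb)
  expect_equal(summarize_reads(list(a))$mean_size_kb,
               summarize_reads(list(b))$mean_size_kb)
})

test_that("summarize over error-free simulated reads recovers truth mean", {
  model <- expansion_model(n_ttta5 = 500L, n_tttca = 400L, n_ttta3 = 100L,
                           somatic_cv = 0, config_mix = c(C2 = 1))
  cells <- simulate_allele_population(model, n_cells = 5, seed = 77)
  reads <- emit_long_reads(cells, cfg,
                           error_model = read_error_model(0, 0, 0),
                           n_reads = 10, p_truncate = 0,
                           p_fusion_if_rearranged = 0, seed = 78)
  dec <- decompose_reads(setNames(reads$sequence, reads$read_id), cfg)
  s <- summarize_reads(dec)
  expect_equal(s$mean_size_kb[["total"]], 5.0)  # 1000 units x 5 bp
  expect_equal(s$units_range, c(1000, 1000))
})
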