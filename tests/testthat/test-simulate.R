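cfg <- test_locus()

test_that("emitters are deterministic given the seed", {
  model <- expansion_model()
  a <- simulate_allele_population(model, n_cells = 30, seed = 5)
  b <- simulate_allele_population(model, n_cells = 30, seed = 5)
  expect_identical(a, b)
  ra <- emit_long_reads(a, cfg, n_reads = 5, seed = 6)
  rb <- emit_long_reads(b, cfg, n_reads = 5, seed = 6)
  expect_identical(ra, rb)
  ca <- emit_combing_table(a, seed = 7)
  cb <- emit_combing_table(b, seed = 7)
  expect_identical(ca, cb)
  # byte-identical file output
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_long_reads(a, cfg, n_reads = 5, seed = 6, out = f1)
  emit_long_reads(a, cfg, n_reads = 5, seed = 6, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_allele_population(model, 5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("zero somatic jitter reproduces the germline in every cell", {
  model <- expansion_model(n_ttta5 = 500L, n_tttca = 300L, n_ttta3 = 100L,
                           somatic_cv = 0, config_mix = c(C2 = 1))
  cells <- simulate_allele_population(model, n_cells = 20, seed = 1)
  expect_true(all(cells$n_ttta5 == 500L))
  expect_true(all(cells$n_tttca == 300L))
  expect_true(all(cells$n_ttta3 == 100L))
  expect_true(all(cells$units_total == 900L))
})

test_that("configurations redistribute units without changing the total", {
  set.seed(33)
  for (config in paste0("C", 1:6)) {
    n5 <- sample(100:800, 1); nc <- sample(100:800, 1)
    n3 <- sample(10:200, 1)
    cnt <- famex:::redistribute_units(config, n5, nc, n3)
    expect_equal(sum(cnt), n5 + nc + n3)
    blocks <- famex:::config_blocks(config, cnt[1], cnt[2], cnt[3])
    expect_equal(sum(blocks$units), n5 + nc + n3)
    # C5 is red-negative; C3/C4/C6 split the red part into 2-3 blocks
    n_red <- sum(blocks$class == "tttca")
    expect_equal(n_red, switch(config, C1 = 1L, C2 = 1L, C3 = 2L,
                               C4 = 2L, C5 = 0L, C6 = 3L))
  }
})

test_that("rearrangement probability is a scaled logistic of size", {
  model <- expansion_model()
  expect_equal(p_rearrange(model, model$rearrange_midpoint_kb),
               model$rearrange_pmax / 2)
  expect_lt(p_rearrange(model, 4), 0.005)
  expect_true(all(diff(p_rearrange(model, seq(1, 40))) > 0))
  # Monte-Carlo calibration at the stated scales
  big <- expansion_model(n_ttta5 = 480L, n_tttca = 2080L, n_ttta3 = 240L)
  cells <- simulate_allele_population(big, n_cells = 1500, seed = 44)
  frac <- mean(cells$rearranged)
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)  # ~10% at 14 kb mean
  small <- expansion_model(n_ttta5 = 500L, n_tttca = 250L, n_ttta3 = 50L)
  cells2 <- simulate_allele_population(small, n_cells = 1500, seed = 45)
  expect_lt(mean(cells2$rearranged), 0.03)  # < 3% at 4 kb mean
})

test_that("error-free reads decompose to exact truth; strands are neutral", {
  model <- expansion_model(somatic_cv = 0.2, config_mix = c(C2 = 1))
  cells <- simulate_allele_population(model, n_cells = 5, seed = 21)
  reads <- emit_long_reads(cells, cfg, error_model = read_error_model(0, 0, 0),
                           n_reads = 6, p_truncate = 0,
                           p_fusion_if_rearranged = 0, seed = 22)
  dec <- decompose_reads(setNames(reads$sequence, reads$read_id), cfg)
  tab <- decomposition_table(dec)
  expect_equal(tab$n_units_total, reads$truth_units)
  expect_equal(tab$n_units_TTTCA, reads$truth_n_tttca)
  # strand flip changes nothing
  flipped <- vapply(reads$sequence, famex:::revcomp, character(1))
  dec2 <- decompose_reads(setNames(flipped, reads$read_id), cfg)
  expect_equal(decomposition_table(dec2)$n_units_total, reads$truth_units)
})

test_that("read error model respects its bounds and rates", {
  expect_error(read_error_model(substitution = 0.5), "0.2")
  set.seed(3)
  s <- strrep("TTTTATTTCA", 2000)
  noisy <- apply_read_errors(s, read_error_model(0.03, 0.03, 0.04))
  # expected length change = (ins - del) = -1%
  expect_equal(nchar(noisy) / nchar(s), 0.99, tolerance = 0.01)
  clean <- apply_read_errors(s, read_error_model(0, 0, 0))
  expect_identical(clean, s)
})

test_that("short-read emitter covers the locus and honors coverage 0", {
  cells <- make_cell(16, 0, 0, config = "C5")
  sr0 <- emit_short_reads(cells, cfg, coverage = 0, seed = 1)
  expect_equal(nrow(sr0$r1), 0L)
  sr <- emit_short_reads(cells, cfg, coverage = 20, seed = 2)
  expect_equal(nrow(sr$r1), nrow(sr$r2))
  expect_true(all(nchar(sr$r1$sequence) == 150L))
  # paired files written
  pre <- tempfile()
  emit_short_reads(cells, cfg, coverage = 5, seed = 3, out_prefix = pre)
  expect_true(file.exists(paste0(pre, "_R1.fastq")))
  expect_true(file.exists(paste0(pre, "_R2.fastq")))
})

test_that("noise-free combing emission recovers sizes exactly", {
  model <- expansion_model(n_ttta5 = 400L, n_tttca = 1200L, n_ttta3 = 200L,
                           somatic_cv = 0.2, config_mix = c(C2 = 1),
                           rearrange_pmax = 0, normal_units = 0L)
  cells <- simulate_allele_population(model, n_cells = 40, seed = 61)
  comb <- emit_combing_table(cells, noise_sd_kb = 0, p_truncate = 0,
                             min_detectable_kb = 0, seed = 62)
  calls <- call_alleles(comb)
  truth <- attr(comb, "truth")
  m <- merge(calls, truth, by = "fiber_id")
  p <- m[m$class %in% c("P_definite", "P_likely"), ]
  expect_equal(nrow(p), 40L)
  expect_equal(p$expansion_kb, p$truth_size_kb, tolerance = 1e-9)
})

test_that("rearranged cells emit grammar-violating fibers", {
  model <- expansion_model(n_ttta5 = 480L, n_tttca = 2080L, n_ttta3 = 240L)
  cells <- simulate_allele_population(model, n_cells = 150, seed = 71)
  comb <- emit_combing_table(cells, seed = 72)
  calls <- call_alleles(comb)
  truth <- attr(comb, "truth")
  m <- merge(calls, truth, by = "fiber_id")
  complete <- m[m$class != "incomplete", ]
  # detection matches emission exactly for complete fibers
  expect_equal(complete$class == "rearranged", complete$rearranged)
})

test_that("simulated cohorts show the built-in inverse TTTCA correlation", {
  coh <- emit_cohort(default_cohort_models(8),
                     phenotype = phenotype_model(sigma = 0),
                     n_cells = 40, seed = 91)
  r <- pearson_with_ci(coh$age_seizure_onset, coh$combing_blood_tttca_kb)
  expect_lt(r$r, -0.9)  # noiseless onset tracks TTTCA size tightly
  truth <- attr(coh, "truth")
  expect_equal(coh$combing_blood_expansion_kb, truth$truth_mean_size_kb,
               tolerance = 0.15)
})
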