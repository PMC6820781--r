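test_that("allele classification follows the printed thresholds exactly", {
  mk <- function(tokens, lengths) combing_allele(tokens, lengths)
  expect_equal(classify_allele(mk(c("B", "Y", "G"), c(2, 3.0, 2))), "N")
  expect_equal(classify_allele(mk(c("B", "Y", "G"), c(2, 5.5, 2))), "U")
  expect_equal(classify_allele(mk(c("B", "Y", "G"), c(2, 8.4999, 2))), "U")
  expect_equal(classify_allele(mk(c("B", "Y", "G"), c(2, 8.5, 2))),
               "P_likely")
  expect_equal(classify_allele(mk(c("B", "Y", "R", "G"), c(2, 1.0, 2.0, 2))),
               "P_definite")
  expect_error(classify_allele(mk(c("B", "G"), c(2, 2))), "measurement")
})

test_that("classification partitions complete non-rearranged alleles", {
  set.seed(12)
  for (y in runif(30, 0, 15)) {
    cls <- classify_allele(combing_allele(c("B", "Y", "G"), c(2, y, 2)))
    expect_true(cls %in% c("N", "U", "P_likely"))
    # monotone in Y for red-negative alleles
    cls2 <- classify_allele(combing_allele(c("B", "Y", "G"), c(2, y + 1, 2)))
    ord <- c(N = 1, U = 2, P_likely = 3)
    expect_gte(ord[[cls2]], ord[[cls]])
  }
})

test_that("expansion_size implements Yp - Yn + R + W and is affine", {
  expect_equal(expansion_size(10, 2, 3, 1), 12)
  expect_equal(expansion_size(2, 2, 0, 0), 0)
  expect_equal(expansion_size(2, 2, 10.4, 1.3), 11.7)
  d <- expansion_size(5 + 0.25, 2, 3, 1) - expansion_size(5, 2, 3, 1)
  expect_equal(d, 0.25)
  expect_error(expansion_size(-1, 2, 3, 1))
})

test_that("micro-rearrangement grammar rules fire in order", {
  expect_false(flag_rearrangement(c("B", "Y", "R", "G"))$rearranged)
  expect_false(flag_rearrangement(c("B", "Y", "G"))$rearranged)
  ov <- flag_rearrangement(c("B", "M", "G"))
  expect_true(ov$rearranged); expect_equal(ov$reason, "overlay")
  dup <- flag_rearrangement(c("B", "Y", "R", "R", "B", "G"))
  expect_true(dup$rearranged); expect_equal(dup$reason, "duplicated_flank")
  mis <- flag_rearrangement(c("B", "Y", "R"))
  expect_true(mis$rearranged); expect_equal(mis$reason, "missing_flank")
  inv <- flag_rearrangement(c("G", "W", "R", "Y", "B"))
  expect_true(inv$rearranged)
  expect_equal(inv$reason, "inverted_flank_order")
  # a lone flank without red is not rearranged (could be a plain fiber end)
  expect_false(flag_rearrangement(c("B", "Y"))$rearranged)
})

test_that("configuration taxonomy maps token patterns deterministically", {
  expect_equal(assign_configuration(c("B", "Y", "R", "G")), "C1")
  expect_equal(assign_configuration(c("B", "Y", "R", "W", "G")), "C2")
  expect_equal(assign_configuration(c("B", "Y", "R", "W", "R", "G")), "C3")
  expect_equal(assign_configuration(c("B", "Y", "R", "W", "R", "W", "G")),
               "C4")
  expect_equal(assign_configuration(c("B", "Y", "G"), y_kb = 9.0), "C5")
  expect_true(is.na(assign_configuration(c("B", "Y", "G"), y_kb = 3.0)))
  expect_equal(
    assign_configuration(c("B", "Y", "R", "W", "R", "W", "R", "G")), "C6")
  expect_error(assign_configuration(c("B", "M", "G")), "rearranged")
  expect_error(assign_configuration(c("B", "Y", "END_TRUNCATED")),
               "incomplete")
})

test_that("call_alleles + cohort_summary match a brute-force recomputation", {
  meas <- rbind(
    comb_normals("P1", c(2.4, 2.5, 2.6, 2.5, 2.7)),
    comb_row("P1", "p001", c("B", "Y", "R", "G"), c(2, 3.0, 4.0, 2)),
    comb_row("P1", "p002", c("B", "Y", "R", "W", "G"),
             c(2, 4.0, 6.0, 1.0, 2)),
    comb_row("P1", "p003", c("B", "Y", "G"), c(2, 9.0, 2)),
    comb_row("P1", "r001", c("B", "M", "G"), c(2, 5, 2)),
    comb_row("P1", "t001", c("B", "Y", "END_TRUNCATED"), c(2, 1.0, 0),
             complete = 0L))
  calls <- call_alleles(meas)
  expect_equal(sum(calls$class == "N"), 5L)
  expect_equal(sum(calls$class == "rearranged"), 1L)
  expect_equal(sum(calls$class == "incomplete"), 1L)
  # baseline: median of the five N-allele Y values
  expect_equal(unique(calls$Yn_kb), 2.5)
  p <- calls[calls$class %in% c("P_definite", "P_likely"), ]
  # brute-force sizes: Yp - Yn + R + W
  expect_equal(sort(p$expansion_kb),
               sort(c(3.0 - 2.5 + 4.0, 4.0 - 2.5 + 6.0 + 1.0, 9.0 - 2.5)))
  expect_equal(p$configuration[p$fiber_id == "p001"], "C1")
  expect_equal(p$configuration[p$fiber_id == "p002"], "C2")
  expect_equal(p$configuration[p$fiber_id == "p003"], "C5")
  summ <- cohort_summary(calls)
  expect_equal(summ$n_P, 3L)
  expect_equal(summ$mean_expansion_kb, mean(p$expansion_kb))
  expect_equal(summ$mean_tttca_kb, mean(p$R_total_kb))
  expect_equal(summ$mean_ttta3_kb, mean(p$W_total_kb))
  # parts sum to the total for every pathogenic allele
  expect_equal(p$ttta5_kb + p$tttca_kb + p$ttta3_kb, p$expansion_kb)
})

test_that("10 percent rearranged alleles convert to 20 percent of cells", {
  meas <- rbind(
    comb_normals("P2", rep(2.5, 17)),
    comb_row("P2", "p1", c("B", "Y", "R", "G"), c(2, 3, 4, 2)),
    comb_row("P2", "r1", c("B", "M", "G"), c(2, 5, 2)),
    comb_row("P2", "r2", c("B", "Y", "R"), c(2, 5, 3)))
  summ <- cohort_summary(call_alleles(meas))
  expect_equal(summ$percent_rearranged_alleles, 10)
  expect_equal(summ$percent_rearranged_cells, 20)
  # the cell percentage caps at 100
  meas2 <- rbind(comb_normals("P3", rep(2.5, 2)),
                 comb_row("P3", "r1", c("B", "M", "G"), c(2, 5, 2)),
                 comb_row("P3", "r2", c("B", "M", "G"), c(2, 5, 2)))
  expect_equal(cohort_summary(call_alleles(meas2))$percent_rearranged_cells,
               100)
})

test_that("rearranged alleles never move the N-allele baseline", {
  base <- comb_normals("P4", c(2.2, 2.5, 2.9, 2.4))
  extra <- rbind(comb_row("P4", "r1", c("B", "M", "G"), c(2, 12, 2)),
                 comb_row("P4", "r2", c("G", "W", "R", "Y", "B"),
                          c(2, 1, 8, 3, 2)))
  yn1 <- unique(call_alleles(base)$Yn_kb)
  yn2 <- unique(call_alleles(rbind(base, extra))$Yn_kb)
  expect_equal(yn1, yn2)
})

test_that("negative sizes are flagged but not clamped", {
  meas <- rbind(comb_normals("P5", c(3.0, 3.2, 3.4)),
                comb_row("P5", "p1", c("B", "Y", "R", "G"),
                         c(2, 2.8, 0.1, 2)))
  calls <- call_alleles(meas)
  p <- calls[calls$class == "P_definite", ]
  expect_lt(p$expansion_kb, 0)
  expect_true(p$negative_flag)
})

test_that("an individual without N alleles fails with a baseline error", {
  meas <- comb_row("P6", "p1", c("B", "Y", "R", "G"), c(2, 3, 4, 2))
  expect_error(cohort_summary(call_alleles(meas)), "baseline unavailable")
})

test_that("combing tables round-trip through TSV", {
  meas <- rbind(comb_normals("P7", c(2.5, 2.6)),
                comb_row("P7", "p1", c("B", "Y", "R", "G"), c(2, 3, 4, 2)))
  path <- tempfile(fileext = ".tsv")
  famex_write_tsv(meas, path)
  back <- read_combing_table(path)
  expect_equal(back$tokens, meas$tokens)
  expect_equal(call_alleles(back)$class, call_alleles(meas)$class)
  expect_error(read_combing_table(famex_write_tsv(data.frame(x = 1),
                                                  tempfile())),
               "missing columns")
})
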