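test_that("pearson_with_ci agrees with a brute-force oracle", {
  x <- 1:5; y <- 2 * (1:5)
  res <- pearson_with_ci(x, y)
  expect_equal(res$r, 1)
  expect_equal(res$r2, 1)
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- pearson_with_ci(x, y)
    expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(res$r2, res$r^2)
    expect_lte(res$ci_low, res$r)
    expect_gte(res$ci_high, res$r)
  }
})

test_that("Fisher interval shrinks with n at fixed r", {
  x <- c(1, 2, 3, 4, 6); y <- c(1.2, 1.9, 3.4, 3.9, 6.3)
  narrow <- pearson_with_ci(rep(x, 4), rep(y, 4))  # same r, larger n
  wide <- pearson_with_ci(x, y)
  expect_equal(narrow$r, wide$r, tolerance = 1e-12)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(pearson_with_ci(1:2, 2:3), "3 complete pairs")
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_ci(c(1, 2, NA, NA, NA), c(1, 2, 3, 4, 5)),
               "3 complete pairs")
})

test_that("the packaged cohort fixture loads with the censored value", {
  coh <- fame3_cohort()
  expect_equal(nrow(coh), 10L)
  cens <- attr(coh, "censored")
  expect_equal(cens$individual_id, "2-IV-9")
  expect_equal(cens$column, "nanopore_blood_tttca_kb")
  expect_equal(cens$bound, 5)
  expect_true(is.na(coh$nanopore_blood_tttca_kb[coh$individual_id ==
                                                  "2-IV-9"]))
  # part means never exceed the total mean (0.05 kb rounding tolerance)
  for (assay in c("nanopore_blood", "combing_blood", "combing_fibroblast")) {
    tot <- coh[[paste0(assay, "_expansion_kb")]]
    for (part in c("ttta5", "tttca", "ttta3")) {
      p <- coh[[paste0(assay, "_", part, "_kb")]]
      ok <- !is.na(tot) & !is.na(p)
      expect_true(all(p[ok] <= tot[ok] + 0.05))
    }
  }
})

test_that("onset report reproduces the expected correlation structure", {
  rep <- onset_correlation_report(fame3_cohort())
  r_seiz_tc <- rep$r[rep$phenotype == "seizure" & rep$part == "tttca"]
  r_trem_tc <- rep$r[rep$phenotype == "tremor" & rep$part == "tttca"]
  expect_lt(r_seiz_tc, 0)
  expect_lt(abs(r_trem_tc), abs(r_seiz_tc))
  expect_equal(rep$n[rep$phenotype == "seizure" & rep$part == "tttca"], 7L)
  expect_equal(rep$n[rep$phenotype == "tremor" & rep$part == "tttca"], 7L)
  # constant covariate -> flagged NA cell
  coh <- fame3_cohort()
  coh$combing_blood_tttca_kb <- 5
  rep2 <- onset_correlation_report(coh)
  bad <- rep2[rep2$part == "tttca" & rep2$phenotype == "seizure", ]
  expect_true(is.na(bad$r))
  expect_match(bad$note, "zero variance")
})

test_that("delta-delta-Ct abundances and rank-sum comparison behave", {
  dct_controls <- c(5, 5.3, 5.1)
  ref <- c(20, 20.4, 20.1, 20.2, 20.0)
  ct <- data.frame(
    sample_id = c("c1", "c2", "c3", "p1", "p2"),
    ct_target = ref + c(dct_controls, mean(dct_controls),
                        mean(dct_controls) - 1),
    ct_reference = ref)
  res <- relative_expression_ddct(ct, c("c1", "c2", "c3"))
  s <- res$samples
  # sample p1 sits exactly at the control mean dCt -> abundance 1
  expect_equal(s$abundance[s$sample_id == "p1"], 1)
  # ddCt of -1 doubles the abundance
  expect_equal(s$abundance[s$sample_id == "p2"], 2)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # plate shift: adding a constant to both Cts of some samples is neutral
  ct2 <- ct
  ct2$ct_target[4:5] <- ct2$ct_target[4:5] + 3
  ct2$ct_reference[4:5] <- ct2$ct_reference[4:5] + 3
  res2 <- relative_expression_ddct(ct2, c("c1", "c2", "c3"))
  expect_equal(res2$samples$abundance, s$abundance)
  # missing reference Ct drops the sample with a warning
  ct3 <- ct; ct3$ct_reference[4] <- NA
  expect_warning(res3 <- relative_expression_ddct(ct3, c("c1", "c2", "c3")),
                 "dropping")
  expect_equal(res3$n_carrier, 1L)
})

test_that("rank-sum p-values are well calibrated under the null", {
  # two groups from one Ct distribution: p > 0.05 in >= 90% of seeds
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    ct <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     ct_target = rnorm(20, 25, 0.5),
                     ct_reference = rnorm(20, 20, 0.3))
    res <- relative_expression_ddct(ct, sprintf("s%02d", 1:10))
    if (res$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
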