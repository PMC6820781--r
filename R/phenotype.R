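#' Pearson correlation with Fisher-z confidence interval
#'
#' Standard Pearson r on complete pairs, with the 95 percent (by default)
#' interval from the Fisher z transform,
#' tanh(atanh(r) +/- z_(1-alpha/2) / sqrt(n - 3)).
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped. At
#'   least 3 complete pairs are required and both variables must vary.
#' @param conf Confidence level (default 0.95).
#' @return Object of class \code{correlation_result}: \code{r}, \code{r2},
#'   \code{ci_low}, \code{ci_high}, \code{n}.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  half <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  structure(list(r = r, r2 = r^2,
                 ci_low = tanh(z - half), ci_high = tanh(z + half),
                 n = n, conf = conf),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (R2 = %.3f), %.0f%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$r2, 100 * x$conf, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Load a cohort table
#'
#' Reads a cohort TSV in the per-individual schema (ages at onset plus
#' per-assay mean expansion-part sizes). Censored entries written as
#' \code{">x"} are parsed as NA with the bound recorded in the
#' \code{"censored"} attribute (a data.frame with \code{individual_id},
#' \code{column}, \code{bound}); they are thereby excluded from means and
#' correlations.
#'
#' @param path Path to the TSV.
#' @return data.frame with numeric assay/age columns and a
#'   \code{"censored"} attribute.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  id_cols <- c("individual_id", "family_id", "sex")
  cens <- data.frame(individual_id = character(), column = character(),
                     bound = numeric())
  for (col in setdiff(names(df), id_cols)) {
    v <- df[[col]]
    gt <- grepl("^>", v)
    if (any(gt, na.rm = TRUE)) {
      cens <- rbind(cens, data.frame(
        individual_id = df$individual_id[which(gt)],
        column = col, bound = as.numeric(sub("^>", "", v[which(gt)]))))
      v[gt] <- NA
    }
    df[[col]] <- suppressWarnings(as.numeric(v))
  }
  attr(df, "censored") <- cens
  df
}

#' Packaged per-individual cohort fixture
#'
#' Transcription of the published per-individual summary table for the ten
#' affected carriers: ages at last examination and at tremor/seizure onset,
#' and mean expansion-part sizes (kb) per assay (nanopore blood, combing
#' blood, combing fibroblasts) with pathogenic-allele counts. The one
#' censored value (a nanopore TTTCA mean reported only as ">5") is exposed
#' via the \code{"censored"} attribute.
#'
#' @return data.frame, see \code{\link{read_cohort_table}}.
#' @export
fame3_cohort <- function() {
  read_cohort_table(system.file("extdata", "cohort_fixture.tsv",
                                package = "famex", mustWork = TRUE))
}

#' Genotype-phenotype correlation report
#'
#' One Pearson correlation (with Fisher-z interval) per combination of
#' onset phenotype (seizure, tremor) and expansion part (total, 5'-TTTTA,
#' TTTCA, combined 5'+3'-TTTTA) for a chosen assay. Pairs with a missing
#' onset age or missing size are dropped per cell (pairwise-complete
#' deletion); cells with fewer than 3 pairs or zero variance are flagged
#' NA.
#'
#' @param cohort data.frame from \code{\link{read_cohort_table}}.
#' @param assay Column prefix, e.g. \code{"combing_blood"} (default).
#' @return data.frame: phenotype, part, n, r, r2, ci_low, ci_high, note.
#' @export
onset_correlation_report <- function(cohort, assay = "combing_blood") {
  parts <- list(
    total = cohort[[paste0(assay, "_expansion_kb")]],
    ttta5 = cohort[[paste0(assay, "_ttta5_kb")]],
    tttca = cohort[[paste0(assay, "_tttca_kb")]],
    ttta5_plus_3 = cohort[[paste0(assay, "_ttta5_kb")]] +
      cohort[[paste0(assay, "_ttta3_kb")]])
  phenos <- c(seizure = "age_seizure_onset", tremor = "age_tremor_onset")
  rows <- list()
  for (ph in names(phenos)) {
    for (pt in names(parts)) {
      x <- cohort[[phenos[[ph]]]]
      y <- parts[[pt]]
      res <- tryCatch(pearson_with_ci(x, y), error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(phenotype = ph, part = pt,
                   n = sum(stats::complete.cases(x, y)),
                   r = NA_real_, r2 = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   note = conditionMessage(res))
      } else {
        data.frame(phenotype = ph, part = pt, n = res$n,
                   r = res$r, r2 = res$r2,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   note = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, delta-Ct = Ct_target - Ct_reference; delta-delta-Ct =
#' delta-Ct - mean(delta-Ct of controls); relative abundance =
#' 2^(-delta-delta-Ct) (the conventional exponent form; control samples
#' thus average to abundance 1). Carrier and control abundances are
#' compared with an exact two-sided Wilcoxon-Mann-Whitney rank-sum test.
#'
#' @param ct data.frame with columns \code{sample_id}, \code{ct_target},
#'   \code{ct_reference} (triplicates averaged upstream).
#' @param control_ids Sample ids forming the control group (>= 2); all
#'   other samples are treated as carriers.
#' @return List with \code{samples} (per-sample data.frame adding
#'   \code{dct}, \code{ddct}, \code{abundance}, \code{group}),
#'   \code{p_value}, \code{n_carrier}, \code{n_control}.
#' @export
relative_expression_ddct <- function(ct, control_ids) {
  stopifnot(all(c("sample_id", "ct_target", "ct_reference") %in% names(ct)))
  if (length(control_ids) < 2L) stop("need at least 2 controls",
                                     call. = FALSE)
  drop <- is.na(ct$ct_reference) | is.na(ct$ct_target)
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) with missing Ct: ",
            paste(ct$sample_id[drop], collapse = ", "), call. = FALSE)
    ct <- ct[!drop, , drop = FALSE]
  }
  ct$group <- ifelse(ct$sample_id %in% control_ids, "control", "carrier")
  if (sum(ct$group == "control") < 2L) {
    stop("fewer than 2 controls after dropping missing Cts", call. = FALSE)
  }
  ct$dct <- ct$ct_target - ct$ct_reference
  ct$ddct <- ct$dct - mean(ct$dct[ct$group == "control"])
  ct$abundance <- 2^(-ct$ddct)
  test <- wilcox.test(ct$abundance[ct$group == "carrier"],
                      ct$abundance[ct$group == "control"],
                      alternative = "two.sided", exact = TRUE)
  list(samples = ct, p_value = test$p.value,
       n_carrier = sum(ct$group == "carrier"),
       n_control = sum(ct$group == "control"))
}
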