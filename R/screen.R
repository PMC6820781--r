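#' Classify one short read against the repeat locus
#'
#' Transparent short-read evidence classifier modeled on the
#' anchored/in-repeat read dichotomy of expansion genotypers:
#' \describe{
#'   \item{spanning}{both flank anchors found (junction k-mers of the left
#'     flank 3' end and right flank 5' end), repeat enclosed; exact unit
#'     counts per motif are measured between the anchors.}
#'   \item{anchored_in_repeat}{exactly one anchor, with at least
#'     \code{min_inner_units} exact tandem motif copies at the inner end.}
#'   \item{fully_in_repeat}{at least 90 percent of the read tiled by exact
#'     copies of one motif (any rotation, either strand); reported under
#'     the motif's canonical form.}
#'   \item{irrelevant}{anything else.}
#' }
#' Both strands are tried; counting is rotation/strand-normalized via
#' \code{\link{canonical_motif}}.
#'
#' @param read Character scalar; length must be >= 2 * \code{min_anchor}.
#' @param config A \code{\link{locus_config}}.
#' @param min_anchor Anchor k-mer length (default 20).
#' @param min_inner_units Tandem copies required at the inner end for
#'   anchored_in_repeat (default 4).
#' @return List with \code{category}, \code{units} (named per motif; only
#'   for spanning reads), \code{inrepeat_motif} (canonical motif for
#'   in-repeat categories) and \code{orientation}.
#' @export
classify_read <- function(read, config, min_anchor = 20L,
                          min_inner_units = 4L) {
  read <- toupper(read)
  if (nchar(read) < 2L * min_anchor) {
    stop("read shorter than 2 * min_anchor", call. = FALSE)
  }
  lf <- config$left_flank
  left_key <- substr(lf, nchar(lf) - min_anchor + 1L, nchar(lf))
  right_key <- substr(config$right_flank, 1L, min_anchor)

  for (orient in c("plus", "minus")) {
    s <- if (orient == "plus") read else revcomp(read)
    lp <- regexpr(left_key, s, fixed = TRUE)[1L]
    rp <- regexpr(right_key, s, fixed = TRUE)[1L]
    if (lp > 0L && rp > 0L && rp >= lp + min_anchor) {
      inner <- substr(s, lp + min_anchor, rp - 1L)
      # the inter-anchor region is known repeat tract: single copies count
      st <- decompose(inner, motifs = config$motifs, min_units = 1L)
      units <- vapply(config$motifs, function(m) {
        sum(st$segments$unit_count[st$segments$motif == m])
      }, numeric(1))
      return(list(category = "spanning", units = units,
                  inrepeat_motif = NA_character_, orientation = orient))
    }
    if (xor(lp > 0L, rp > 0L)) {
      # In-repeat evidence must show the repeat continuing past the read:
      # the anchor sits at the read's outer edge and the inner remainder is
      # essentially all repeat, running to the inner edge. Otherwise a
      # spanned normal microsatellite whose far anchor lies just beyond
      # the read end would mimic an expansion.
      n <- nchar(s)
      outer_ok <- if (lp > 0L) lp <= 11L else rp + min_anchor - 1L >= n - 10L
      inner <- if (lp > 0L) substr(s, lp + min_anchor, n) else
        substr(s, 1L, rp - 1L)
      if (outer_ok && nchar(inner) >= 5L * min_inner_units) {
        for (m in config$motifs) {
          runs <- find_tandem_runs(inner, m, min_units = min_inner_units)
          if (nrow(runs) == 0L) next
          edge_ok <- if (lp > 0L) {
            any(runs$start + runs$span - 1L >= nchar(inner) - 4L)
          } else {
            any(runs$start <= 5L)
          }
          if (edge_ok && max(runs$span) >= 0.9 * nchar(inner)) {
            return(list(category = "anchored_in_repeat", units = NULL,
                        inrepeat_motif = canonical_motif(m),
                        orientation = orient))
          }
        }
      }
    }
  }
  # no anchors: pure-repeat content check, rotation/strand-normalized
  n <- nchar(read)
  for (m in config$motifs) {
    cov <- max(vapply(motif_variants(m), function(v) {
      runs <- find_tandem_runs(read, v, min_units = 2L)
      sum(runs$span) / n
    }, numeric(1)))
    if (cov >= 0.9) {
      return(list(category = "fully_in_repeat", units = NULL,
                  inrepeat_motif = canonical_motif(m),
                  orientation = NA_character_))
    }
  }
  list(category = "irrelevant", units = NULL,
       inrepeat_motif = NA_character_, orientation = NA_character_)
}

#' Genotype the locus from short reads of one individual
#'
#' Classifies every read (\code{\link{classify_read}}), clusters spanning
#' unit counts into at most two alleles (1-D clustering, 1-unit tolerance),
#' and calls expansions per motif. If anchored-in-repeat or
#' fully-in-repeat reads exist for a motif, one allele is reported as a
#' lower bound at the maximum observable unit count
#' \code{floor((read_length - 2 * min_anchor) / 5)}. The expansion call for
#' the locus's primary motif requires an allele above
#' \code{normal_max_units} (default 30) or a lower-bound allele; for the
#' other motifs any presence calls the expansion (the motif is never seen
#' at the locus in controls).
#'
#' @param reads Character vector of read sequences (both mates pooled).
#' @param config A \code{\link{locus_config}}.
#' @param min_anchor Anchor k-mer length (default 20).
#' @param normal_max_units Normal maximum for the primary motif
#'   (default 30).
#' @return Object of class \code{screen_result}: list with
#'   \code{locus_id}, counts per category, \code{allele_estimates}
#'   (data.frame: allele, one unit column per motif, \code{lower_bound},
#'   \code{n_reads}), \code{expansion_call} (named logical per motif),
#'   \code{max_observable_units} and \code{no_coverage}.
#' @export
genotype_locus <- function(reads, config, min_anchor = 20L,
                           normal_max_units = 30L) {
  motifs <- config$motifs
  cls <- lapply(reads, function(r) {
    tryCatch(classify_read(r, config, min_anchor = min_anchor),
             error = function(e) list(category = "irrelevant", units = NULL,
                                      inrepeat_motif = NA_character_))
  })
  cat_of <- vapply(cls, `[[`, character(1), "category")
  spanning <- cls[cat_of == "spanning"]
  inrep <- cls[cat_of %in% c("anchored_in_repeat", "fully_in_repeat")]
  read_len <- if (length(reads)) max(nchar(reads)) else 0L
  max_obs <- max(0L, (read_len - 2L * min_anchor) %/% 5L)

  inrep_motifs <- vapply(inrep, `[[`, character(1), "inrepeat_motif")
  canon <- vapply(motifs, canonical_motif, character(1))
  inrep_evidence <- setNames(canon %in% inrep_motifs, motifs)

  res <- list(locus_id = config$locus_id,
              n_spanning_reads = sum(cat_of == "spanning"),
              n_anchored_inrepeat_reads = sum(cat_of == "anchored_in_repeat"),
              n_fully_inrepeat_reads = sum(cat_of == "fully_in_repeat"),
              max_observable_units = max_obs)

  if (length(spanning) == 0L && length(inrep) == 0L) {
    res$no_coverage <- TRUE
    res$allele_estimates <- NULL
    res$expansion_call <- setNames(rep(NA, length(motifs)), motifs)
    class(res) <- "screen_result"
    return(res)
  }
  res$no_coverage <- FALSE

  alleles <- NULL
  if (length(spanning) > 0L) {
    um <- do.call(rbind, lapply(spanning, `[[`, "units"))
    totals <- rowSums(um)
    ord <- order(totals)
    brk <- cumsum(c(1L, as.integer(diff(totals[ord]) > 1)))
    clusters <- split(ord, brk)
    clusters <- clusters[order(-lengths(clusters))]
    clusters <- clusters[seq_len(min(2L, length(clusters)))]
    alleles <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      idx <- clusters[[i]]
      row <- data.frame(allele = i)
      for (m in motifs) {
        row[[paste0("units_", m)]] <- round(median(um[idx, m]))
      }
      row$lower_bound <- FALSE
      row$n_reads <- length(idx)
      row
    }))
    alleles <- alleles[order(rowSums(
      alleles[, paste0("units_", motifs), drop = FALSE])), , drop = FALSE]
    alleles$allele <- seq_len(nrow(alleles))
  }
  if (any(inrep_evidence)) {
    lb <- data.frame(allele = if (is.null(alleles)) 1L else
      max(alleles$allele) + 1L)
    for (m in motifs) {
      lb[[paste0("units_", m)]] <-
        if (inrep_evidence[[m]]) max_obs else 0L
    }
    lb$lower_bound <- TRUE
    lb$n_reads <- length(inrep)
    if (!is.null(alleles) && nrow(alleles) >= 2L) {
      # the lower-bound allele replaces the larger spanning cluster
      alleles <- alleles[-nrow(alleles), , drop = FALSE]
    }
    alleles <- rbind(alleles, lb)
    alleles$allele <- seq_len(nrow(alleles))
  }
  rownames(alleles) <- NULL
  res$allele_estimates <- alleles

  call <- setNames(logical(length(motifs)), motifs)
  for (m in motifs) {
    u <- alleles[[paste0("units_", m)]]
    threshold <- if (m == motifs[1L]) normal_max_units else 0L
    call[m] <- inrep_evidence[[m]] ||
      any(alleles$lower_bound & u > 0L) || any(u > threshold)
  }
  res$expansion_call <- call
  class(res) <- "screen_result"
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> locus", x$locus_id, "\n")
  cat("  reads: spanning", x$n_spanning_reads,
      "| anchored-in-repeat", x$n_anchored_inrepeat_reads,
      "| fully-in-repeat", x$n_fully_inrepeat_reads, "\n")
  if (isTRUE(x$no_coverage)) {
    cat("  no coverage at locus\n")
  } else {
    print(x$allele_estimates)
    cat("  expansion call:",
        paste(names(x$expansion_call), x$expansion_call,
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' One-line TSV row for a screen result
#' @param x A \code{screen_result}.
#' @param individual_id Identifier for the row.
#' @return data.frame with one row.
#' @export
screen_table <- function(x, individual_id = "individual") {
  row <- data.frame(individual_id = individual_id,
                    locus_id = x$locus_id,
                    n_spanning = x$n_spanning_reads,
                    n_anchored_inrepeat = x$n_anchored_inrepeat_reads,
                    n_fully_inrepeat = x$n_fully_inrepeat_reads,
                    no_coverage = isTRUE(x$no_coverage))
  al <- x$allele_estimates
  motifs <- names(x$expansion_call)
  for (i in 1:2) {
    for (m in motifs) {
      row[[sprintf("allele%d_units_%s", i, m)]] <-
        if (!is.null(al) && nrow(al) >= i) al[[paste0("units_", m)]][i] else NA
    }
    row[[sprintf("allele%d_lower_bound", i)]] <-
      if (!is.null(al) && nrow(al) >= i) al$lower_bound[i] else NA
  }
  for (m in motifs) {
    row[[paste0("call_", m)]] <- x$expansion_call[[m]]
  }
  row
}
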