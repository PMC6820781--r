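#' Decompose one long read at the configured locus
#'
#' Anchors the read (\code{\link{locate_expansion}}), slices out the
#' expansion interval and decomposes it into exact motif runs
#' (\code{\link{decompose}}). TTTTA segments upstream of the first TTTCA
#' segment are assigned to the 5' part, downstream to the 3' part; reads
#' without TTTCA assign all TTTTA to the 5' part.
#'
#' Two unit-count views are reported. \code{units_exact} counts exact motif
#' copies only (the decomposition contract). \code{units_est} is a
#' span-based estimate (class span / 5, total interval span / 5) that stays
#' unbiased under base-calling error, where exact-copy counting
#' systematically undercounts; it is the per-read total-repeat estimator
#' used for robustness checks.
#'
#' Per-motif kb sizes exclude gap bases (exact copies only); the total
#' expansion kb is the physical span including gaps.
#'
#' @param read Character scalar DNA sequence.
#' @param config A \code{\link{locus_config}}.
#' @param read_id Identifier carried through to outputs.
#' @param min_units,max_merge_gap Passed to \code{\link{decompose}}.
#' @param min_identity,min_anchor_len Passed to
#'   \code{\link{locate_expansion}}.
#' @return An object of class \code{decomposed_read}: a list with
#'   \code{read_id}, \code{orientation}, \code{coverage},
#'   \code{anchor_left}/\code{anchor_right}, \code{structure}
#'   (a \code{repeat_structure} whose segments carry a \code{class}
#'   column), \code{units_exact}, \code{units_est}, \code{size_kb}
#'   (named: one entry per class plus \code{total}) and \code{n_gaps}.
#' @export
decompose_read <- function(read, config, read_id = "read",
                           min_units = 2L, max_merge_gap = 10L,
                           min_identity = 0.8, min_anchor_len = 60L) {
  loc <- locate_expansion(read, config, min_identity = min_identity,
                          min_anchor_len = min_anchor_len)
  exp_seq <- if (loc$interval[2L] > loc$interval[1L]) {
    substr(loc$read_oriented, loc$interval[1L] + 1L, loc$interval[2L])
  } else ""
  st <- decompose(exp_seq, motifs = config$motifs,
                  min_units = min_units, max_merge_gap = max_merge_gap)
  st$segments$class <- segment_classes(st$segments, config$motifs)
  classes <- class_labels(config$motifs)
  exact <- setNames(integer(length(classes)), classes)
  est <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    sel <- st$segments$class == cl
    exact[cl] <- sum(st$segments$unit_count[sel])
    est[cl] <- sum(st$segments$span_bases[sel]) / 5
  }
  size_kb <- c(exact * 5 / 1000, total = st$total_span_bases / 1000)
  structure(list(
    read_id = read_id, orientation = loc$orientation,
    coverage = loc$coverage,
    anchor_left = loc$anchor_left, anchor_right = loc$anchor_right,
    structure = st,
    units_exact = c(exact, total = sum(exact)),
    units_est = c(est, total = st$total_span_bases / 5),
    size_kb = size_kb,
    n_gaps = nrow(st$gaps)),
    class = "decomposed_read")
}

# class labels: <motif1>_5p, <motif2>, <motif1>_3p
#' @keywords internal
class_labels <- function(motifs) {
  c(paste0(motifs[1L], "_5p"), motifs[2L], paste0(motifs[1L], "_3p"))
}

#' @keywords internal
segment_classes <- function(segments, motifs) {
  primary <- motifs[1L]
  second <- motifs[2L]
  first_tc <- if (any(segments$motif == second)) {
    min(segments$start_offset[segments$motif == second])
  } else Inf
  ifelse(segments$motif == second, second,
         ifelse(segments$start_offset < first_tc,
                paste0(primary, "_5p"), paste0(primary, "_3p")))
}

#' @export
print.decomposed_read <- function(x, ...) {
  cat("<decomposed_read> ", x$read_id, " [", x$orientation, ", ",
      x$coverage, "] ", structure_string(x$structure),
      "  total ", sprintf("%.2f", x$size_kb[["total"]]), " kb\n", sep = "")
  invisible(x)
}

#' Decompose a collection of long reads
#'
#' @param reads Named character vector of sequences, or a path to a
#'   FASTA/FASTQ file (optionally gzipped), read with
#'   \code{\link{read_sequences}}.
#' @param config A \code{\link{locus_config}}.
#' @param ... Passed to \code{\link{decompose_read}}.
#' @param skip_unanchored Reads where no flank anchor is found are dropped
#'   with a warning instead of failing (default TRUE).
#' @return List of \code{decomposed_read} objects.
#' @export
decompose_reads <- function(reads, config, ..., skip_unanchored = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    rec <- read_sequences(reads)
    reads <- setNames(rec$sequence, rec$id)
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%04d", seq_along(reads))
  }
  out <- list()
  for (i in seq_along(reads)) {
    dr <- tryCatch(
      decompose_read(reads[[i]], config, read_id = names(reads)[i], ...),
      error = function(e) {
        if (!skip_unanchored) stop(e)
        warning("read ", names(reads)[i], " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(dr)) out[[dr$read_id]] <- dr
  }
  out
}

#' Tabulate decomposed reads
#'
#' One row per read with the columns of the per-read report: orientation,
#' coverage, exact unit counts per class, gap count, kb sizes and the
#' compact structure string.
#' @param reads List of \code{decomposed_read} objects.
#' @return data.frame.
#' @export
decomposition_table <- function(reads) {
  stopifnot(length(reads) > 0L)
  cls <- names(reads[[1L]]$units_exact)
  cls <- cls[cls != "total"]
  rows <- lapply(reads, function(r) {
    row <- data.frame(read_id = r$read_id, orientation = r$orientation,
                      coverage = r$coverage, stringsAsFactors = FALSE)
    for (cl in cls) row[[paste0("n_units_", cl)]] <- r$units_exact[[cl]]
    row$n_units_total <- r$units_exact[["total"]]
    row$units_est_total <- r$units_est[["total"]]
    row$n_gaps <- r$n_gaps
    for (cl in cls) row[[paste0("size_kb_", cl)]] <- r$size_kb[[cl]]
    row$size_kb_total <- r$size_kb[["total"]]
    row$structure <- structure_string(r$structure)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize decomposed reads for one individual
#'
#' Mean expansion size and per-motif-class sizes over expansion-bearing
#' reads, mirroring a per-individual nanopore summary block (mean expansion
#' size, mean 5'-TTTTA size, mean TTTCA size). Partial-coverage reads are
#' excluded from the means by default.
#'
#' @param reads List of \code{decomposed_read} objects (one individual).
#' @param include_partial Include left/right-partial reads in the means
#'   (default FALSE).
#' @return A list with \code{n_reads} (all expansion-bearing reads),
#'   \code{n_included}, \code{mean_size_kb} (named: per class and total),
#'   \code{units_range} (range of exact total units over included reads)
#'   and \code{undefined} (TRUE when no read qualifies; means are then NA).
#' @export
summarize_reads <- function(reads, include_partial = FALSE) {
  n_all <- length(reads)
  if (!include_partial) {
    reads <- Filter(function(r) r$coverage == "full", reads)
  }
  if (length(reads) == 0L) {
    return(list(n_reads = n_all, n_included = 0L,
                mean_size_kb = NULL, units_range = NULL, undefined = TRUE))
  }
  sizes <- do.call(rbind, lapply(reads, function(r) r$size_kb))
  units <- vapply(reads, function(r) r$units_exact[["total"]], numeric(1))
  list(n_reads = n_all, n_included = length(reads),
       mean_size_kb = colMeans(sizes),
       units_range = range(units), undefined = FALSE)
}
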