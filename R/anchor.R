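#' Locate the repeat expansion in a read via flanking anchors
#'
#' Searches a read and its reverse complement for local alignments of the
#' 3' end of the left flank and the 5' end of the right flank, and returns
#' the orientation maximizing summed anchor identity together with the
#' enclosed expansion interval. Alignment is local with unit scores
#' (+1 match, -1 mismatch, -2 gap), tolerant of long-read error.
#'
#' @param read Character scalar DNA sequence.
#' @param config A \code{\link{locus_config}}.
#' @param min_identity Minimum anchor identity fraction (default 0.8).
#' @param min_anchor_len Minimum anchor alignment length in bases
#'   (default 60).
#' @param anchor_query_len How many terminal flank bases are used as the
#'   anchor query (default 150).
#' @return A list with elements
#'   \item{orientation}{\code{"plus"} or \code{"minus"} (read strand
#'     relative to the locus).}
#'   \item{read_oriented}{the read in locus orientation.}
#'   \item{anchor_left, anchor_right}{\code{NULL} or a list with
#'     \code{start}, \code{end} (1-based, on the oriented read),
#'     \code{identity} and \code{score}.}
#'   \item{interval}{0-based half-open expansion interval on the oriented
#'     read.}
#'   \item{coverage}{\code{"full"}, \code{"left_partial"} or
#'     \code{"right_partial"}.}
#' @export
locate_expansion <- function(read, config, min_identity = 0.8,
                             min_anchor_len = 60L, anchor_query_len = 150L) {
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  if (nchar(read) < min_anchor_len) {
    stop("read shorter than min_anchor_len", call. = FALSE)
  }
  lf <- config$left_flank
  left_q <- substr(lf, max(1L, nchar(lf) - anchor_query_len + 1L), nchar(lf))
  right_q <- substr(config$right_flank, 1L,
                    min(anchor_query_len, nchar(config$right_flank)))

  score_one <- function(query, subject) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = query, subject = subject, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 2)
    len <- Biostrings::nchar(aln)
    ident <- Biostrings::nmatch(aln) / len
    sub <- Biostrings::subject(aln)
    list(start = Biostrings::start(sub), end = Biostrings::end(sub),
         identity = ident, score = Biostrings::score(aln), len = len)
  }
  best <- NULL
  for (orient in c("plus", "minus")) {
    s <- if (orient == "plus") read else revcomp(read)
    la <- score_one(left_q, s)
    ra <- score_one(right_q, s)
    ok_l <- la$len >= min_anchor_len && la$identity >= min_identity
    ok_r <- ra$len >= min_anchor_len && ra$identity >= min_identity
    total <- (if (ok_l) la$score else 0) + (if (ok_r) ra$score else 0)
    if (is.null(best) || total > best$total) {
      best <- list(orientation = orient, seq = s,
                   left = if (ok_l) la else NULL,
                   right = if (ok_r) ra else NULL,
                   total = total)
    }
  }
  if (is.null(best$left) && is.null(best$right)) {
    stop("locus not found: no flank anchor at identity >= ", min_identity,
         call. = FALSE)
  }
  n <- nchar(best$seq)
  if (!is.null(best$left) && !is.null(best$right)) {
    coverage <- "full"
    interval <- c(best$left$end, max(best$left$end, best$right$start - 1L))
  } else if (!is.null(best$left)) {
    coverage <- "left_partial"
    interval <- c(best$left$end, n)
  } else {
    coverage <- "right_partial"
    interval <- c(0L, best$right$start - 1L)
  }
  list(orientation = best$orientation, read_oriented = best$seq,
       anchor_left = best$left, anchor_right = best$right,
       interval = as.integer(interval), coverage = coverage)
}
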