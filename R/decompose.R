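#' Find maximal exact tandem runs of one motif
#'
#' Scans a sequence for maximal runs of at least \code{min_units} exact,
#' back-to-back copies of \code{motif}. Occurrences are located with a
#' zero-width lookahead so self-overlapping motifs are handled, and chained
#' at exact motif-length spacing.
#'
#' @param seq Character scalar DNA sequence.
#' @param motif Character scalar repeat unit.
#' @param min_units Minimum number of tandem copies that starts a run.
#' @return data.frame with columns \code{motif}, \code{start} (1-based),
#'   \code{units}, \code{span} (bases, = units * motif length).
#' @keywords internal
find_tandem_runs <- function(seq, motif, min_units = 2L) {
  k <- nchar(motif)
  n <- nchar(seq)
  empty <- data.frame(motif = character(), start = integer(),
                      units = integer(), span = integer())
  if (n < k * min_units) return(empty)
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  st <- as.integer(hits)
  pos <- logical(n)
  pos[st] <- TRUE
  is_chain_start <- vapply(st, function(s) s - k < 1L || !pos[s - k],
                           logical(1))
  runs <- lapply(st[is_chain_start], function(s) {
    u <- 1L
    while (s + u * k <= n - k + 1L && pos[s + u * k]) u <- u + 1L
    c(start = s, units = u)
  })
  runs <- do.call(rbind, runs)
  runs <- runs[runs[, "units"] >= min_units, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  data.frame(motif = motif, start = runs[, "start"],
             units = runs[, "units"], span = runs[, "units"] * k)
}

#' Decompose a sequence into exact motif runs
#'
#' Segments a sequence (in locus orientation) into maximal runs of exact
#' tandem copies of the configured motifs, the way an expansion-bearing
#' read is rendered as colored motif blocks separated by gaps. Candidate
#' runs of different motifs that overlap are resolved longest-first
#' (leftmost on ties); the losing run is trimmed to its longest conflict-free
#' stretch of whole copies and kept if it still reaches \code{min_units}.
#' Uncovered stretches become gaps; they may correspond to repeat
#' interruptions or to base-calling errors. Adjacent runs of the same motif
#' separated by a gap of at most \code{max_merge_gap} bases are reported as
#' a single segment whose \code{unit_count} sums only the exact copies (the
#' merged segment's span then exceeds \code{unit_count * 5}).
#'
#' @param seq Character scalar DNA sequence in locus orientation; an empty
#'   sequence yields an empty structure.
#' @param motifs Character vector of repeat units (default TTTTA, TTTCA).
#' @param min_units Minimum exact tandem copies starting a run (default 2;
#'   single isolated motif copies count as gap content).
#' @param max_merge_gap Maximum gap, in bases, bridged when merging
#'   same-motif runs (default 10).
#' @return An object of class \code{repeat_structure}: a list with
#'   \item{segments}{data.frame \code{motif}, \code{unit_count},
#'     \code{start_offset} (0-based), \code{span_bases}.}
#'   \item{gaps}{data.frame \code{start_offset}, \code{span_bases}.}
#'   \item{total_units}{sum of exact unit counts.}
#'   \item{total_span_bases}{length of the decomposed interval
#'     (\code{nchar(seq)}); segments and gaps tile it exactly.}
#' @examples
#' decompose(strrep("TTTTA", 4))
#' decompose(paste0(strrep("TTTTA", 4), strrep("TTTCA", 3)))
#' @export
decompose <- function(seq, motifs = c("TTTTA", "TTTCA"),
                      min_units = 2L, max_merge_gap = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  cand <- do.call(rbind, lapply(toupper(motifs), function(m) {
    find_tandem_runs(seq, m, min_units = min_units)
  }))
  segs <- resolve_overlaps(cand, min_units = min_units)
  segs <- merge_same_motif(segs, max_merge_gap = max_merge_gap)
  gaps <- structure_gaps(segs, n)
  structure(list(
    segments = data.frame(
      motif = segs$motif,
      unit_count = as.integer(segs$units),
      start_offset = as.integer(segs$start - 1L),
      span_bases = as.integer(segs$span)),
    gaps = gaps,
    total_units = as.integer(sum(segs$units)),
    total_span_bases = as.integer(n)),
    class = "repeat_structure")
}

# longest-first (leftmost on tie) acceptance with whole-copy trimming
#' @keywords internal
resolve_overlaps <- function(cand, min_units = 2L) {
  empty <- data.frame(motif = character(), start = integer(),
                      units = integer(), span = integer())
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$span, cand$start), , drop = FALSE]
  acc <- empty
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; u <- cand$units[i]
    k <- cand$span[i] %/% u
    cs <- s + (seq_len(u) - 1L) * k   # copy starts
    ce <- cs + k - 1L
    if (nrow(acc)) {
      a_s <- acc$start; a_e <- acc$start + acc$span - 1L
      free <- vapply(seq_along(cs), function(j) {
        !any(a_s <= ce[j] & a_e >= cs[j])
      }, logical(1))
    } else {
      free <- rep(TRUE, u)
    }
    if (!any(free)) next
    # longest contiguous stretch of conflict-free copies
    r <- rle(free)
    best <- which(r$values & r$lengths == max(r$lengths[r$values]))[1L]
    len <- r$lengths[best]
    if (len < min_units) next
    first <- sum(r$lengths[seq_len(best - 1L)]) + 1L
    acc <- rbind(acc, data.frame(motif = cand$motif[i],
                                 start = cs[first],
                                 units = len, span = len * k))
  }
  acc[order(acc$start), , drop = FALSE]
}

# merge adjacent same-motif runs across small gaps (exact copies only)
#' @keywords internal
merge_same_motif <- function(segs, max_merge_gap = 10L) {
  if (nrow(segs) <= 1L) return(segs)
  out <- segs[1L, , drop = FALSE]
  for (i in 2L:nrow(segs)) {
    last <- nrow(out)
    gap <- segs$start[i] - (out$start[last] + out$span[last])
    if (segs$motif[i] == out$motif[last] && gap <= max_merge_gap) {
      out$units[last] <- out$units[last] + segs$units[i]
      out$span[last] <- segs$start[i] + segs$span[i] - out$start[last]
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}

#' @keywords internal
structure_gaps <- function(segs, n) {
  if (n == 0L) {
    return(data.frame(start_offset = integer(), span_bases = integer()))
  }
  covered <- logical(n)
  for (i in seq_len(nrow(segs))) {
    covered[segs$start[i]:(segs$start[i] + segs$span[i] - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(!r$values)
  data.frame(start_offset = as.integer(starts[idx] - 1L),
             span_bases = as.integer(r$lengths[idx]))
}

#' Compact text rendering of a repeat structure
#'
#' @param x A \code{repeat_structure}.
#' @param with_gaps Include gap lengths, e.g. \code{"(TTTTA)12[gap 4](TTTCA)7"}.
#' @return Character scalar like \code{"(TTTTA)791(TTTCA)244"}.
#' @export
structure_string <- function(x, with_gaps = FALSE) {
  stopifnot(inherits(x, "repeat_structure"))
  if (nrow(x$segments) == 0L) return("")
  if (!with_gaps) {
    return(paste0("(", x$segments$motif, ")", x$segments$unit_count,
                  collapse = ""))
  }
  ev <- rbind(
    data.frame(off = x$segments$start_offset,
               txt = paste0("(", x$segments$motif, ")", x$segments$unit_count)),
    data.frame(off = x$gaps$start_offset,
               txt = paste0("[gap ", x$gaps$span_bases, "]")))
  paste(ev$txt[order(ev$off)], collapse = "")
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat("<repeat_structure> ", structure_string(x),
      "  (", x$total_units, " units over ", x$total_span_bases, " bases, ",
      nrow(x$gaps), " gaps)\n", sep = "")
  invisible(x)
}
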