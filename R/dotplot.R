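#' Dot-plot comparison of two sequences
#'
#' Classic word-match dot plot: cell (i, j) is TRUE when the
#' \code{word}-length substrings starting at position i of \code{seq_a} and
#' j of \code{seq_b} are identical. Tandem expansions against a reference
#' appear as filled blocks or vertical lines.
#'
#' @param seq_a,seq_b Character scalar DNA sequences.
#' @param word Word length (default 10); must not exceed either sequence
#'   length.
#' @param step Step between sampled positions (default 1).
#' @return Logical matrix; rows index positions in \code{seq_a}, columns
#'   positions in \code{seq_b}. Row/column names carry the 1-based
#'   positions.
#' @examples
#' m <- dotplot(strrep("TTTTA", 10), strrep("TTTTA", 10), word = 5)
#' @export
dotplot <- function(seq_a, seq_b, word = 10L, step = 1L) {
  stopifnot(is.character(seq_a), is.character(seq_b))
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (word > nchar(seq_a) || word > nchar(seq_b)) {
    stop("word length exceeds a sequence length", call. = FALSE)
  }
  ia <- seq.int(1L, nchar(seq_a) - word + 1L, by = step)
  ib <- seq.int(1L, nchar(seq_b) - word + 1L, by = step)
  wa <- substring(seq_a, ia, ia + word - 1L)
  wb <- substring(seq_b, ib, ib + word - 1L)
  m <- outer(wa, wb, "==")
  dimnames(m) <- list(ia, ib)
  m
}

#' Write a dot-plot matrix as TSV
#' @param m Logical matrix from \code{\link{dotplot}} (written as 0/1).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dotplot <- function(m, path) {
  utils::write.table(m * 1L, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Plot a dot-plot matrix
#' @param m Logical matrix from \code{\link{dotplot}}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot_dotplot <- function(m, ...) {
  graphics::image(x = as.integer(rownames(m)), y = as.integer(colnames(m)),
                  z = m * 1L, col = c("white", "black"),
                  xlab = "sequence A (bp)", ylab = "sequence B (bp)",
                  useRaster = TRUE, ...)
  invisible(NULL)
}
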