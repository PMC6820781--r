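#' Canonical form of a repeat motif
#'
#' Repeat motifs are reported under a strand- and rotation-independent
#' canonical form: the lexicographically smallest string among all rotations
#' of the motif and all rotations of its reverse complement. This is the
#' usual convention of short-tandem-repeat genotypers, under which TTTTA is
#' reported as AAAAT and TTTCA as AAATG.
#'
#' @param motif Character scalar over the alphabet A/C/G/T (case
#'   insensitive).
#' @return Character scalar, the canonical motif. Idempotent:
#'   \code{canonical_motif(canonical_motif(x)) == canonical_motif(x)}.
#' @examples
#' canonical_motif("TTTTA") # "AAAAT"
#' canonical_motif("TTTCA") # "AAATG"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("invalid alphabet: motif must contain only A, C, G, T", call. = FALSE)
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' All rotations of a string
#' @param x character scalar
#' @return character vector of nchar(x) rotations
#' @keywords internal
rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i) {
    paste0(substr(x, i, n), substr(x, 1L, i - 1L))
  }, character(1))
}

#' Reverse complement of a DNA string
#' @param x character scalar (A/C/G/T)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Strand/rotation variants of a motif
#'
#' All rotations of a motif and of its reverse complement; used when tiling
#' reads whose register and strand relative to the repeat are unknown.
#' @param motif character scalar
#' @return character vector of unique variants
#' @keywords internal
motif_variants <- function(motif) {
  unique(c(rotations(toupper(motif)), rotations(revcomp(toupper(motif)))))
}
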