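#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first record character ('>' FASTA,
#' '@' FASTQ); plain and gzip-compressed files are handled transparently.
#' Record ids are preserved verbatim.
#'
#' @param path Path to a FASTA/FASTQ file, optionally .gz.
#' @return data.frame with columns \code{id}, \code{sequence} and
#'   \code{quality} (NA for FASTA).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  first_line <- readLines(con, n = 1L, warn = FALSE)
  close(con)
  first <- substr(first_line, 1L, 1L)
  if (!length(first) || !nzchar(first)) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character()))
  }
  if (first == ">") {
    set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                    error = function(e) {
                      stop("malformed FASTA in ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    data.frame(id = names(set), sequence = as.character(set),
               quality = NA_character_, row.names = NULL)
  } else if (first == "@") {
    tryCatch({
      set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
      data.frame(id = names(set), sequence = as.character(set),
                 quality = as.character(S4Vectors::mcols(set)$qualities),
                 row.names = NULL)
    }, error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    stop("unrecognized sequence format in ", path,
         " (expected '>' or '@')", call. = FALSE)
  }
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path (.gz supported).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTQ
#' @param seqs Named character vector of sequences.
#' @param path Output path (.gz supported).
#' @param qualities Optional character vector of quality strings; defaults
#'   to a constant high quality.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  if (is.null(qualities)) {
    qualities <- strrep("I", nchar(seqs))
  }
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(qualities),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Headers mandatory, UTF-8, '.' decimal separator, no quoting.
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
famex_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
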