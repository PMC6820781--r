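#' Locus configuration
#'
#' Describes the repeat locus being analyzed: the flanking anchor sequences
#' used to locate the repeat in reads, the set of repeat motifs (in locus
#' orientation), the reference coordinates of the repeat tract, and the
#' combing classification thresholds.
#'
#' @param locus_id Identifier for the locus.
#' @param left_flank,right_flank Flanking sequences in locus orientation
#'   (>= 100 bases each). The 3' end of \code{left_flank} and the 5' end of
#'   \code{right_flank} abut the repeat tract. Flanks must not contain a run
#'   of two or more consecutive copies of any configured motif.
#' @param motifs Character vector of repeat units in locus orientation
#'   (default \code{c("TTTTA", "TTTCA")}); every motif must have length 5.
#' @param ref_assembly Assembly label, e.g. \code{"GRCh37"}.
#' @param ref_start,ref_end 1-based inclusive genomic coordinates of the
#'   reference repeat tract (\code{ref_end >= ref_start}).
#' @param chrom Chromosome label.
#' @param thresholds Named list with combing classification parameters
#'   \code{normal_max_kb} (default 5.5) and \code{pathogenic_min_kb}
#'   (default 8.5).
#' @return An object of class \code{locus_config}.
#' @seealso \code{\link{fame3_locus}} for the packaged example locus,
#'   \code{\link{read_locus_config}} / \code{\link{write_locus_config}} for
#'   JSON round-tripping.
#' @export
locus_config <- function(locus_id, left_flank, right_flank,
                         motifs = c("TTTTA", "TTTCA"),
                         ref_assembly = "GRCh37",
                         ref_start, ref_end, chrom = "chr5",
                         thresholds = list(normal_max_kb = 5.5,
                                           pathogenic_min_kb = 8.5)) {
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  motifs <- toupper(motifs)
  cfg <- structure(
    list(locus_id = as.character(locus_id),
         left_flank = left_flank, right_flank = right_flank,
         motifs = motifs, ref_assembly = ref_assembly,
         chrom = chrom,
         ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
         thresholds = thresholds),
    class = "locus_config")
  validate_locus_config(cfg)
  cfg
}

#' @keywords internal
validate_locus_config <- function(cfg) {
  stopifnot(inherits(cfg, "locus_config"))
  if (cfg$ref_end < cfg$ref_start) {
    stop("ref_end must be >= ref_start", call. = FALSE)
  }
  if (any(nchar(cfg$motifs) != 5L)) {
    stop("every motif must have length 5", call. = FALSE)
  }
  if (nchar(cfg$left_flank) < 100L || nchar(cfg$right_flank) < 100L) {
    stop("flanks must be at least 100 bases", call. = FALSE)
  }
  for (fl in c(cfg$left_flank, cfg$right_flank)) {
    for (m in cfg$motifs) {
      if (grepl(paste0(m, m), fl, fixed = TRUE)) {
        stop("flank contains a tandem run of motif ", m, call. = FALSE)
      }
    }
  }
  for (th in c("normal_max_kb", "pathogenic_min_kb")) {
    if (is.null(cfg$thresholds[[th]])) {
      stop("thresholds must define ", th, call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.locus_config <- function(x, ...) {
  cat("<locus_config>", x$locus_id, "\n")
  cat("  ", x$ref_assembly, " ", x$chrom, ":", x$ref_start, "-", x$ref_end,
      " (", x$ref_end - x$ref_start + 1L, " bp reference tract)\n", sep = "")
  cat("  motifs:", paste(x$motifs, collapse = ", "), "\n")
  cat("  flanks:", nchar(x$left_flank), "/", nchar(x$right_flank), "bases\n")
  cat("  thresholds: N < ", x$thresholds$normal_max_kb, " kb <= U < ",
      x$thresholds$pathogenic_min_kb, " kb <= P\n", sep = "")
  invisible(x)
}

#' Read a locus configuration from JSON
#' @param path Path to a JSON file as written by
#'   \code{\link{write_locus_config}}.
#' @return A \code{\link{locus_config}} object.
#' @export
read_locus_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("locus_id", "left_flank", "right_flank", "motifs",
                "ref_assembly", "chrom", "ref_start", "ref_end", "thresholds")
  missing <- setdiff(required, names(js))
  if (length(missing)) {
    stop("locus config missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  locus_config(js$locus_id, js$left_flank, js$right_flank,
               motifs = js$motifs, ref_assembly = js$ref_assembly,
               ref_start = js$ref_start, ref_end = js$ref_end,
               chrom = js$chrom, thresholds = as.list(js$thresholds))
}

#' Write a locus configuration to JSON
#' @param cfg A \code{\link{locus_config}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_locus_config <- function(cfg, path) {
  validate_locus_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Packaged example locus configuration
#'
#' The intron-1 TTTTA/TTTCA locus on chromosome 5p15.2 with its GRCh37
#' reference tract coordinates (chr5:10,356,460-10,356,519; 12 TTTTA units).
#' The flanking sequences are \emph{synthetic} stand-ins generated under a
#' fixed seed (the true genomic flanks are not shipped with the package);
#' they satisfy the anchoring contract (>= 100 bases, no tandem motif runs)
#' and are suitable for simulation and testing.
#' @return A \code{\link{locus_config}}.
#' @export
fame3_locus <- function() {
  read_locus_config(system.file("extdata", "fame3_locus_synthetic.json",
                                package = "famex", mustWork = TRUE))
}

#' Reference repeat tract implied by a locus configuration
#'
#' Builds the repeat tract sequence of the reference assembly: a pure
#' tandem of the first configured motif spanning the printed 1-based
#' inclusive coordinates. The tract length must be a multiple of the motif
#' length.
#' @param cfg A \code{\link{locus_config}}.
#' @return Character scalar DNA sequence.
#' @export
reference_tract <- function(cfg) {
  validate_locus_config(cfg)
  len <- cfg$ref_end - cfg$ref_start + 1L
  unit <- cfg$motifs[[1L]]
  if (len %% nchar(unit) != 0L) {
    stop("reference tract length ", len,
         " is not a multiple of the motif length", call. = FALSE)
  }
  strrep(unit, len %/% nchar(unit))
}
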