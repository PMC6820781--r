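#' Molecular-combing (fiber FISH) analysis
#'
#' A combed fiber at the expansion locus is read as a token sequence:
#' B (blue 5' flank probe), Y (unstained part between the blue and red
#' signals, or between blue and green when no red signal is present),
#' R (red repeat probe), W (unstained part between red and green or between
#' two red signals), G (green 3' flank probe). M (magenta) and C (cyan) are
#' overlays of red+blue and green+blue probes, indicating probes that should
#' be separated lying on top of each other; END_TRUNCATED marks a fiber that
#' ends before the locus is fully covered.
#'
#' @name combing
NULL

.combing_tokens <- c("B", "Y", "R", "W", "G", "M", "C", "END_TRUNCATED")

#' Construct a combing allele record
#'
#' @param tokens Character vector of signal tokens (see \link{combing}).
#' @param lengths_kb Numeric vector of measured lengths (kb), parallel to
#'   \code{tokens}; END_TRUNCATED carries length 0.
#' @param individual_id,fiber_id Identifiers.
#' @param complete FALSE iff the fiber is truncated (END_TRUNCATED present).
#' @return Object of class \code{combing_allele}.
#' @export
combing_allele <- function(tokens, lengths_kb, individual_id = "ind",
                           fiber_id = "fiber", complete = !("END_TRUNCATED" %in% tokens)) {
  tokens <- toupper(tokens)
  if (!all(tokens %in% .combing_tokens)) {
    stop("unknown combing token: ",
         paste(setdiff(tokens, .combing_tokens), collapse = ", "),
         call. = FALSE)
  }
  if (length(tokens) != length(lengths_kb)) {
    stop("tokens and lengths_kb must have equal length", call. = FALSE)
  }
  if (any(lengths_kb < 0, na.rm = TRUE)) {
    stop("lengths must be >= 0", call. = FALSE)
  }
  if (complete == ("END_TRUNCATED" %in% tokens)) {
    stop("complete flag inconsistent with END_TRUNCATED token",
         call. = FALSE)
  }
  structure(list(individual_id = individual_id, fiber_id = fiber_id,
                 tokens = tokens, lengths_kb = as.numeric(lengths_kb),
                 complete = complete),
            class = "combing_allele")
}

#' Flag micro-rearrangements from a fiber's token sequence
#'
#' A fiber is flagged as rearranged when its signal grammar is violated:
#' an overlay token (M or C) is present; one flank probe is absent while
#' the other flank and the red repeat signal are present; a flank probe is
#' duplicated; or flank polarity is inverted (G before B). The first
#' matching rule is recorded as the reason.
#'
#' @param tokens Character vector of signal tokens.
#' @return List with \code{rearranged} (logical) and \code{reason}
#'   (character; NA when not rearranged).
#' @export
flag_rearrangement <- function(tokens) {
  tokens <- toupper(tokens)
  has <- function(t) t %in% tokens
  if (has("M") || has("C")) {
    return(list(rearranged = TRUE, reason = "overlay"))
  }
  if (xor(has("B"), has("G")) && has("R")) {
    return(list(rearranged = TRUE, reason = "missing_flank"))
  }
  if (sum(tokens == "B") > 1L || sum(tokens == "G") > 1L) {
    return(list(rearranged = TRUE, reason = "duplicated_flank"))
  }
  if (has("B") && has("G") &&
      match("G", tokens) < match("B", tokens)) {
    return(list(rearranged = TRUE, reason = "inverted_flank_order"))
  }
  list(rearranged = FALSE, reason = NA_character_)
}

#' Classify a complete, non-rearranged allele
#'
#' Red-positive alleles are definite pathogenic. Red-negative alleles are
#' classified by the unstained length Y: normal (N) when
#' Y < \code{normal_max}, undefined (U) when
#' \code{normal_max} <= Y < \code{pathogenic_min}, likely pathogenic
#' (P_likely) when Y >= \code{pathogenic_min}. Threshold ties follow the
#' printed inequalities exactly (Y = 5.5 is U; Y = 8.5 is P_likely).
#'
#' @param allele A \code{\link{combing_allele}} (complete, not rearranged;
#'   those classes take precedence and must be handled by the caller).
#' @param thresholds Named list with \code{normal_max_kb} (default 5.5) and
#'   \code{pathogenic_min_kb} (default 8.5).
#' @return One of \code{"N"}, \code{"U"}, \code{"P_likely"},
#'   \code{"P_definite"}.
#' @export
classify_allele <- function(allele,
                            thresholds = list(normal_max_kb = 5.5,
                                              pathogenic_min_kb = 8.5)) {
  if ("R" %in% allele$tokens) return("P_definite")
  y <- allele_Y(allele)
  if (is.na(y)) {
    stop("measurement error: red-negative allele without Y measurement",
         call. = FALSE)
  }
  if (y < thresholds$normal_max_kb) "N"
  else if (y < thresholds$pathogenic_min_kb) "U"
  else "P_likely"
}

# Y value of an allele: the (single) Y token before the first R
#' @keywords internal
allele_Y <- function(allele) {
  idx <- which(allele$tokens == "Y")
  if (!length(idx)) return(NA_real_)
  first_r <- match("R", allele$tokens)
  if (!is.na(first_r)) idx <- idx[idx < first_r]
  if (!length(idx)) return(NA_real_)
  allele$lengths_kb[idx[1L]]
}

#' Expansion size from combing measurements
#'
#' Total expansion size of a pathogenic allele:
#' \code{Yp - Yn + R_total + W_total}, where Yp is the allele's own Y
#' measurement and Yn the median Y of the same individual's normal alleles.
#' Near-normal alleles can yield slightly negative values; they are
#' returned as-is (callers flag them) to keep means unbiased.
#'
#' @param Yp,Yn,R_total,W_total Non-negative kb values.
#' @return Numeric size in kb.
#' @examples
#' expansion_size(10, 2, 3, 1)  # 12
#' @export
expansion_size <- function(Yp, Yn, R_total, W_total) {
  stopifnot(all(c(Yp, Yn, R_total, W_total) >= 0))
  Yp - Yn + R_total + W_total
}

#' Assign an expansion configuration label
#'
#' Deterministic mapping from an accepted token pattern to a configuration
#' class. The taxonomy is a declared convention of this package (the
#' configurations are defined pictorially in the source material):
#' C1 = B,Y,R,G; C2 = B,Y,R,W,G; C3 = B,Y,R,W,R,G; C4 = B,Y,R,W,R,W,G;
#' C5 = B,Y,G with an expanded Y (>= \code{pathogenic_min}, red-negative
#' likely pathogenic); C6 = any other accepted B...G pattern with at least
#' three red segments. Anything else (including normal B,Y,G fibers) maps
#' to NA.
#'
#' @param tokens Character vector of signal tokens; must not describe a
#'   rearranged fiber (precondition error otherwise).
#' @param y_kb Y measurement (needed to separate C5 from a normal fiber).
#' @param pathogenic_min Threshold for the expanded-Y rule (default 8.5).
#' @return \code{"C1"}..\code{"C6"} or \code{NA_character_}.
#' @export
assign_configuration <- function(tokens, y_kb = NA_real_,
                                 pathogenic_min = 8.5) {
  tokens <- toupper(tokens)
  fr <- flag_rearrangement(tokens)
  if (fr$rearranged) {
    stop("precondition violated: rearranged fiber (", fr$reason, ")",
         call. = FALSE)
  }
  if ("END_TRUNCATED" %in% tokens) {
    stop("precondition violated: incomplete fiber", call. = FALSE)
  }
  pat <- paste(tokens, collapse = ",")
  if (pat == "B,Y,R,G") return("C1")
  if (pat == "B,Y,R,W,G") return("C2")
  if (pat == "B,Y,R,W,R,G") return("C3")
  if (pat == "B,Y,R,W,R,W,G") return("C4")
  if (pat == "B,Y,G") {
    return(if (!is.na(y_kb) && y_kb >= pathogenic_min) "C5"
           else NA_character_)
  }
  if (sum(tokens == "R") >= 3L &&
      tokens[1L] == "B" && tokens[length(tokens)] == "G" &&
      all(tokens[-c(1L, length(tokens))] %in% c("Y", "R", "W"))) {
    return("C6")
  }
  NA_character_
}

#' Read a combing measurement table
#'
#' Expected TSV columns: \code{individual_id}, \code{fiber_id},
#' \code{tokens} (comma-joined symbols), \code{lengths_kb} (comma-joined kb
#' values parallel to the tokens) and \code{complete} (0/1).
#'
#' @param path Path to the TSV.
#' @return data.frame in the measurement schema.
#' @export
read_combing_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "fiber_id", "tokens", "lengths_kb",
                "complete")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("combing table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Call alleles from a combing measurement table
#'
#' Full allele-level analysis: parses each fiber, flags incomplete and
#' rearranged fibers (which take precedence over size classes), classifies
#' the remainder into N/U/P_likely/P_definite, derives the per-individual
#' baseline Yn (median Y of that individual's N alleles), and computes, for
#' every pathogenic allele, the total expansion size Yp - Yn + R + W and
#' its parts (5'-TTTTA = Yp - Yn, TTTCA = sum of R, 3'-TTTTA = sum of W;
#' the W measurement is kept raw alongside this interpretation).
#'
#' @param measurements data.frame in the schema of
#'   \code{\link{read_combing_table}}.
#' @param thresholds Named list with \code{normal_max_kb} and
#'   \code{pathogenic_min_kb}; defaults to the standard 5.5/8.5 kb.
#' @return data.frame with one row per fiber: identifiers, class,
#'   rearrangement reason, configuration, Y/R/W measurements, baseline
#'   \code{Yn_kb}, \code{expansion_kb} and part sizes (NA outside P
#'   classes), and a \code{negative_flag} for slightly negative sizes.
#' @export
call_alleles <- function(measurements,
                         thresholds = list(normal_max_kb = 5.5,
                                           pathogenic_min_kb = 8.5)) {
  n <- nrow(measurements)
  parse_one <- function(i) {
    toks <- strsplit(measurements$tokens[i], ",[ ]*")[[1L]]
    lens <- as.numeric(strsplit(as.character(measurements$lengths_kb[i]),
                                ",[ ]*")[[1L]])
    combing_allele(toks, lens,
                   individual_id = measurements$individual_id[i],
                   fiber_id = measurements$fiber_id[i],
                   complete = as.logical(as.integer(measurements$complete[i])))
  }
  alleles <- lapply(seq_len(n), parse_one)
  rows <- lapply(alleles, function(a) {
    fr <- flag_rearrangement(a$tokens)
    klass <- if (!a$complete) "incomplete"
    else if (fr$rearranged) "rearranged"
    else classify_allele(a, thresholds)
    data.frame(individual_id = a$individual_id, fiber_id = a$fiber_id,
               class = klass, rearranged_reason = fr$reason,
               Y_kb = allele_Y(a),
               R_total_kb = sum(a$lengths_kb[a$tokens == "R"]),
               W_total_kb = sum(a$lengths_kb[a$tokens == "W"]),
               n_R = sum(a$tokens == "R"),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  # per-individual baseline from N alleles only
  yn <- tapply(calls$Y_kb[calls$class == "N"],
               calls$individual_id[calls$class == "N"], median)
  calls$Yn_kb <- as.numeric(yn[calls$individual_id])
  is_p <- calls$class %in% c("P_definite", "P_likely")
  calls$expansion_kb <- NA_real_
  calls$ttta5_kb <- NA_real_
  calls$tttca_kb <- NA_real_
  calls$ttta3_kb <- NA_real_
  ok <- is_p & !is.na(calls$Yn_kb) & !is.na(calls$Y_kb)
  calls$ttta5_kb[ok] <- calls$Y_kb[ok] - calls$Yn_kb[ok]
  calls$tttca_kb[ok] <- calls$R_total_kb[ok]
  calls$ttta3_kb[ok] <- calls$W_total_kb[ok]
  calls$expansion_kb[ok] <- expansion_size(calls$Y_kb[ok], calls$Yn_kb[ok],
                                           calls$R_total_kb[ok],
                                           calls$W_total_kb[ok])
  calls$negative_flag <- !is.na(calls$expansion_kb) &
    (calls$expansion_kb < 0 | calls$ttta5_kb < 0)
  calls$configuration <- NA_character_
  cfg_ok <- calls$class %in% c("N", "U", "P_likely", "P_definite")
  calls$configuration[cfg_ok] <- vapply(which(cfg_ok), function(i) {
    assign_configuration(alleles[[i]]$tokens, y_kb = calls$Y_kb[i],
                         pathogenic_min = thresholds$pathogenic_min_kb)
  }, character(1))
  calls
}

#' Per-individual combing summary
#'
#' Aggregates allele calls into the per-individual combing block: number of
#' pathogenic alleles, mean/median/SD of expansion size and of each part
#' over pathogenic alleles only (rearranged and incomplete alleles are
#' excluded from all size statistics), the fraction of rearranged alleles,
#' and its per-cell conversion \code{min(100, 2 x percent_alleles)} (a cell
#' carries two alleles; at most one is assumed rearranged).
#'
#' @param calls data.frame from \code{\link{call_alleles}}.
#' @return data.frame with one row per individual.
#' @export
cohort_summary <- function(calls) {
  out <- lapply(split(calls, calls$individual_id), function(d) {
    ind <- d$individual_id[1L]
    n_N <- sum(d$class == "N")
    if (n_N == 0L) {
      stop("baseline unavailable: individual ", ind,
           " has no normal (N) alleles", call. = FALSE)
    }
    p <- d[d$class %in% c("P_definite", "P_likely"), , drop = FALSE]
    n_complete <- sum(d$class != "incomplete")
    pct_alleles <- 100 * sum(d$class == "rearranged") / n_complete
    data.frame(
      individual_id = ind,
      n_alleles = nrow(d),
      n_N = n_N,
      n_U = sum(d$class == "U"),
      n_P = nrow(p),
      n_rearranged = sum(d$class == "rearranged"),
      n_incomplete = sum(d$class == "incomplete"),
      Yn_kb = d$Yn_kb[1L],
      mean_expansion_kb = mean(p$expansion_kb),
      median_expansion_kb = median(p$expansion_kb),
      sd_expansion_kb = sd(p$expansion_kb),
      mean_ttta5_kb = mean(p$ttta5_kb),
      mean_tttca_kb = mean(p$tttca_kb),
      mean_ttta3_kb = mean(p$ttta3_kb),
      percent_rearranged_alleles = pct_alleles,
      percent_rearranged_cells = min(100, 2 * pct_alleles),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
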