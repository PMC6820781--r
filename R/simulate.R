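#' Seeded evaluation
#'
#' Runs an expression under an explicit RNG seed and restores the previous
#' RNG state afterwards, so all emitters are deterministic and free of
#' global side effects.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Germline expansion model for one individual
#'
#' States the generative world the simulators draw from: a germline
#' 5'-(TTTTA)(TTTCA)(TTTTA)-3' structure in repeat units, per-cell
#' log-normal length jitter (somatic mosaicism), a mix over expansion
#' configurations, and a size-dependent micro-rearrangement probability.
#'
#' The rearrangement probability is a scaled logistic of the cell's
#' expansion size, p(s) = p_max / (1 + exp(-slope (s - midpoint))). With
#' the defaults (p_max 0.12, midpoint 12 kb, slope 0.8 per kb) an
#' individual with a 14-kb mean expansion shows about 10 percent rearranged
#' alleles, while a 4-kb individual stays below 3 percent, matching the
#' observed association of micro-rearrangements with the largest
#' expansions.
#'
#' @param n_ttta5,n_tttca,n_ttta3 Germline unit counts per segment
#'   (defaults 560/480/120, i.e. a 5.8-kb expansion in the typical range).
#' @param somatic_cv Coefficient of variation of the per-cell log-normal
#'   length jitter applied to each segment (default 0.3).
#' @param config_mix Named probabilities over configurations C1..C6
#'   (must sum to 1). Configurations redistribute the jittered units
#'   without changing the total: C1 folds the 3' TTTTA into the 5' part,
#'   C3/C4/C6 split the TTTCA (and spacer TTTTA) into multiple blocks, C5
#'   converts everything to TTTTA (red-negative expansion).
#' @param rearrange_pmax,rearrange_midpoint_kb,rearrange_slope Scaled
#'   logistic parameters of the rearrangement probability.
#' @param normal_units TTTTA units on the individual's normal allele
#'   (default 12; controls range roughly 9-20).
#' @return Object of class \code{expansion_model}.
#' @export
expansion_model <- function(n_ttta5 = 560L, n_tttca = 480L, n_ttta3 = 120L,
                            somatic_cv = 0.3,
                            config_mix = c(C1 = 0.25, C2 = 0.55, C3 = 0.08,
                                           C4 = 0.04, C5 = 0.05, C6 = 0.03),
                            rearrange_pmax = 0.12,
                            rearrange_midpoint_kb = 12,
                            rearrange_slope = 0.8,
                            normal_units = 12L) {
  stopifnot(n_ttta5 >= 0, n_tttca >= 0, n_ttta3 >= 0, somatic_cv >= 0,
            rearrange_pmax >= 0, rearrange_pmax <= 1)
  if (abs(sum(config_mix) - 1) > 1e-8) {
    stop("config_mix probabilities must sum to 1", call. = FALSE)
  }
  if (!all(names(config_mix) %in% paste0("C", 1:6))) {
    stop("config_mix names must be C1..C6", call. = FALSE)
  }
  structure(list(n_ttta5 = as.integer(n_ttta5),
                 n_tttca = as.integer(n_tttca),
                 n_ttta3 = as.integer(n_ttta3),
                 somatic_cv = somatic_cv, config_mix = config_mix,
                 rearrange_pmax = rearrange_pmax,
                 rearrange_midpoint_kb = rearrange_midpoint_kb,
                 rearrange_slope = rearrange_slope,
                 normal_units = as.integer(normal_units)),
            class = "expansion_model")
}

#' Rearrangement probability at a given expansion size
#' @param model An \code{\link{expansion_model}}.
#' @param size_kb Expansion size(s) in kb.
#' @return Probability in [0, rearrange_pmax].
#' @export
p_rearrange <- function(model, size_kb) {
  model$rearrange_pmax /
    (1 + exp(-model$rearrange_slope *
               (size_kb - model$rearrange_midpoint_kb)))
}

#' Long-read per-base error model
#'
#' Substitution/insertion/deletion rates per base, emulating nanopore-like
#' base-calling error (defaults 0.03/0.03/0.04, i.e. 10 percent combined).
#' @param substitution,insertion,deletion Rates, each in [0, 0.2].
#' @return Object of class \code{read_error_model}.
#' @export
read_error_model <- function(substitution = 0.03, insertion = 0.03,
                             deletion = 0.04) {
  rates <- c(substitution, insertion, deletion)
  if (any(rates < 0 | rates > 0.2)) {
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion), class = "read_error_model")
}

#' Phenotype generative model
#'
#' Age at seizure onset = a - b * mean TTTCA size (kb) + Normal(0, sigma),
#' truncated at 10 years; b > 0 encodes the inverse relationship between
#' TTTCA length and onset that the correlation analysis must detect. Age
#' at tremor onset is drawn independently of expansion size.
#' @param a,b,sigma Seizure-onset parameters (defaults 45, 2.5, 5; years
#'   and years per kb).
#' @param tremor_mean,tremor_sd Independent tremor-onset distribution
#'   (defaults 30, 12 years, truncated at 5).
#' @return Object of class \code{phenotype_model}.
#' @export
phenotype_model <- function(a = 45, b = 2.5, sigma = 5,
                            tremor_mean = 30, tremor_sd = 12) {
  structure(list(a = a, b = b, sigma = sigma,
                 tremor_mean = tremor_mean, tremor_sd = tremor_sd),
            class = "phenotype_model")
}

#' Simulate a somatically mosaic allele population
#'
#' Per cell: each germline segment's unit count is jittered by a log-normal
#' multiplier with unit mean and coefficient of variation
#' \code{somatic_cv}; a configuration is drawn from \code{config_mix} and
#' redistributes the units (total preserved); the cell is marked rearranged
#' with probability \code{p_rearrange(model, size)}.
#'
#' @param model An \code{\link{expansion_model}}.
#' @param n_cells Number of cells.
#' @param seed Explicit RNG seed.
#' @return Truth data.frame: \code{cell_id}, \code{config},
#'   \code{n_ttta5}, \code{n_tttca}, \code{n_ttta3} (effective unit counts
#'   after configuration redistribution), \code{units_total},
#'   \code{size_kb}, \code{rearranged}, \code{normal_units}.
#' @export
simulate_allele_population <- function(model, n_cells = 200L, seed = 1L) {
  stopifnot(inherits(model, "expansion_model"))
  with_seed(seed, {
    cv <- model$somatic_cv
    sigma <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    germ <- c(model$n_ttta5, model$n_tttca, model$n_ttta3)
    rows <- lapply(seq_len(n_cells), function(i) {
      mult <- if (sigma > 0) exp(rnorm(3L, -sigma^2 / 2, sigma)) else
        rep(1, 3L)
      cnt <- pmax(0L, as.integer(round(germ * mult)))
      config <- sample(names(model$config_mix), 1L,
                       prob = model$config_mix)
      cnt <- redistribute_units(config, cnt[1L], cnt[2L], cnt[3L])
      size_kb <- 5 * sum(cnt) / 1000
      data.frame(cell_id = sprintf("cell%04d", i), config = config,
                 n_ttta5 = cnt[1L], n_tttca = cnt[2L], n_ttta3 = cnt[3L],
                 units_total = sum(cnt), size_kb = size_kb,
                 rearranged = runif(1L) < p_rearrange(model, size_kb),
                 normal_units = model$normal_units,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# configuration redistributions preserve the unit total
#' @keywords internal
redistribute_units <- function(config, n5, nc, n3) {
  switch(config,
         C1 = c(n5 + n3, nc, 0L),
         C5 = c(n5 + nc + n3, 0L, 0L),
         c(n5, nc, n3))  # C2/C3/C4/C6 keep totals per part
}

# ordered sequence blocks of a cell's expansion (class, motif, units)
#' @keywords internal
config_blocks <- function(config, n5, nc, n3,
                          motifs = c("TTTTA", "TTTCA")) {
  t5 <- motifs[1L]; tc <- motifs[2L]
  halves <- function(x, k) {
    base <- x %/% k
    out <- rep(base, k)
    out[seq_len(x - base * k)] <- out[seq_len(x - base * k)] + 1L
    out
  }
  blocks <- switch(config,
    C1 = list(c("ttta5", n5), c("tttca", nc)),
    C2 = list(c("ttta5", n5), c("tttca", nc), c("ttta3", n3)),
    C3 = {
      r <- halves(nc, 2L)
      list(c("ttta5", n5), c("tttca", r[1L]), c("ttta3", n3),
           c("tttca", r[2L]))
    },
    C4 = {
      r <- halves(nc, 2L); w <- halves(n3, 2L)
      list(c("ttta5", n5), c("tttca", r[1L]), c("ttta3", w[1L]),
           c("tttca", r[2L]), c("ttta3", w[2L]))
    },
    C5 = list(c("ttta5", n5)),
    C6 = {
      r <- halves(nc, 3L); w <- halves(n3, 2L)
      list(c("ttta5", n5), c("tttca", r[1L]), c("ttta3", w[1L]),
           c("tttca", r[2L]), c("ttta3", w[2L]), c("tttca", r[3L]))
    },
    stop("unknown configuration ", config, call. = FALSE))
  df <- data.frame(class = vapply(blocks, `[`, character(1), 1L),
                   units = as.integer(vapply(blocks, `[`, character(1), 2L)),
                   stringsAsFactors = FALSE)
  df$motif <- ifelse(df$class == "tttca", tc, t5)
  df[df$units > 0L, , drop = FALSE]
}

# expansion sequence of one cell
#' @keywords internal
cell_sequence <- function(cell, motifs = c("TTTTA", "TTTCA")) {
  b <- config_blocks(cell$config, cell$n_ttta5, cell$n_tttca,
                     cell$n_ttta3, motifs)
  paste(strrep(b$motif, b$units), collapse = "")
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Apply per-base sequencing errors to a sequence
#' @param seq Character scalar.
#' @param model A \code{\link{read_error_model}}.
#' @return Character scalar with substitutions, insertions and deletions
#'   applied. Uses the current RNG stream (callers control the seed).
#' @export
apply_read_errors <- function(seq, model) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  if (n == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  u <- runif(n)
  del <- u < model$deletion
  sub <- !del & u < model$deletion + model$substitution
  if (any(sub)) {
    idx <- match(b[sub], bases)
    shift <- sample(1:3, sum(sub), replace = TRUE)
    b[sub] <- bases[((idx - 1L + shift) %% 4L) + 1L]
  }
  ins <- runif(n) < model$insertion
  piece <- b
  piece[del] <- ""
  if (any(ins)) {
    piece[ins] <- paste0(piece[ins],
                         sample(bases, sum(ins), replace = TRUE))
  }
  paste(piece, collapse = "")
}

#' Emit simulated long reads over the locus
#'
#' Samples cells (with replacement) from a truth table, builds
#' flank + expansion + flank sequences, optionally truncates a fraction of
#' reads (partial locus coverage), converts rearranged cells into
#' translocation-like fusion reads (right flank replaced by foreign
#' sequence) with probability \code{p_fusion_if_rearranged}, applies
#' per-base errors, and emits each read on a random strand.
#'
#' @param cells Truth data.frame from
#'   \code{\link{simulate_allele_population}}.
#' @param config A \code{\link{locus_config}}.
#' @param error_model A \code{\link{read_error_model}}; use zero rates for
#'   error-free reads.
#' @param n_reads Number of reads.
#' @param p_truncate Probability a read is truncated to partial coverage
#'   (default 0.1).
#' @param p_fusion_if_rearranged Probability a rearranged cell's read is a
#'   fusion read (default 0.5).
#' @param seed Explicit RNG seed.
#' @param out Optional FASTQ path (plain or .gz); written via
#'   \code{\link{write_fastq}}.
#' @return data.frame with \code{read_id}, \code{cell_id}, \code{strand},
#'   \code{truncated}, \code{fusion}, truth unit counts and
#'   \code{sequence}.
#' @export
emit_long_reads <- function(cells, config,
                            error_model = read_error_model(),
                            n_reads = 50L, p_truncate = 0.1,
                            p_fusion_if_rearranged = 0.5,
                            seed = 1L, out = NULL) {
  with_seed(seed, {
    pick <- sample(nrow(cells), n_reads, replace = TRUE)
    rows <- lapply(seq_len(n_reads), function(i) {
      cell <- cells[pick[i], , drop = FALSE]
      rep_seq <- cell_sequence(cell, config$motifs)
      fusion <- cell$rearranged && runif(1L) < p_fusion_if_rearranged
      s <- if (fusion) {
        paste0(config$left_flank, rep_seq, random_dna(nchar(config$right_flank)))
      } else {
        paste0(config$left_flank, rep_seq, config$right_flank)
      }
      truncated <- runif(1L) < p_truncate
      if (truncated) {
        # keep one locus end plus part of the repeat
        keep <- nchar(config$left_flank) +
          sample.int(max(1L, nchar(rep_seq) - 10L), 1L)
        s <- if (runif(1L) < 0.5) substr(s, 1L, keep)
             else substr(s, nchar(s) - keep + 1L, nchar(s))
      }
      s <- apply_read_errors(s, error_model)
      strand <- sample(c("plus", "minus"), 1L)
      if (strand == "minus") s <- revcomp(s)
      data.frame(read_id = sprintf("simread%04d", i),
                 cell_id = cell$cell_id, strand = strand,
                 truncated = truncated, fusion = fusion,
                 truth_n_ttta5 = cell$n_ttta5,
                 truth_n_tttca = cell$n_tttca,
                 truth_n_ttta3 = cell$n_ttta3,
                 truth_units = cell$units_total,
                 sequence = s, stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, rows)
    if (!is.null(out)) {
      write_fastq(setNames(reads$sequence, reads$read_id), out)
    }
    reads
  })
}

#' Emit simulated paired 150-bp short reads over the locus
#'
#' Uniform fragment sampling over the diploid locus (flank + repeat +
#' flank): each fragment picks the expanded haplotype (a random cell of the
#' truth table) or the normal haplotype with probability proportional to
#' haplotype length, a start position uniform over that haplotype, and an
#' insert size Normal(\code{insert_mean}, \code{insert_sd}) clamped to at
#' least twice the read length. Reads are error-free (PCR-free short-read
#' error is negligible at this scale).
#'
#' @param cells Truth data.frame from
#'   \code{\link{simulate_allele_population}}.
#' @param config A \code{\link{locus_config}}.
#' @param read_length Read length (default 150).
#' @param coverage Haploid-locus fold coverage (default 30); 0 yields an
#'   empty read set.
#' @param insert_mean,insert_sd Fragment length distribution.
#' @param seed Explicit RNG seed.
#' @param out_prefix Optional path prefix; writes
#'   \code{<prefix>_R1.fastq} and \code{<prefix>_R2.fastq}.
#' @return List with data.frames \code{r1} and \code{r2} (\code{id},
#'   \code{sequence}).
#' @export
emit_short_reads <- function(cells, config, read_length = 150L,
                             coverage = 30, insert_mean = 350,
                             insert_sd = 35, seed = 1L,
                             out_prefix = NULL) {
  with_seed(seed, {
    norm_hap <- paste0(config$left_flank,
                       strrep(config$motifs[1L], cells$normal_units[1L]),
                       config$right_flank)
    mean_exp_len <- nchar(config$left_flank) + nchar(config$right_flank) +
      round(mean(cells$units_total) * 5)
    n_frag <- ceiling(coverage * (nchar(norm_hap) + mean_exp_len) /
                        (2 * 2 * read_length))
    r1 <- character(0); r2 <- character(0); ids <- character(0)
    if (n_frag > 0 && coverage > 0) {
      for (i in seq_len(n_frag)) {
        p_exp <- mean_exp_len / (mean_exp_len + nchar(norm_hap))
        hap <- if (runif(1L) < p_exp) {
          cell <- cells[sample(nrow(cells), 1L), , drop = FALSE]
          paste0(config$left_flank, cell_sequence(cell, config$motifs),
                 config$right_flank)
        } else norm_hap
        len <- nchar(hap)
        ins <- max(2L * read_length,
                   min(len, as.integer(round(rnorm(1L, insert_mean,
                                                   insert_sd)))))
        if (len < ins) next
        s <- sample.int(len - ins + 1L, 1L)
        ids <- c(ids, sprintf("frag%05d", i))
        r1 <- c(r1, substr(hap, s, s + read_length - 1L))
        r2 <- c(r2, revcomp(substr(hap, s + ins - read_length,
                                   s + ins - 1L)))
      }
    }
    res <- list(r1 = data.frame(id = ids, sequence = r1,
                                stringsAsFactors = FALSE),
                r2 = data.frame(id = ids, sequence = r2,
                                stringsAsFactors = FALSE))
    if (!is.null(out_prefix)) {
      write_fastq(setNames(res$r1$sequence, paste0(res$r1$id, "/1")),
                  paste0(out_prefix, "_R1.fastq"))
      write_fastq(setNames(res$r2$sequence, paste0(res$r2$id, "/2")),
                  paste0(out_prefix, "_R2.fastq"))
    }
    res
  })
}

#' Emit a simulated combing measurement table
#'
#' Converts each cell's two alleles into fiber signal-token sequences with
#' kb lengths: flank probes B and G at fixed lengths from
#' \code{probe_map}; Y spanning the unstained offset plus the 5'-TTTTA
#' part; one R per TTTCA block; one W per internal TTTTA spacer; Gaussian
#' measurement noise on every signal; R/W signals below the detection limit
#' are dropped. Rearranged cells emit grammar-violating patterns (overlay,
#' duplicated flank, missing flank, inverted polarity); a fraction of
#' fibers is truncated and marked incomplete.
#'
#' @param cells Truth data.frame from
#'   \code{\link{simulate_allele_population}}.
#' @param probe_map List with \code{B_kb}, \code{G_kb} (flank probe
#'   lengths) and \code{y_offset_kb} (unstained distance between the blue
#'   probe and the repeat start; default 2.5 kb, the scale of normal-allele
#'   Y values).
#' @param noise_sd_kb Measurement noise SD per signal (default 0.3).
#' @param min_detectable_kb Detection limit for R/W signals (default 0.8).
#' @param p_truncate Probability a fiber is truncated (default 0.03).
#' @param individual_id Identifier used in the table.
#' @param seed Explicit RNG seed.
#' @param out Optional TSV path.
#' @return Measurement data.frame (\code{individual_id}, \code{fiber_id},
#'   \code{tokens}, \code{lengths_kb}, \code{complete}) with a
#'   \code{"truth"} attribute mapping fibers to cells
#'   (\code{fiber_id}, \code{cell_id}, \code{is_expanded},
#'   \code{rearranged}, \code{truth_size_kb}).
#' @export
emit_combing_table <- function(cells,
                               probe_map = list(B_kb = 2, G_kb = 2,
                                                y_offset_kb = 2.5),
                               noise_sd_kb = 0.3, min_detectable_kb = 0.8,
                               p_truncate = 0.03,
                               individual_id = "SIM1", seed = 1L,
                               out = NULL) {
  with_seed(seed, {
    noisy <- function(x) pmax(0.01, x + rnorm(length(x), 0, noise_sd_kb))
    meas <- list(); truth <- list()
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, , drop = FALSE]
      # expanded allele fiber
      if (cell$rearranged) {
        fib <- rearranged_fiber(cell, probe_map, noisy)
      } else {
        blocks <- config_blocks(cell$config, cell$n_ttta5, cell$n_tttca,
                                cell$n_ttta3)
        toks <- "B"; lens <- noisy(probe_map$B_kb)
        y <- probe_map$y_offset_kb +
          (if (nrow(blocks) && blocks$class[1L] == "ttta5")
            blocks$units[1L] * 5 / 1000 else 0)
        toks <- c(toks, "Y"); lens <- c(lens, noisy(y))
        rest <- if (nrow(blocks) && blocks$class[1L] == "ttta5") {
          seq_len(nrow(blocks))[-1L]
        } else seq_len(nrow(blocks))
        if (length(rest)) {
          for (j in rest) {
            kb <- noisy(blocks$units[j] * 5 / 1000)
            tok <- if (blocks$class[j] == "tttca") "R" else "W"
            if (kb >= min_detectable_kb) {
              toks <- c(toks, tok); lens <- c(lens, kb)
            }
          }
        }
        toks <- c(toks, "G"); lens <- c(lens, noisy(probe_map$G_kb))
        fib <- list(tokens = toks, lengths = lens)
      }
      ids <- paste0(cell$cell_id, c("_a", "_b"))
      norm <- list(tokens = c("B", "Y", "G"),
                   lengths = c(noisy(probe_map$B_kb),
                               noisy(probe_map$y_offset_kb +
                                       cell$normal_units * 5 / 1000),
                               noisy(probe_map$G_kb)))
      for (k in 1:2) {
        f <- if (k == 1L) fib else norm
        complete <- TRUE
        if (runif(1L) < p_truncate && length(f$tokens) > 1L) {
          keep <- sample.int(length(f$tokens) - 1L, 1L)
          f$tokens <- c(f$tokens[seq_len(keep)], "END_TRUNCATED")
          f$lengths <- c(f$lengths[seq_len(keep)], 0)
          complete <- FALSE
        }
        meas[[length(meas) + 1L]] <- data.frame(
          individual_id = individual_id, fiber_id = ids[k],
          tokens = paste(f$tokens, collapse = ","),
          lengths_kb = paste(sprintf("%.3f", f$lengths), collapse = ","),
          complete = as.integer(complete), stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          fiber_id = ids[k], cell_id = cell$cell_id,
          is_expanded = (k == 1L),
          rearranged = (k == 1L) && cell$rearranged,
          truth_size_kb = if (k == 1L) cell$size_kb else
            cell$normal_units * 5 / 1000,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, meas)
    attr(df, "truth") <- do.call(rbind, truth)
    if (!is.null(out)) {
      famex_write_tsv(df, out)
    }
    df
  })
}

# grammar-violating fiber for a rearranged cell
#' @keywords internal
rearranged_fiber <- function(cell, probe_map, noisy) {
  kind <- sample(c("overlay", "duplicated_flank", "missing_flank",
                   "inversion"), 1L)
  y <- probe_map$y_offset_kb + cell$n_ttta5 * 5 / 1000
  r <- max(0.2, cell$n_tttca * 5 / 1000)
  switch(kind,
    overlay = list(tokens = c("B", "M", "G"),
                   lengths = noisy(c(probe_map$B_kb, y, probe_map$G_kb))),
    duplicated_flank = list(
      tokens = c("B", "Y", "R", "B", "G"),
      lengths = noisy(c(probe_map$B_kb, y, r, probe_map$B_kb,
                        probe_map$G_kb))),
    missing_flank = list(tokens = c("B", "Y", "R"),
                         lengths = noisy(c(probe_map$B_kb, y, r))),
    inversion = list(
      tokens = c("G", "W", "R", "Y", "B"),
      lengths = noisy(c(probe_map$G_kb, cell$n_ttta3 * 5 / 1000 + 0.2, r,
                        y, probe_map$B_kb))))
}

#' Default per-individual models for a simulated cohort
#'
#' Ten individuals spanning the observed range of mean expansion sizes
#' (roughly 3-14 kb total, TTTCA parts from about 1.5 to 10.5 kb), without
#' claiming to reproduce any real individual.
#' @param n Number of individuals (default 10).
#' @return Named list of \code{\link{expansion_model}} objects.
#' @export
default_cohort_models <- function(n = 10L) {
  tttca <- round(seq(300, 2100, length.out = n))
  ttta5 <- round(seq(250, 550, length.out = n))
  ttta3 <- round(seq(80, 200, length.out = n))
  models <- lapply(seq_len(n), function(i) {
    expansion_model(n_ttta5 = ttta5[i], n_tttca = tttca[i],
                    n_ttta3 = ttta3[i])
  })
  names(models) <- sprintf("SIM%02d", seq_len(n))
  models
}

#' Emit a simulated phenotype cohort
#'
#' For each individual: simulates a cell population, emits and analyzes a
#' combing table (allele calling plus per-individual summary), and draws
#' onset ages from the phenotype model using the individual's mean truth
#' TTTCA size. The output follows the cohort schema used by
#' \code{\link{onset_correlation_report}} (combing_blood assay columns).
#'
#' @param models Named list of \code{\link{expansion_model}}s
#'   (default \code{\link{default_cohort_models}()}).
#' @param phenotype A \code{\link{phenotype_model}}.
#' @param n_cells Cells per individual (default 120).
#' @param seed Explicit RNG seed; per-individual sub-seeds are derived
#'   from it.
#' @param out Optional TSV path.
#' @return Cohort data.frame with a \code{"truth"} attribute holding the
#'   per-individual truth mean sizes.
#' @export
emit_cohort <- function(models = default_cohort_models(),
                        phenotype = phenotype_model(),
                        n_cells = 120L, seed = 1L, out = NULL) {
  rows <- list(); truths <- list()
  for (i in seq_along(models)) {
    id <- names(models)[i]
    sub <- (seed * 131L + i * 7L) %% 2147483647L
    cells <- simulate_allele_population(models[[i]], n_cells = n_cells,
                                        seed = sub)
    comb <- emit_combing_table(cells, individual_id = id, seed = sub + 1L)
    summ <- cohort_summary(call_alleles(comb))
    truth_tc <- mean(cells$n_tttca) * 5 / 1000
    ages <- with_seed(sub + 2L, {
      c(seizure = max(10, phenotype$a - phenotype$b * truth_tc +
                        rnorm(1L, 0, phenotype$sigma)),
        tremor = max(5, rnorm(1L, phenotype$tremor_mean,
                              phenotype$tremor_sd)))
    })
    rows[[i]] <- data.frame(
      individual_id = id, family_id = "SIM", sex = NA_character_,
      age_last_exam = NA_real_,
      age_tremor_onset = ages[["tremor"]],
      age_seizure_onset = ages[["seizure"]],
      combing_blood_n_P = summ$n_P,
      combing_blood_expansion_kb = summ$mean_expansion_kb,
      combing_blood_ttta5_kb = summ$mean_ttta5_kb,
      combing_blood_tttca_kb = summ$mean_tttca_kb,
      combing_blood_ttta3_kb = summ$mean_ttta3_kb,
      stringsAsFactors = FALSE)
    truths[[i]] <- data.frame(individual_id = id,
                              truth_mean_size_kb = mean(cells$size_kb),
                              truth_mean_tttca_kb = truth_tc,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  attr(df, "truth") <- do.call(rbind, truths)
  if (!is.null(out)) famex_write_tsv(df, out)
  df
}
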