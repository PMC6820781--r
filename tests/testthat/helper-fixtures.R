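# shared fixtures: everything is built in code, no stored data

test_locus <- function() fame3_locus()

# truth table row without going through the stochastic simulator
make_cell <- function(n5, nc, n3, config = "C2", cell_id = "cell0001",
                      rearranged = FALSE, normal_units = 12L) {
  data.frame(cell_id = cell_id, config = config,
             n_ttta5 = as.integer(n5), n_tttca = as.integer(nc),
             n_ttta3 = as.integer(n3),
             units_total = as.integer(n5 + nc + n3),
             size_kb = 5 * (n5 + nc + n3) / 1000,
             rearranged = rearranged,
             normal_units = as.integer(normal_units),
             stringsAsFactors = FALSE)
}

# combing measurement row
comb_row <- function(individual_id, fiber_id, tokens, lengths,
                     complete = 1L) {
  data.frame(individual_id = individual_id, fiber_id = fiber_id,
             tokens = paste(tokens, collapse = ","),
             lengths_kb = paste(sprintf("%.3f", lengths), collapse = ","),
             complete = complete, stringsAsFactors = FALSE)
}

# n normal fibers with fixed Y values
comb_normals <- function(individual_id, y_values, start_id = 1L) {
  do.call(rbind, lapply(seq_along(y_values), function(i) {
    comb_row(individual_id, sprintf("n%03d", start_id + i - 1L),
             c("B", "Y", "G"), c(2, y_values[i], 2))
  }))
}

# independent textbook Pearson oracle (explicit sums, no stats::cor)
oracle_pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
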