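# Independent oracles and small generators used across the test files.

# Exhaustive enumeration of natural-isotope assignments for a fragment with
# j labeled tracer carbons: every atom independently draws a mass shift
# from its element's natural distribution; labeled carbons contribute a
# fixed +1 each. Feasible for fragments with a handful of atoms; kept
# deliberately independent of the package's convolution code.
brute_force_column <- function(counts, n_tracer, j, isotope_table, nrow_out) {
  cts <- counts
  if ("C" %in% names(cts)) cts[["C"]] <- cts[["C"]] - j
  atoms <- unlist(lapply(names(cts), function(el) rep(el, cts[[el]])))
  col <- numeric(nrow_out)
  if (length(atoms) == 0L) {
    if (j + 1L <= nrow_out) col[j + 1L] <- 1
    return(col)
  }
  opts <- lapply(atoms, function(el) {
    d <- isotope_table[[el]]
    which(d > 0) - 1L  # attainable shifts
  })
  grid <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    shifts <- as.integer(grid[r, ])
    prob <- prod(mapply(function(el, s) isotope_table[[el]][s + 1L],
                        atoms, shifts))
    total <- sum(shifts) + j
    if (total + 1L <= nrow_out) col[total + 1L] <- col[total + 1L] + prob
  }
  col
}

# Expected number of labeled carbons, computed directly from the weights.
mean_mass_oracle <- function(m) {
  f <- as.numeric(m)
  sum(f * (seq_along(f) - 1L)) / sum(f)
}

# Random fractional MID over n carbons.
random_mid <- function(n) {
  v <- stats::runif(n + 1L)
  mid(v / sum(v), fractional = TRUE)
}

# Row-wise Welch t-test p-values for two matrices (rows = variables).
# Closed-form Welch formulas, independent of group_compare's t.test path.
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

central_reference <- function() {
  ref <- load_metabolite_reference()
  ref[ref$central_carbon, ]
}
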