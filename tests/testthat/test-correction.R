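iso <- default_isotope_table()

test_that("single-carbon fragment smears only its unlabeled state", {
  f <- elemental_formula(c(C = 1), n_tracer_carbons = 1)
  cm <- build_correction_matrix(f, iso, headroom = 0)
  # unlabeled column: the one tracer carbon still carries natural 13C;
  # labeled column: a fixed +1 shift with nothing left to smear
  expect_equal(cm$M, cbind(c(0.9893, 0.0107), c(0, 1)))
})

test_that("two non-tracer carbons smear by the binomial 13C pattern", {
  f <- elemental_formula(c(C = 2), n_tracer_carbons = 0)
  cm <- build_correction_matrix(f, iso, headroom = 2)
  p13 <- 0.0107
  expect_equal(cm$M[2, 1], 2 * p13 * (1 - p13), tolerance = 1e-12)
  expect_equal(cm$M[2, 1], 0.021171, tolerance = 1e-4)
  expect_equal(cm$M[1, 1], (1 - p13)^2, tolerance = 1e-12)
  expect_equal(cm$M[3, 1], p13^2, tolerance = 1e-12)
})

test_that("matrix columns match exhaustive isotope enumeration (<= 6 atoms)", {
  cases <- list(
    list(counts = c(C = 2, O = 1), n = 1),
    list(counts = c(C = 3, H = 2), n = 2),
    list(counts = c(C = 1, Si = 1), n = 1),
    list(counts = c(C = 3, O = 2, S = 1), n = 3),
    list(counts = c(C = 2, N = 1, O = 1), n = 2)
  )
  for (cs in cases) {
    f <- elemental_formula(cs$counts, n_tracer_carbons = cs$n)
    cm <- build_correction_matrix(f, iso, headroom = 4)
    for (j in 0:cs$n) {
      oracle <- brute_force_column(f$counts, cs$n, j, iso, nrow(cm$M))
      expect_equal(cm$M[, j + 1], oracle, tolerance = 1e-12)
    }
  }
})

test_that("an extra labeled carbon shifts columns by exactly one row", {
  # removing one tracer carbon from the fragment and re-indexing: a fixed
  # labeled carbon contributes a constant +1 and no natural smearing
  m_hi <- build_correction_matrix(
    elemental_formula(parse_formula("C6H12NO3Si"), 3), iso)$M
  m_lo <- build_correction_matrix(
    elemental_formula(parse_formula("C5H12NO3Si"), 2), iso)$M
  for (j in 1:3) {
    expect_equal(m_hi[-1, j + 1], m_lo[seq_len(nrow(m_hi) - 1), j],
                 tolerance = 1e-12)
  }
})

test_that("packaged fragments lose at most 1e-3 column mass at headroom 4", {
  ref <- load_metabolite_reference()
  for (i in seq_len(nrow(ref))) {
    f <- elemental_formula(ref$fragment_formula[i], ref$n_tracer_carbons[i])
    cm <- build_correction_matrix(f, iso, headroom = 4)
    expect_true(all(colSums(cm$M) >= 0.999),
                label = paste("column mass for", ref$metabolite_id[i]))
    expect_true(all(cm$M >= 0 & cm$M <= 1))
    # labels cannot lower mass: zero above the diagonal shift
    for (j in seq_len(ncol(cm$M) - 1)) {
      expect_equal(cm$M[seq_len(j), j + 1], rep(0, j))
    }
  }
})

test_that("NNLS correction inverts the forward convolution", {
  ref <- central_reference()
  set.seed(21)
  for (i in seq_len(nrow(ref))) {
    f <- elemental_formula(ref$fragment_formula[i], ref$n_tracer_carbons[i])
    cm <- build_correction_matrix(f, iso, headroom = 4)
    x <- stats::runif(ncol(cm$M)) * 1000
    raw <- as.numeric(cm$M %*% x)
    rec <- as.numeric(correct_natural_abundance(mid(raw), cm))
    expect_lt(max(abs(rec - x)), 1e-6)
  }
})

test_that("an unlabeled standard corrects to a pure m+0 pattern", {
  f <- elemental_formula("C9H22O3Si2", n_tracer_carbons = 3)  # lactate 2TMS
  cm <- build_correction_matrix(f, iso, headroom = 4)
  raw <- 5e5 * cm$M[, 1]
  out <- correct_natural_abundance(mid(raw), cm, fractional = TRUE)
  expect_equal(as.numeric(out), c(1, 0, 0, 0), tolerance = 1e-8)
})

test_that("pure tracer with no non-tracer atoms stays a spike at m+n", {
  f <- elemental_formula(c(C = 2), n_tracer_carbons = 2)
  cm <- build_correction_matrix(f, iso, headroom = 0)
  out <- correct_natural_abundance(mid(c(0, 0, 7e4)), cm, fractional = TRUE)
  expect_equal(as.numeric(out), c(0, 0, 1), tolerance = 1e-10)
})

test_that("correction rejects bad inputs", {
  f <- elemental_formula("C3H6O3", n_tracer_carbons = 3)
  cm <- build_correction_matrix(f, iso)
  expect_error(correct_natural_abundance(mid(rep(0, 4)), cm),
               "empty measurement")
  expect_error(correct_natural_abundance(mid(rep(1, 20)), cm),
               "dimension mismatch")
  expect_error(
    build_correction_matrix(elemental_formula(c(C = 1, Zz = 2), 1), iso),
    "Zz")
})
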