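# Natural-abundance correction of GC-MS mass isotopologue distributions.
#
# A measured mass-shift pattern is the tracer MID smeared by natural heavy
# isotopes of every atom in the derivatized fragment (13C on unlabeled
# carbons, 29/30Si from TMS groups, 18O, ...). Column j of the correction
# matrix is the predicted measured pattern of a molecule carrying exactly j
# tracer 13C atoms; correction inverts the smearing by non-negative least
# squares.

# Truncated polynomial multiplication of two shift distributions.
conv_trunc <- function(a, b, maxlen) {
  out <- numeric(min(length(a) + length(b) - 1L, maxlen))
  for (i in seq_along(a)) {
    if (i > maxlen) break
    idx <- i + seq_along(b) - 1L
    keep <- idx <= maxlen
    if (!any(keep)) next
    out[idx[keep]] <- out[idx[keep]] + a[i] * b[keep]
  }
  out
}

#' Build a natural-abundance correction matrix
#'
#' Column j (j = 0 ... n tracer carbons) is the convolution of the natural
#' mass-shift distributions of every atom in the fragment except the j
#' labeled tracer carbons, which contribute a fixed shift of +j. Rows run
#' m+0 ... m+(n+headroom): the headroom accommodates natural-isotope shifts
#' beyond m+n (Si-rich TMS fragments need it).
#'
#' @param formula An [elemental_formula()].
#' @param isotope_table Per-element natural mass-shift distributions, as
#'   returned by [default_isotope_table()].
#' @param headroom Extra rows beyond m+n (default 4).
#' @return Object of class `correction_matrix`: list with the
#'   `(n+1+headroom) x (n+1)` matrix `M`, the `formula` and `headroom`.
#' @examples
#' f <- elemental_formula("C6H12NO3Si", n_tracer_carbons = 3)
#' cm <- build_correction_matrix(f)
#' colSums(cm$M)  # each close to 1; deficit is truncation loss
#' @export
build_correction_matrix <- function(formula,
                                    isotope_table = default_isotope_table(),
                                    headroom = 4L) {
  stopifnot(inherits(formula, "elemental_formula"))
  headroom <- as.integer(headroom)
  if (headroom < 0L) stop("headroom must be nonnegative")
  counts <- formula$counts
  absent <- setdiff(names(counts), names(isotope_table))
  if (length(absent)) {
    stop("isotope table has no entry for element(s): ",
         paste(absent, collapse = ", "))
  }
  n <- formula$n_tracer_carbons
  nrow_out <- n + 1L + headroom
  M <- matrix(0, nrow = nrow_out, ncol = n + 1L)
  for (j in 0:n) {
    cts <- counts
    if ("C" %in% names(cts)) cts[["C"]] <- cts[["C"]] - j
    d <- 1
    for (el in names(cts)) {
      for (i in seq_len(cts[[el]])) {
        d <- conv_trunc(d, isotope_table[[el]], nrow_out)
      }
    }
    idx <- seq_along(d) + j
    keep <- idx <= nrow_out
    col <- numeric(nrow_out)
    col[idx[keep]] <- d[keep]
    M[, j + 1L] <- col
  }
  structure(list(M = M, formula = formula, headroom = headroom),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> ", x$formula$formula, ", ",
      ncol(x$M), " tracer columns, headroom ", x$headroom, "\n", sep = "")
  invisible(x)
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves \eqn{\min_x \|Mx - raw\|_2} subject to \eqn{x \ge 0}
#' (Lawson-Hanson non-negative least squares, via [pracma::lsqnonneg()]).
#' NNLS is used instead of matrix inversion so that noisy measurements can
#' never produce negative isotopologues.
#'
#' @param raw Measured pattern: `mid` or numeric vector of length between
#'   n+1 and n+1+headroom (headroom rows of the measurement are used when
#'   present).
#' @param matrix A `correction_matrix` built for the same fragment.
#' @param fractional If `TRUE`, renormalize the corrected MID to sum to 1.
#' @return Corrected `mid` of length n+1.
#' @export
correct_natural_abundance <- function(raw, matrix, fractional = FALSE) {
  stopifnot(inherits(matrix, "correction_matrix"))
  v <- as.numeric(raw)
  if (anyNA(v) || any(v < 0)) stop("raw MID must be nonnegative")
  if (all(v == 0)) stop("empty measurement: all isotopologue abundances are zero")
  M <- matrix$M
  if (length(v) < ncol(M) || length(v) > nrow(M)) {
    stop("dimension mismatch: raw has ", length(v), " rows, matrix expects ",
         ncol(M), " to ", nrow(M))
  }
  Msub <- M[seq_along(v), , drop = FALSE]
  # solve at unit scale (NNLS is scale-equivariant); large raw counts can
  # otherwise trip the solver's convergence test
  s <- sum(v)
  x <- pracma::lsqnonneg(Msub, v / s)$x * s
  x[x < 0] <- 0  # lsqnonneg can return -0 / tiny negatives at convergence
  if (fractional) {
    fractional_enrichment(mid(x, metabolite_id = attr(raw, "metabolite_id")))
  } else {
    mid(x, metabolite_id = attr(raw, "metabolite_id"))
  }
}
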