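#' Mass isotopologue distribution (MID)
#'
#' The pipeline's atomic data structure: abundances of the mass shifts
#' m+0 ... m+n for one metabolite in one sample, where n is the number of
#' tracer carbons. Raw MIDs are in arbitrary ion-count units; fractional
#' MIDs sum to 1.
#'
#' @param abundances Nonnegative numeric vector of length n+1 (m+0 ... m+n).
#' @param metabolite_id Optional metabolite identifier.
#' @param fractional Logical; if `TRUE` the entries must sum to 1 (within
#'   1e-9).
#' @return Numeric vector of class `mid` with attributes `metabolite_id`
#'   and `fractional`.
#' @examples
#' mid(c(0.5, 0.25, 0.25), "pyruvate", fractional = TRUE)
#' @export
mid <- function(abundances, metabolite_id = NA_character_, fractional = FALSE) {
  x <- as.numeric(abundances)
  if (length(x) < 1L || anyNA(x)) stop("MID abundances must be non-missing")
  if (any(x < 0)) stop("MID abundances must be nonnegative")
  if (fractional && abs(sum(x) - 1) > 1e-9) {
    stop("fractional MID must sum to 1 (got ", format(sum(x)), ")")
  }
  structure(x, class = "mid",
            metabolite_id = metabolite_id, fractional = isTRUE(fractional))
}

#' @export
print.mid <- function(x, ...) {
  cat("<mid> ", attr(x, "metabolite_id"),
      if (attr(x, "fractional")) " (fractional)" else " (raw)", "\n", sep = "")
  v <- as.numeric(x)
  names(v) <- paste0("m+", seq_along(v) - 1L)
  print(v, ...)
  invisible(x)
}

#' Number of tracer carbons of a MID
#' @param x A `mid`.
#' @return Integer n (the distribution covers m+0 ... m+n).
#' @export
mid_carbons <- function(x) length(unclass(x)) - 1L

#' Is a MID fractional?
#' @param x A `mid`.
#' @export
is_fractional <- function(x) isTRUE(attr(x, "fractional"))

#' Fractional enrichment
#'
#' Normalizes a raw MID so that each isotopologue is expressed relative to
#' the sum over all isotopologues of the metabolite.
#'
#' @param dist A `mid` or numeric vector with at least one positive entry.
#' @return Fractional `mid` summing to 1.
#' @examples
#' fractional_enrichment(mid(c(50, 25, 25)))
#' @export
fractional_enrichment <- function(dist) {
  v <- as.numeric(dist)
  if (any(v < 0)) stop("MID abundances must be nonnegative")
  s <- sum(v)
  if (s <= 0) stop("empty measurement: all isotopologue abundances are zero")
  mid(v / s, metabolite_id = attr(dist, "metabolite_id"), fractional = TRUE)
}

#' Labeled fraction of a MID
#'
#' The share of molecules carrying any tracer label,
#' \eqn{1 - f_0 = \sum_{i \ge 1} f_i}, computed after normalization.
#'
#' @inheritParams fractional_enrichment
#' @return A number in `[0, 1]`.
#' @export
labeled_fraction <- function(dist) {
  f <- as.numeric(fractional_enrichment(dist))
  min(max(1 - f[1L], 0), 1)
}

#' Convolve two fractional MIDs
#'
#' The MID of a condensation product (e.g. citrate from oxaloacetate +
#' acetyl-CoA) is the convolution of its substrates' MIDs: mass shifts add.
#'
#' @param a,b Fractional `mid`s over n_a and n_b carbons.
#' @return Fractional `mid` over n_a + n_b carbons.
#' @export
convolve_mids <- function(a, b) {
  if (!is_fractional(a) || !is_fractional(b)) {
    stop("convolve_mids requires fractional MIDs")
  }
  va <- as.numeric(a); vb <- as.numeric(b)
  out <- numeric(length(va) + length(vb) - 1L)
  for (i in seq_along(va)) {
    idx <- i + seq_along(vb) - 1L
    out[idx] <- out[idx] + va[i] * vb
  }
  out <- out / sum(out)
  mid(out, fractional = TRUE)
}

#' Remove one carbon from a MID (random-carbon-loss approximation)
#'
#' Models a decarboxylation (e.g. pyruvate -> acetyl-CoA + CO2) on mass
#' isotopologues: one of the n carbons is lost uniformly at random, so
#' \eqn{out_k = f_k (n-k)/n + f_{k+1} (k+1)/n}. Positional information is
#' not tracked; this is an approximation, documented in the methods
#' vignette.
#'
#' @param dist Fractional `mid` over n >= 1 carbons.
#' @return List with `mid` (fractional, over n-1 carbons) and
#'   `lost_label_prob`, the probability \eqn{\sum_k f_k k/n} that the lost
#'   carbon was labeled (feeds the labeled-CO2 pool).
#' @export
decarboxylate <- function(dist) {
  if (!is_fractional(dist)) stop("decarboxylate requires a fractional MID")
  f <- as.numeric(dist)
  n <- length(f) - 1L
  if (n < 1L) stop("cannot decarboxylate a zero-carbon distribution")
  k <- 0:(n - 1L)
  out <- f[k + 1L] * (n - k) / n + f[k + 2L] * (k + 1L) / n
  lost <- sum(f * (0:n)) / n
  list(mid = mid(out / sum(out), fractional = TRUE), lost_label_prob = lost)
}

#' Pad a MID with unlabeled carbons
#'
#' Adds carbons that are certainly unlabeled (e.g. the CO2-derived carbon in
#' the pyruvate-carboxylase product when CO2 is unlabeled): the capacity
#' grows but no mass shifts change.
#'
#' @param dist A `mid`.
#' @param extra Number of unlabeled carbons to add.
#' @return `mid` over n + extra carbons.
#' @export
pad_mid <- function(dist, extra = 1L) {
  extra <- as.integer(extra)
  stopifnot(extra >= 0L)
  mid(c(as.numeric(dist), rep(0, extra)),
      metabolite_id = attr(dist, "metabolite_id"),
      fractional = is_fractional(dist))
}

# Elementwise convex combination of equally-long fractional MIDs.
mix_mids <- function(weights, mids) {
  stopifnot(length(weights) == length(mids), all(weights >= 0))
  len <- unique(vapply(mids, length, integer(1)))
  if (length(len) != 1L) stop("cannot mix MIDs of different carbon counts")
  v <- Reduce(`+`, Map(function(w, m) w * as.numeric(m), weights, mids))
  v <- v / sum(v)
  mid(v, fractional = TRUE)
}

# Mean mass shift of a MID (expected number of labeled carbons).
mean_mass <- function(dist) {
  f <- as.numeric(fractional_enrichment(dist))
  sum(f * (seq_along(f) - 1L))
}
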