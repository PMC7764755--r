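#' Parse a Hill-notation elemental formula
#'
#' Turns a string such as `"C14H33NO3Si2"` into a named integer vector of
#' atom counts. One- and two-letter element symbols are supported; a missing
#' count means 1.
#'
#' @param x A single formula string.
#' @return Named integer vector of atom counts.
#' @examples
#' parse_formula("C14H33NO3Si2")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- trimws(x)
  if (!nzchar(x)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  el <- sub("[0-9]*$", "", tokens)
  ct <- sub("^[A-Za-z]+", "", tokens)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Elemental formula of a derivatized GC-MS fragment
#'
#' Describes the quantified fragment ion of a (typically TMS/MOX-derivatized)
#' metabolite: its atom counts and how many of its carbons belong to the
#' metabolite backbone and can therefore carry tracer \eqn{^{13}}C.
#'
#' @param formula Hill-notation string (e.g. `"C14H33NO3Si2"`) or a named
#'   nonnegative integer vector of atom counts.
#' @param n_tracer_carbons Number of backbone carbons that can carry the
#'   \eqn{^{13}}C label; must satisfy `0 <= n_tracer_carbons <= C`.
#' @return An object of class `elemental_formula`: a list with `counts`,
#'   `n_tracer_carbons` and the original `formula` string.
#' @examples
#' elemental_formula("C6H12NO3Si", n_tracer_carbons = 3)  # pyruvate MOX-1TMS
#' @export
elemental_formula <- function(formula, n_tracer_carbons) {
  if (is.character(formula)) {
    string <- formula
    counts <- parse_formula(formula)
  } else {
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("atom counts must be named by element symbol")
    }
    counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
    string <- paste0(names(counts), ifelse(counts == 1L, "", counts),
                     collapse = "")
  }
  if (any(counts < 0)) stop("atom counts must be nonnegative")
  n_tracer_carbons <- as.integer(n_tracer_carbons)
  stopifnot(length(n_tracer_carbons) == 1L, !is.na(n_tracer_carbons))
  if (n_tracer_carbons < 0) stop("n_tracer_carbons must be nonnegative")
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_tracer_carbons > n_c) {
    stop("n_tracer_carbons (", n_tracer_carbons,
         ") exceeds the carbon count of the fragment (", n_c, ")")
  }
  structure(
    list(counts = counts[counts > 0L],
         n_tracer_carbons = n_tracer_carbons,
         formula = string),
    class = "elemental_formula"
  )
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", x$formula,
      " (", x$n_tracer_carbons, " tracer carbons)\n", sep = "")
  invisible(x)
}
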