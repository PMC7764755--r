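#' Natural isotope mass-shift table
#'
#' Reads the per-element natural-isotope mass-shift probabilities used to
#' build natural-abundance correction matrices. The packaged table
#' (`inst/extdata/isotopes.csv`) carries standard terrestrial abundances
#' (e.g. \eqn{^{13}}C 0.0107, \eqn{^{29}}Si 0.04685, \eqn{^{30}}Si 0.03092);
#' it is an editable physical-constants file, not a fitted quantity.
#'
#' @param path CSV with columns `element`, `mass_shift`, `probability`.
#'   Defaults to the packaged table.
#' @return Named list: element symbol -> numeric vector of probabilities
#'   indexed by mass shift (position 1 = shift 0).
#' @export
read_isotope_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "mass_shift", "probability")
  if (!all(need %in% names(tab))) {
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$probability < 0) || any(tab$probability > 1)) {
    stop("isotope probabilities must lie in [0, 1]")
  }
  out <- lapply(split(tab, tab$element), function(d) {
    v <- numeric(max(d$mass_shift) + 1L)
    v[d$mass_shift + 1L] <- d$probability
    if (abs(sum(v) - 1) > 1e-6) {
      stop("isotope probabilities for element ", d$element[1],
           " do not sum to 1")
    }
    v
  })
  out
}

#' @rdname read_isotope_table
#' @export
default_isotope_table <- function() {
  read_isotope_table(system.file("extdata", "isotopes.csv",
                                 package = "sirmtrace", mustWork = TRUE))
}
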