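# Pathway-distribution analysis and enzyme-activity surrogates.

#' Pathway distribution of 13C enrichment
#'
#' For each pathway, the mean labeled fraction over its metabolites is
#' expressed as a percent of the summed means across all pathways (the
#' per-tissue donut analysis). The mean is the unweighted arithmetic mean
#' over metabolites, not abundance-weighted.
#'
#' @param labeled_fractions Named numeric vector (metabolite -> labeled
#'   fraction) or a tibble/data.frame with columns `metabolite_id` and
#'   `labeled_fraction`.
#' @param map Named character vector metabolite -> pathway, as returned by
#'   [load_pathway_map()].
#' @return Tibble with `pathway`, `mean_labeled_fraction` and `share_pct`;
#'   shares sum to 100.
#' @examples
#' pathway_distribution(c(pyruvate = 0.2, glutamate = 0.6),
#'                      c(pyruvate = "glycolysis",
#'                        glutamate = "neurotransmitters"))
#' @export
pathway_distribution <- function(labeled_fractions, map) {
  if (is.data.frame(labeled_fractions)) {
    lf <- stats::setNames(labeled_fractions$labeled_fraction,
                          labeled_fractions$metabolite_id)
  } else {
    lf <- labeled_fractions
  }
  if (is.null(names(lf))) stop("labeled fractions must be named by metabolite")
  unmapped <- setdiff(names(lf), names(map))
  if (length(unmapped)) {
    stop("metabolite(s) missing from pathway map: ",
         paste(unmapped, collapse = ", "))
  }
  pw <- unname(map[names(lf)])
  means <- tapply(lf, pw, mean)
  total <- sum(means)
  if (total <= 0) stop("no enrichment: every pathway is fully unlabeled")
  tibble::tibble(
    pathway = names(means),
    mean_labeled_fraction = as.numeric(means),
    share_pct = 100 * as.numeric(means) / total
  )
}

#' PDH and PC surrogate enzyme activities
#'
#' Ratios of citrate to pyruvate isotopologues used as surrogates for
#' pyruvate dehydrogenase and pyruvate carboxylase activity:
#' PDH = citrate m+2 / pyruvate m+3 and PC = citrate m+3 / pyruvate m+3.
#' Both MIDs are normalized internally, so the surrogates are invariant to
#' the scale of the raw ion counts.
#'
#' @param citrate,pyruvate `mid`s (raw or fractional) for citrate (>= 3
#'   carbons) and pyruvate (3 carbons).
#' @return Named numeric vector `c(pdh = ..., pc = ...)`.
#' @export
enzyme_surrogates <- function(citrate, pyruvate) {
  cf <- as.numeric(fractional_enrichment(citrate))
  pf <- as.numeric(fractional_enrichment(pyruvate))
  if (length(pf) < 4L || length(cf) < 4L) {
    stop("need at least m+3 for pyruvate and citrate")
  }
  if (pf[4L] <= 0) {
    stop("undefined surrogate: pyruvate m+3 fraction is zero")
  }
  c(pdh = cf[3L] / pf[4L], pc = cf[4L] / pf[4L])
}

#' Group mean and SEM of isotopologue fractions over time
#'
#' Aggregates per-sample fractional MIDs to mean +/- SEM per metabolite,
#' tissue, time point and isotopologue. SEM is reported only for n >= 2;
#' cells absent from the data are omitted with a warning.
#'
#' @param fractions Long table with columns `sample_id`, `tissue`,
#'   `time_min`, `metabolite_id`, `mass_shift`, `frac`.
#' @return Tibble with `tissue`, `metabolite_id`, `time_min`, `mass_shift`,
#'   `n`, `mean_frac`, `sem_frac` (NA when n < 2), ordered by time.
#' @export
timecourse_summary <- function(fractions) {
  need <- c("sample_id", "tissue", "time_min", "metabolite_id",
            "mass_shift", "frac")
  miss <- setdiff(need, names(fractions))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- fractions |>
    dplyr::group_by(.data$tissue, .data$metabolite_id, .data$time_min,
                    .data$mass_shift) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_frac = mean(.data$frac),
      sem_frac = ifelse(dplyr::n() >= 2,
                        stats::sd(.data$frac) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$tissue, .data$metabolite_id, .data$time_min,
                   .data$mass_shift)
  grid <- tidyr::expand_grid(
    tissue = unique(fractions$tissue),
    metabolite_id = unique(fractions$metabolite_id),
    time_min = unique(fractions$time_min)
  )
  have <- dplyr::distinct(out, .data$tissue, .data$metabolite_id,
                          .data$time_min)
  n_missing <- nrow(dplyr::anti_join(
    grid, have, by = c("tissue", "metabolite_id", "time_min")))
  if (n_missing > 0) {
    warning(n_missing, " tissue x metabolite x time cell(s) have no samples",
            " and were omitted")
  }
  out
}
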