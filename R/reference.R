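# Packaged metabolite reference table and pathway map.

#' Load the metabolite reference table
#'
#' The packaged table describes the 80 metabolites of a typical GC-MS
#' central-carbon panel: identifier, backbone tracer-carbon count, the
#' elemental formula of the quantified derivatized fragment, a single
#' pathway assignment, and two flags -- `central_carbon` marks the 15
#' metabolites that receive simulated \eqn{^{13}}C enrichment, and `panel`
#' marks the 13 representative metabolites used by the pathway-distribution
#' donut analysis. The study does not state which fragment ion was
#' quantified per metabolite, so the packaged fragment formulas are
#' documented assumptions (TMS/MOX derivatives), editable via a user table.
#'
#' @param path CSV with columns `metabolite_id`, `n_tracer_carbons`,
#'   `fragment_formula`, `pathway`, `central_carbon`, `panel`. Defaults to
#'   the packaged table.
#' @return Tibble, one row per metabolite.
#' @export
load_metabolite_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_reference.csv",
                        package = "sirmtrace", mustWork = TRUE)
  }
  ref <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("metabolite_id", "n_tracer_carbons", "fragment_formula", "pathway")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("reference table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ref$metabolite_id)) {
    stop("duplicated metabolite_id in reference table")
  }
  bad <- setdiff(unique(ref$pathway), PATHWAYS)
  if (length(bad)) {
    stop("unknown pathway label(s): ", paste(bad, collapse = ", "))
  }
  ref
}

PATHWAYS <- c("glycolysis", "TCA", "amino_acids", "neurotransmitters", "other")

#' Load a pathway map
#'
#' Maps each metabolite to exactly one pathway of
#' \{glycolysis, TCA, amino_acids, neurotransmitters, other\}. The packaged
#' map assigns glutamate, aspartate, GABA and pyroglutamate to the
#' neurotransmitter pathway.
#'
#' @param reference A metabolite reference tibble
#'   (default: [load_metabolite_reference()]), or a CSV path with columns
#'   `metabolite_id` and `pathway`.
#' @return Named character vector: metabolite_id -> pathway.
#' @export
load_pathway_map <- function(reference = load_metabolite_reference()) {
  if (is.character(reference)) {
    reference <- tibble::as_tibble(
      utils::read.csv(reference, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("metabolite_id", "pathway") %in% names(reference)))
  stats::setNames(reference$pathway, reference$metabolite_id)
}

#' Representative metabolite panel for the donut analysis
#'
#' The packaged panel behind the per-tissue pathway-distribution donuts:
#' glycolysis (GAP/3PG, pyruvate, lactate, alanine), TCA (citrate,
#' fumarate, malate), amino acids (serine, glycine) and neurotransmitters
#' (glutamate, aspartate, GABA, pyroglutamate).
#'
#' @param reference A metabolite reference tibble.
#' @return Tibble with `metabolite_id` and `pathway` for the 13 panel
#'   metabolites.
#' @export
representative_panel <- function(reference = load_metabolite_reference()) {
  stopifnot("panel" %in% names(reference))
  dplyr::select(dplyr::filter(reference, .data$panel),
                "metabolite_id", "pathway")
}
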