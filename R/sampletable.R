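# Emission of raw GC-MS-like sample tables from the pool simulator, and
# the correction/enrichment stages that read them back.

#' Generate a raw GC-MS-like sample table
#'
#' For each sample in the design, pool MIDs at the sample's harvest time
#' are forward-convolved with each metabolite's natural-abundance
#' correction matrix (so natural isotopes are ON in the raw data), scaled
#' by a per-metabolite base abundance and a per-sample recovery factor, and
#' degraded with multiplicative log-normal noise of coefficient of
#' variation `noise_cv`. Metabolites outside the simulated central-carbon
#' subset are emitted unlabeled. Deterministic given `params$seed`.
#'
#' @param params A `sirm_params` object.
#' @param design Data frame with columns `tissue`, `time_min`, `n`
#'   (replicates) and optionally `group` (default `"WT"`).
#' @param reference Metabolite reference table
#'   ([load_metabolite_reference()]).
#' @param isotope_table Natural-isotope table ([default_isotope_table()]).
#' @param headroom Extra mass-shift rows emitted beyond m+n (default 4).
#' @param group_effects Optional named list: group label -> named numeric
#'   vector of log2 fold changes applied to that group's metabolite base
#'   abundances (simulates pool-size differences between e.g. disease model
#'   and control).
#' @return Long tibble: `sample_id`, `tissue`, `time_min`, `group`,
#'   `metabolite_id`, `mass_shift`, `raw_abundance`, `norvaline`,
#'   `protein_mg`.
#' @export
generate_sample_table <- function(params, design,
                                  reference = load_metabolite_reference(),
                                  isotope_table = default_isotope_table(),
                                  headroom = 4L,
                                  group_effects = NULL) {
  stopifnot(inherits(params, "sirm_params"))
  need <- c("tissue", "time_min", "n")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"group" %in% names(design)) design$group <- "WT"
  bad <- setdiff(unique(design$tissue), names(params$lambda))
  if (length(bad)) stop("unknown tissue: ", paste(bad, collapse = ", "))
  if (any(design$time_min < 0)) stop("unknown time: times must be >= 0")

  set.seed(params$seed)
  mets <- reference$metabolite_id
  base_abundance <- stats::setNames(
    stats::rlnorm(length(mets), meanlog = log(1e6), sdlog = 1), mets)
  matrices <- lapply(seq_along(mets), function(i) {
    f <- elemental_formula(reference$fragment_formula[i],
                           reference$n_tracer_carbons[i])
    build_correction_matrix(f, isotope_table, headroom = headroom)
  })
  names(matrices) <- mets

  sims <- lapply(unique(design$tissue), function(tis) {
    simulate_pools(params, tis,
                   times = unique(design$time_min[design$tissue == tis]))
  })
  names(sims) <- unique(design$tissue)

  sdlog <- sqrt(log(1 + params$noise_cv^2))
  rows <- list()
  sample_counter <- 0L
  for (r in seq_len(nrow(design))) {
    tis <- design$tissue[r]
    t <- design$time_min[r]
    grp <- design$group[r]
    effects <- if (!is.null(group_effects)) group_effects[[grp]]
    for (i in seq_len(design$n[r])) {
      sample_counter <- sample_counter + 1L
      sid <- sprintf("S%03d_%s_%gmin_%s", sample_counter, tis, t, grp)
      recovery <- stats::rlnorm(1, 0, 0.1)
      norvaline <- 1e5 * recovery *
        (if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
      protein <- stats::rlnorm(1, log(2), 0.1)
      met_rows <- lapply(mets, function(m) {
        central <- reference$central_carbon[match(m, mets)]
        frac <- if (isTRUE(central)) {
          pool_mid(sims[[tis]], m, t)
        } else {
          n <- reference$n_tracer_carbons[match(m, mets)]
          mid(c(1, rep(0, n)), fractional = TRUE)
        }
        measured <- as.numeric(matrices[[m]]$M %*% as.numeric(frac))
        scale_fc <- if (!is.null(effects) && m %in% names(effects)) {
          2^effects[[m]]
        } else 1
        counts <- measured * base_abundance[[m]] * recovery * protein *
          scale_fc
        if (sdlog > 0) {
          counts <- counts *
            stats::rlnorm(length(counts), -sdlog^2 / 2, sdlog)
        }
        tibble::tibble(
          sample_id = sid, tissue = tis, time_min = t, group = grp,
          metabolite_id = m, mass_shift = seq_along(counts) - 1L,
          raw_abundance = counts, norvaline = norvaline,
          protein_mg = protein
        )
      })
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(met_rows)
    }
  }
  dplyr::bind_rows(rows)
}

#' Natural-abundance-correct a raw sample table
#'
#' Applies [correct_natural_abundance()] to every sample x metabolite MID
#' of a long raw table and appends fractional enrichments.
#'
#' @param raw Long raw table as produced by [generate_sample_table()] or
#'   [read_sample_table()].
#' @inheritParams generate_sample_table
#' @return Long tibble with `mass_shift` 0 ... n per metabolite,
#'   `corrected_abundance` and `frac` (fractional enrichment), plus the
#'   sample metadata columns.
#' @export
correct_sample_table <- function(raw,
                                 reference = load_metabolite_reference(),
                                 isotope_table = default_isotope_table()) {
  unknown <- setdiff(unique(raw$metabolite_id), reference$metabolite_id)
  if (length(unknown)) {
    stop("metabolite(s) absent from reference table: ",
         paste(unknown, collapse = ", "))
  }
  headroom_by_met <- raw |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::summarise(max_shift = max(.data$mass_shift), .groups = "drop")
  matrices <- new.env(parent = emptyenv())
  get_matrix <- function(m) {
    if (!is.null(matrices[[m]])) return(matrices[[m]])
    i <- match(m, reference$metabolite_id)
    hr <- headroom_by_met$max_shift[match(m, headroom_by_met$metabolite_id)] -
      reference$n_tracer_carbons[i]
    if (hr < 0) stop("raw table for ", m, " has fewer rows than m+n")
    f <- elemental_formula(reference$fragment_formula[i],
                           reference$n_tracer_carbons[i])
    matrices[[m]] <- build_correction_matrix(f, isotope_table, headroom = hr)
    matrices[[m]]
  }
  meta_cols <- intersect(
    c("sample_id", "tissue", "time_min", "group", "metabolite_id",
      "norvaline", "protein_mg"), names(raw))
  raw |>
    dplyr::arrange(.data$sample_id, .data$metabolite_id, .data$mass_shift) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::reframe({
      cm <- get_matrix(.data$metabolite_id[1])
      x <- correct_natural_abundance(.data$raw_abundance, cm)
      v <- as.numeric(x)
      tibble::tibble(mass_shift = seq_along(v) - 1L,
                     corrected_abundance = v,
                     frac = v / sum(v))
    })
}

#' Per-sample labeled fractions
#'
#' Collapses a corrected table to the labeled fraction
#' (1 - m+0 fraction) per sample and metabolite.
#'
#' @param corrected Output of [correct_sample_table()].
#' @return Tibble with sample metadata, `metabolite_id`,
#'   `labeled_fraction`.
#' @export
enrichment_table <- function(corrected) {
  meta_cols <- intersect(c("sample_id", "tissue", "time_min", "group"),
                         names(corrected))
  corrected |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(meta_cols, "metabolite_id")))) |>
    dplyr::summarise(
      labeled_fraction = 1 - .data$frac[.data$mass_shift == 0L],
      .groups = "drop"
    )
}
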