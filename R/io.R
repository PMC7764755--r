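# Readers, writers and the end-to-end pipeline driver.

SAMPLE_TABLE_COLS <- c("sample_id", "tissue", "time_min", "group",
                       "metabolite_id", "mass_shift", "raw_abundance",
                       "norvaline", "protein_mg")

#' Read a long-format raw sample table
#'
#' Validates the interchange CSV: required columns, numeric abundances, no
#' duplicated (sample, metabolite, shift) rows, contiguous mass shifts
#' 0 ... max per sample x metabolite, and (when a reference is supplied)
#' known metabolites. Lines starting with `#` are treated as comments.
#'
#' @param path CSV path.
#' @param reference Optional metabolite reference table used to reject
#'   unknown metabolites.
#' @return Validated tibble.
#' @export
read_sample_table <- function(path, reference = NULL) {
  tab <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                           stringsAsFactors = FALSE))
  miss <- setdiff(SAMPLE_TABLE_COLS, names(tab))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("time_min", "mass_shift", "raw_abundance", "norvaline",
                "protein_mg")) {
    if (!is.numeric(tab[[col]])) stop("non-numeric values in column ", col)
  }
  key <- paste(tab$sample_id, tab$metabolite_id, tab$mass_shift, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicated row(s) for key (sample_id, metabolite_id, mass_shift): ",
         key[duplicated(key)][1])
  }
  contiguous <- tab |>
    dplyr::group_by(.data$sample_id, .data$metabolite_id) |>
    dplyr::summarise(
      ok = identical(sort(.data$mass_shift), 0:max(.data$mass_shift)),
      .groups = "drop"
    )
  if (!all(contiguous$ok)) {
    bad <- contiguous[!contiguous$ok, ]
    stop("non-contiguous mass shifts for ", bad$sample_id[1], " / ",
         bad$metabolite_id[1])
  }
  if (!is.null(reference)) {
    unknown <- setdiff(unique(tab$metabolite_id), reference$metabolite_id)
    if (length(unknown)) {
      stop("unknown metabolite(s) not in reference table: ",
           paste(unknown, collapse = ", "))
    }
  }
  tab
}

#' Write a sample table (or any tibble) as CSV
#'
#' @param tab Data frame.
#' @param path Output path.
#' @param header Optional comment lines (written with a `#` prefix; they
#'   carry the run's seed and config hash in pipeline outputs).
#' @export
write_sample_table <- function(tab, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full SIRM analysis pipeline
#'
#' Chains the workflow stages: simulate (or read) raw GC-MS tables,
#' natural-abundance correction, fractional enrichment, per-tissue pathway
#' distribution, PDH/PC surrogates, and (when two groups are present)
#' normalized pool statistics with two-stage BKY FDR and PCA. All outputs
#' carry the seed and a config hash in their header; a `manifest.json`
#' records them. Deterministic given the config.
#'
#' @param config A list or YAML file path. Fields: `out_dir` (required);
#'   `design` (data frame or CSV path with tissue, time_min, n, group;
#'   default: the packaged study design, 4 harvest times x 3 tissues x
#'   `n_per_group`); `params` (list of [sirm_params()] overrides);
#'   `input` (optional raw-table CSV; replaces simulation);
#'   `pathway_map` (`NA` to skip the pathway stage); `reference_group` and
#'   `q` for the statistics stage; `group_effects` passed to the simulator.
#' @return Invisible list with the stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(field) config[[field]]  # exact match, no partial matching
  if (is.null(cfg("out_dir"))) stop("config$out_dir is required")
  params <- do.call(sirm_params, as.list(cfg("params")))
  reference <- if (is.null(cfg("reference"))) {
    load_metabolite_reference()
  } else load_metabolite_reference(cfg("reference"))

  design <- cfg("design")
  if (is.null(design)) {
    design <- expand.grid(tissue = c("plasma", "liver", "brain"),
                          time_min = c(15, 30, 120, 240),
                          stringsAsFactors = FALSE)
    design$n <- params$n_per_group
    design$group <- "WT"
  } else if (is.character(design)) {
    design <- utils::read.csv(design, stringsAsFactors = FALSE)
  }

  dir.create(cfg("out_dir"), recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(list(params = unclass(params), design = design,
                               input = cfg("input"),
                               group_effects = cfg("group_effects")))
  hdr <- sprintf("sirmtrace %s seed=%d config=%s",
                 as.character(utils::packageVersion("sirmtrace")),
                 params$seed, cfg_hash)
  out <- function(name) file.path(cfg("out_dir"), name)
  files <- character(0)
  emit <- function(tab, name) {
    write_sample_table(tab, out(name), header = hdr)
    files <<- c(files, name)
  }

  stage <- "simulate"
  res <- list()
  tryCatch({
    raw <- if (!is.null(cfg("input"))) {
      stage <- "read"
      read_sample_table(cfg("input"), reference)
    } else {
      generate_sample_table(params, design, reference,
                            group_effects = cfg("group_effects"))
    }
    emit(raw, "raw_sample_table.csv")

    stage <- "correct"
    corrected <- correct_sample_table(raw, reference)
    emit(corrected, "corrected_mids.csv")

    stage <- "enrich"
    enriched <- enrichment_table(corrected)
    emit(enriched, "labeled_fractions.csv")
    res$enrichment <- enriched

    stage <- "pathways"
    skip_pathways <- !is.null(cfg("pathway_map")) &&
      is.na(cfg("pathway_map")[1])
    if (skip_pathways) {
      warning("no pathway map supplied: pathway-distribution stage skipped")
    } else {
      map <- if (is.null(cfg("pathway_map"))) {
        load_pathway_map(reference)
      } else load_pathway_map(cfg("pathway_map"))
      panel <- representative_panel(reference)
      shares <- enriched |>
        dplyr::filter(.data$metabolite_id %in% panel$metabolite_id) |>
        dplyr::group_by(.data$tissue, .data$time_min, .data$group,
                        .data$sample_id) |>
        dplyr::reframe(pathway_distribution(
          stats::setNames(.data$labeled_fraction, .data$metabolite_id),
          map)) |>
        dplyr::group_by(.data$tissue, .data$time_min, .data$group,
                        .data$pathway) |>
        dplyr::summarise(share_pct = mean(.data$share_pct),
                         .groups = "drop")
      emit(shares, "pathway_shares.csv")
      res$pathway_shares <- shares
    }

    stage <- "surrogates"
    surrogates <- corrected |>
      dplyr::filter(.data$metabolite_id %in% c("citrate", "pyruvate")) |>
      dplyr::group_by(.data$tissue, .data$time_min, .data$group,
                      .data$sample_id) |>
      dplyr::reframe({
        # a sample whose corrected pyruvate m+3 is exactly zero (late time
        # points under noise) has no defined surrogate; drop it from the mean
        s <- tryCatch(
          enzyme_surrogates(
            .data$frac[.data$metabolite_id == "citrate"],
            .data$frac[.data$metabolite_id == "pyruvate"]),
          error = function(e) c(pdh = NA_real_, pc = NA_real_))
        tibble::tibble(pdh = s[["pdh"]], pc = s[["pc"]])
      }) |>
      dplyr::group_by(.data$tissue, .data$time_min, .data$group) |>
      dplyr::summarise(pdh = mean(.data$pdh, na.rm = TRUE),
                       pc = mean(.data$pc, na.rm = TRUE),
                       .groups = "drop")
    emit(surrogates, "enzyme_surrogates.csv")
    res$surrogates <- surrogates

    stage <- "stats"
    if (length(unique(raw$group)) == 2L) {
      pools <- normalize_pools(corrected)
      pools <- iqr_filter(pools, cfg("drop_fraction") %||% 0.1)
      tests <- group_compare(
        pools,
        reference = cfg("reference_group") %||% unique(raw$group)[1],
        Q = cfg("q") %||% 0.01)
      emit(tests, "pool_stats.csv")
      res$pool_stats <- tests
      scaled <- autoscale(pools)
      pca <- pca_scores(scaled, k = 2)
      scores <- tibble::tibble(sample_id = rownames(scaled),
                               group = pools$samples$group,
                               pc1 = pca$scores[, 1], pc2 = pca$scores[, 2])
      emit(scores, "pca_scores.csv")
      res$pca <- pca
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(package = "sirmtrace",
                   version = as.character(utils::packageVersion("sirmtrace")),
                   seed = params$seed, config_hash = cfg_hash,
                   files = files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
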