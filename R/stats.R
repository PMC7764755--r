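# Non-tracer pool-size statistics: normalization, IQR filtering,
# auto-scaling, Welch tests with two-stage BKY FDR, and PCA.

#' Normalize metabolite pools to internal standard and protein
#'
#' Total pool size per sample x metabolite is the sum over isotopologues of
#' the (corrected) ion counts, divided by the sample's L-norvaline internal
#' standard abundance (recovery correction) and by its protein mass (input
#' correction).
#'
#' @param tab Long sample table with columns `sample_id`, `metabolite_id`,
#'   `norvaline`, `protein_mg`, and an abundance column.
#' @param value_col Abundance column to sum; defaults to
#'   `corrected_abundance` when present, else `raw_abundance`.
#' @return Object of class `pool_table`: list with `values` (samples x
#'   metabolites matrix) and `samples` (tibble of per-sample metadata:
#'   `sample_id` plus any of `tissue`, `time_min`, `group`).
#' @export
normalize_pools <- function(tab, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- if ("corrected_abundance" %in% names(tab)) {
      "corrected_abundance"
    } else "raw_abundance"
  }
  need <- c("sample_id", "metabolite_id", "norvaline", "protein_mg", value_col)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  per_sample <- dplyr::distinct(tab, .data$sample_id, .data$norvaline,
                                .data$protein_mg)
  bad <- per_sample$sample_id[per_sample$norvaline <= 0 |
                                per_sample$protein_mg <= 0]
  if (length(bad)) {
    stop("nonpositive norvaline or protein for sample(s): ",
         paste(bad, collapse = ", "))
  }
  totals <- tab |>
    dplyr::group_by(.data$sample_id, .data$metabolite_id) |>
    dplyr::summarise(
      value = sum(.data[[value_col]]) /
        (.data$norvaline[1] * .data$protein_mg[1]),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(totals, names_from = "metabolite_id",
                             values_from = "value")
  meta_cols <- intersect(c("sample_id", "tissue", "time_min", "group"),
                         names(tab))
  samples <- dplyr::distinct(tab[, meta_cols, drop = FALSE])
  samples <- samples[match(wide$sample_id, samples$sample_id), , drop = FALSE]
  values <- as.matrix(wide[, -1, drop = FALSE])
  rownames(values) <- wide$sample_id
  structure(list(values = values, samples = tibble::as_tibble(samples)),
            class = "pool_table")
}

#' @export
print.pool_table <- function(x, ...) {
  cat("<pool_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites\n", sep = "")
  invisible(x)
}

#' Drop low-variability metabolites by interquartile range
#'
#' Metabolites are ranked by IQR across samples and the lowest
#' `drop_fraction` removed (ties broken by metabolite id, lexicographic).
#'
#' @param x A `pool_table` or samples x metabolites matrix.
#' @param drop_fraction Fraction of metabolites to drop, in `[0, 1)`.
#' @return Same class as the input, with the dropped columns removed.
#' @export
iqr_filter <- function(x, drop_fraction = 0.1) {
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must lie in [0, 1)")
  }
  values <- if (inherits(x, "pool_table")) x$values else x
  m <- ncol(values)
  n_drop <- floor(m * drop_fraction + 1e-9)
  if (n_drop > 0) {
    iqrs <- apply(values, 2, stats::IQR)
    ord <- order(iqrs, colnames(values))
    keep <- sort(ord[-seq_len(n_drop)])
    values <- values[, keep, drop = FALSE]
  }
  if (inherits(x, "pool_table")) {
    structure(list(values = values, samples = x$samples),
              class = "pool_table")
  } else {
    values
  }
}

#' Auto-scale a metabolite matrix
#'
#' Mean-centers each metabolite and divides by its standard deviation, so
#' every column has mean 0 and sd 1. Idempotent. Columns with zero sd are
#' an error (they should have been filtered).
#'
#' @param x A `pool_table` or samples x metabolites matrix.
#' @param log_transform Apply `log(x + 1)` before scaling (off by default).
#' @return Numeric matrix of scaled values.
#' @export
autoscale <- function(x, log_transform = FALSE) {
  values <- if (inherits(x, "pool_table")) x$values else as.matrix(x)
  if (log_transform) values <- log1p(values)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance metabolite(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  }
  out <- scale(values)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive linear step-up control of the false discovery rate. Stage 1
#' runs the BH step-up at q' = Q/(1+Q), giving r1 rejections; if
#' 0 < r1 < m, stage 2 reruns BH at level q' m/(m - r1), using m - r1 as
#' the estimate of the number of true nulls. Never less powerful than
#' plain BH at Q.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param Q Target FDR (default 0.01, i.e. Q = 1\%).
#' @return Logical rejection flags, in the input order.
#' @examples
#' two_stage_bky(c(0.001, 0.01, 0.02, 0.8), Q = 0.05)  # 3 discoveries
#' @export
two_stage_bky <- function(pvalues, Q = 0.01) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (Q <= 0 || Q >= 1) stop("Q must lie in (0, 1)")
  m <- length(pvalues)
  if (m == 0L) return(logical(0))
  q1 <- Q / (1 + Q)
  adj <- stats::p.adjust(pvalues, method = "BH")
  r1 <- sum(adj <= q1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  adj <= q1 * m / (m - r1)
}

#' Two-group comparison with two-stage FDR
#'
#' Welch (unequal-variance by default) two-sided t-test per variable
#' between two groups, with discoveries flagged by [two_stage_bky()] at
#' level `Q`. For pool-size data a log2 fold change (non-reference over
#' reference group) is reported; set `log2fc = FALSE` for isotopologue
#' fractions. The `log2fc` and `neg_log10_p` columns are the volcano-plot
#' inputs.
#'
#' @param x A `pool_table`, or a samples x variables matrix (then `groups`
#'   is required).
#' @param reference Reference group label (fold changes are other/reference).
#' @param groups Group label per row of `x` (taken from the sample metadata
#'   for a `pool_table`).
#' @param Q Target FDR for [two_stage_bky()] (default 0.01).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param log2fc Report log2 fold changes of group means.
#' @return Tibble with one row per variable: group means, `mean_diff`,
#'   `log2fc`, `t`, `p`, `neg_log10_p`, `discovery`.
#' @export
group_compare <- function(x, reference, groups = NULL, Q = 0.01,
                          var_equal = FALSE, log2fc = TRUE) {
  if (inherits(x, "pool_table")) {
    groups <- x$samples$group
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(groups)) stop("groups must be supplied")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (!reference %in% lev) stop("reference group not found: ", reference)
  other <- setdiff(lev, reference)
  a <- x[groups == reference, , drop = FALSE]
  b <- x[groups == other, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  res <- lapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0 &&
        mean(a[, j]) == mean(b[, j])) {
      # identical constant groups: no evidence against the null
      return(c(t = 0, p = 1))
    }
    tt <- stats::t.test(b[, j], a[, j], var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  mean_a <- colMeans(a)
  mean_b <- colMeans(b)
  mean_a <- unname(mean_a); mean_b <- unname(mean_b)
  out <- tibble::tibble(
    variable = colnames(x) %||% as.character(seq_len(ncol(x))),
    mean_ref = mean_a,
    mean_alt = mean_b,
    mean_diff = mean_b - mean_a,
    t = res[, "t"],
    p = res[, "p"],
    neg_log10_p = -log10(res[, "p"]),
    discovery = two_stage_bky(res[, "p"], Q = Q)
  )
  if (log2fc) {
    lfc <- rep(NA_real_, length(mean_a))
    ok <- mean_a > 0 & mean_b > 0
    lfc[ok] <- log2(mean_b[ok] / mean_a[ok])
    out$log2fc <- lfc
    out <- dplyr::relocate(out, "log2fc", .after = "mean_diff")
  }
  attr(out, "reference") <- reference
  attr(out, "comparison") <- other
  out
}

#' Principal component scores of a scaled metabolite matrix
#'
#' Thin wrapper over the singular value decomposition ([stats::prcomp()])
#' with a fixed sign convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param x Samples x metabolites matrix (typically [autoscale()] output).
#' @param k Number of components, `1 <= k <= min(dim(x))`.
#' @return List with `scores` (n x k), `explained_variance` (fractions for
#'   all components, summing to <= 1) and `rotation`.
#' @export
pca_scores <- function(x, k = 2L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(x))) stop("invalid number of components k")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (i in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, i]))
    if (pr$rotation[j, i] < 0) {
      pr$rotation[, i] <- -pr$rotation[, i]
      pr$x[, i] <- -pr$x[, i]
    }
  }
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       explained_variance = ev,
       rotation = pr$rotation)
}
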