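# Internal helpers for the samples-x-ions representation: a tibble with a
# sample_id column followed by one numeric column per ion, linear scale.

ion_columns <- function(intensities) {
  setdiff(names(intensities), "sample_id")
}

check_matrix_meta <- function(intensities, meta) {
  if (!"sample_id" %in% names(intensities) || !"sample_id" %in% names(meta)) {
    stop_pt("Both tables need a `sample_id` column.", "peroxitools_bad_input")
  }
  if (!setequal(intensities$sample_id, meta$sample_id)) {
    stop_pt("`intensities` and `meta` cover different samples.",
            "peroxitools_bad_input")
  }
  ions <- ion_columns(intensities)
  if (any(vapply(intensities[ions], function(x) any(x < 0), logical(1)))) {
    stop_pt("Negative intensities are not allowed.", "peroxitools_bad_input")
  }
  invisible(ions)
}

#' Discard OD600 and total-ion-current outlier samples
#'
#' Flags samples whose OD600 at harvest or total ion current deviates from
#' the batch median by more than `k_mad` median absolute deviations
#' (computed per condition batch) and removes them before normalization.
#' Total ion current is screened on the log scale, since instrument-level
#' failures (missed injections, double loads) are multiplicative; when the
#' injection order is known, log TIC is first detrended by a running median
#' over injection order so that the ordinary acquisition drift does not
#' inflate the MAD and gross failures stand out against injection-level
#' noise. `k_mad = Inf` disables filtering.
#'
#' @param intensities Samples-x-ions tibble (`sample_id` + ion columns).
#' @param meta Sample metadata with `sample_id`, `condition`, `od600`;
#'   `total_ion_current` is taken from `meta` when present, otherwise
#'   computed as the row sum of `intensities`.
#' @param k_mad MAD multiplier (default 3).
#' @return List with filtered `intensities`, `meta`, and `discarded`
#'   (tibble: `sample_id`, `reason` in `"od600"`/`"tic"`). Errors if every
#'   sample would be discarded.
#' @export
filter_outliers <- function(intensities, meta, k_mad = 3) {
  check_matrix_meta(intensities, meta)
  if (!"total_ion_current" %in% names(meta)) {
    tic <- rowSums(intensities[ion_columns(intensities)])
    meta$total_ion_current <-
      tic[match(meta$sample_id, intensities$sample_id)]
  }
  if (!"condition" %in% names(meta)) meta$condition <- "all"
  batches <- split(meta, meta$condition)
  if (any(vapply(batches, nrow, integer(1)) < 5)) {
    stop_pt("Need >= 5 samples per condition batch for outlier screening.",
            "peroxitools_bad_input")
  }
  flag <- function(x) {
    m <- mad(x)
    if (!is.finite(m) || m == 0) rep(FALSE, length(x))
    else abs(x - median(x)) > k_mad * m
  }
  # log TIC minus its injection-order running median (robust to isolated
  # failures); with no injection order, the absolute log TIC
  tic_metric <- function(b) {
    lt <- log2(pmax(b$total_ion_current, .Machine$double.xmin))
    if (!"injection_index" %in% names(b) || nrow(b) < 9) return(lt)
    ord <- order(b$injection_index)
    k <- min(11L, nrow(b) - (1 - nrow(b) %% 2))  # odd, <= n
    trend <- numeric(nrow(b))
    trend[ord] <- stats::runmed(lt[ord], k)
    lt - trend
  }
  discarded <- purrr::map_dfr(batches, function(b) {
    od_bad <- flag(b$od600)
    tic_bad <- flag(tic_metric(b))
    tibble(sample_id = b$sample_id[od_bad | tic_bad],
           reason = ifelse(od_bad[od_bad | tic_bad], "od600", "tic"))
  })
  if (nrow(discarded) >= nrow(meta)) {
    stop_pt("Outlier screening would discard every sample.",
            "peroxitools_all_discarded")
  }
  keep <- !(meta$sample_id %in% discarded$sample_id)
  list(
    intensities = dplyr::filter(intensities,
                                .data$sample_id %in% meta$sample_id[keep]),
    meta = meta[keep, , drop = FALSE],
    discarded = discarded
  )
}

#' LOWESS correction of injection-order intensity drift
#'
#' Flow-injection runs accumulate a slow temporal drift in ion intensity.
#' For each ion, a locally weighted regression (LOWESS, one robustifying
#' iteration) of log2 intensity on injection index is fitted; the fitted
#' trend is subtracted and the ion's pre-correction median added back, so
#' corrected intensities stay on the original scale and strictly positive.
#'
#' @param intensities Samples-x-ions tibble.
#' @param meta Metadata with `sample_id` and `injection_index`.
#' @param span LOWESS smoother span (fraction of points; default 0.3). When
#'   the run is too small for the span to cover at least four points it is
#'   widened with a warning.
#' @return Corrected intensities tibble (same shape, linear scale).
#' @export
lowess_drift_correct <- function(intensities, meta, span = 0.3) {
  ions <- check_matrix_meta(intensities, meta)
  if (!"injection_index" %in% names(meta)) {
    stop_pt("`meta` needs an `injection_index` column.",
            "peroxitools_bad_input")
  }
  idx <- meta$injection_index[match(intensities$sample_id, meta$sample_id)]
  n <- length(idx)
  f <- span
  if (floor(f * n) < 4) {
    f <- min(1, 4 / n)
    warn(sprintf("Too few samples for span %.2f; widened to %.2f.", span, f))
  }
  out <- intensities
  for (ion in ions) {
    y <- log2(pmax(out[[ion]], .Machine$double.xmin))
    lo <- lowess(idx, y, f = f, iter = 1)
    fitted <- approx(lo$x, lo$y, xout = idx, rule = 2, ties = mean)$y
    out[[ion]] <- 2^(y - fitted + median(y))
  }
  out
}

#' Linear correction of OD600 effects on ion intensity
#'
#' Culture density at harvest leaves a systematic intensity component. For
#' each ion, log2 intensity is regressed linearly on OD600 and every sample
#' is mapped to the value predicted at the reference density plus its own
#' residual, removing the OD dependence while preserving sample-specific
#' signal. Constant OD600 across samples leaves the data unchanged with a
#' warning.
#'
#' When this stage runs after [lowess_drift_correct()], the share of the OD
#' signal that is smooth in injection order has already been absorbed by
#' the drift smoother; regressing on raw OD600 would then subtract it a
#' second time. Setting `detrend_span` applies the same smoother to the
#' OD600 covariate over injection order and regresses on the detrended
#' remainder, so the two corrections partition the signal instead of
#' double-counting it (the pipeline wrapper does this automatically).
#'
#' @param intensities Samples-x-ions tibble.
#' @param meta Metadata with `sample_id` and `od600`.
#' @param reference_od Reference density the samples are mapped to (default
#'   1.5, the target harvest OD600).
#' @param detrend_span `NULL` (regress on raw OD600) or the LOWESS span used
#'   by the preceding drift correction (requires `injection_index` in
#'   `meta`).
#' @return Corrected intensities tibble (linear scale).
#' @export
od_correct <- function(intensities, meta, reference_od = 1.5,
                       detrend_span = NULL) {
  ions <- check_matrix_meta(intensities, meta)
  od <- meta$od600[match(intensities$sample_id, meta$sample_id)]
  if (sd(od) == 0) {
    warn("OD600 is constant across samples; no correction applied.")
    return(intensities)
  }
  covariate <- od - mean(od)
  if (!is.null(detrend_span)) {
    if (!"injection_index" %in% names(meta)) {
      stop_pt("OD detrending needs `injection_index` in `meta`.",
              "peroxitools_bad_input")
    }
    idx <- meta$injection_index[match(intensities$sample_id,
                                      meta$sample_id)]
    f <- max(detrend_span, min(1, 4 / length(idx)))
    lo <- lowess(idx, od, f = f, iter = 1)
    od_smooth <- approx(lo$x, lo$y, xout = idx, rule = 2, ties = mean)$y
    covariate <- od - od_smooth
    if (sd(covariate) == 0) {
      warn("OD600 has no variation beyond its injection-order trend; no correction applied.")
      return(intensities)
    }
  }
  shift <- reference_od - mean(od)
  out <- intensities
  for (ion in ions) {
    y <- log2(pmax(out[[ion]], .Machine$double.xmin))
    fit <- lm(y ~ covariate)
    corrected <- unname(resid(fit) + coef(fit)[1] + coef(fit)[2] * shift)
    out[[ion]] <- 2^corrected
  }
  out
}

#' Strain-averaged, z-scored metabolome profiles
#'
#' Averages replicate samples per strain on the log2 scale, then z-scores
#' each ion across strains (per-ion mean 0, SD 1). Averaging precedes
#' z-scoring by default; `z_score_first = TRUE` z-scores across samples
#' before averaging, for comparison. Ions with zero across-strain variance
#' get all-zero profiles and are listed in the `zero_sd_ions` attribute.
#'
#' @param intensities Corrected samples-x-ions tibble.
#' @param meta Metadata with `sample_id` and `strain` (>= 2 strains).
#' @param z_score_first Z-score per ion across samples before averaging
#'   per strain (the final across-strain z-scoring is applied either way).
#' @return Tibble of class `profile_matrix`: `strain` column plus one
#'   z-scored column per ion.
#' @export
metabolome_profiles <- function(intensities, meta, z_score_first = FALSE) {
  ions <- check_matrix_meta(intensities, meta)
  strain <- meta$strain[match(intensities$sample_id, meta$sample_id)]
  if (length(unique(strain)) < 2) {
    stop_pt("Need >= 2 strains to build profiles.", "peroxitools_bad_input")
  }
  work <- intensities
  if (z_score_first) {
    for (ion in ions) {
      y <- log2(pmax(work[[ion]], .Machine$double.xmin))
      s <- sd(y)
      work[[ion]] <- 2^(if (s == 0) y * 0 else (y - mean(y)) / s)
    }
  }
  logi <- dplyr::mutate(work, strain = strain) |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(ions),
                                   ~ mean(log2(pmax(.x, .Machine$double.xmin)))),
                     .groups = "drop")
  zero_sd <- character()
  for (ion in ions) {
    s <- sd(logi[[ion]])
    if (s == 0) {
      zero_sd <- c(zero_sd, ion)
      logi[[ion]] <- rep(0, nrow(logi))
    } else {
      logi[[ion]] <- (logi[[ion]] - mean(logi[[ion]])) / s
    }
  }
  attr(logi, "zero_sd_ions") <- zero_sd
  class(logi) <- c("profile_matrix", class(logi))
  logi
}

#' Cluster metabolome profiles by Ward linkage on Manhattan distances
#'
#' Computes the Manhattan distance between strain profiles and cuts a Ward
#' hierarchical tree at a fixed number of clusters. Ward's update is applied
#' to the Manhattan dissimilarities as supplied (classical Ward assumes
#' squared Euclidean distances; pairing it with Manhattan distances is a
#' deliberate, documented deviation).
#'
#' @param profiles A [metabolome_profiles()] result.
#' @param k Number of clusters (<= number of strains).
#' @return Tibble `strain`, `cluster` (exactly `k` non-empty clusters);
#'   the `hclust` tree is in attribute `hclust` for dendrogram export.
#' @export
cluster_profiles <- function(profiles, k) {
  ions <- setdiff(names(profiles), "strain")
  if (k > nrow(profiles)) {
    stop_pt("`k` cannot exceed the number of strains.",
            "peroxitools_bad_input")
  }
  mat <- as.matrix(profiles[ions])
  rownames(mat) <- profiles$strain
  tree <- hclust(dist(mat, method = "manhattan"), method = "ward.D")
  assignment <- cutree(tree, k = k)
  out <- tibble(strain = names(assignment), cluster = unname(assignment))
  attr(out, "hclust") <- tree
  out
}

#' Write a clustering dendrogram in Newick format
#'
#' @param clusters A [cluster_profiles()] result (carries the `hclust`
#'   tree).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  tree <- attr(clusters, "hclust")
  if (is.null(tree)) {
    stop_pt("No hclust tree attached to this cluster assignment.",
            "peroxitools_bad_input")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Per-cluster GO enrichment of metabolome clusters
#'
#' Runs [go_enrichment()] for each cluster, using the known annotated genes
#' within the cluster as input against the supplied background, and reports
#' the selected term (largest enrichment factor among BH-adjusted p <
#' `alpha`) per cluster.
#'
#' @param clusters Tibble `strain`, `cluster` (strain names must be gene
#'   identifiers present in `background` to participate; strains outside
#'   the background, e.g. controls, are ignored).
#' @param gene_sets Named list of term -> genes.
#' @param background Gene universe.
#' @param alpha Adjusted-p threshold.
#' @return Tibble with one row per cluster x term plus `cluster` column;
#'   per-cluster selected terms in attribute `selected_terms` (named
#'   character vector, `NA` where no term passed).
#' @export
go_enrich_clusters <- function(clusters, gene_sets, background,
                               alpha = 0.05) {
  res <- purrr::map_dfr(sort(unique(clusters$cluster)), function(cl) {
    genes <- intersect(clusters$strain[clusters$cluster == cl], background)
    if (length(genes) == 0) return(NULL)
    dplyr::mutate(go_enrichment(genes, gene_sets, background, alpha),
                  cluster = cl, .before = 1)
  })
  sel <- res |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(term = if (any(.data$selected)) {
      .data$term[.data$selected]
    } else {
      NA_character_
    }, .groups = "drop")
  attr(res, "selected_terms") <- setNames(sel$term, sel$cluster)
  res
}

#' Slopes of ion intensity versus OD600 and mutant/control fold-changes
#'
#' For experimental designs that sample cultures across a range of optical
#' densities, the metabolic signal is the slope of linear-scale ion
#' intensity with respect to OD600. Slopes are estimated per strain x ion by
#' ordinary least squares (pooling replicate series); fold-changes are
#' mutant slope over control slope. Ions whose control slope is
#' statistically indistinguishable from zero (|slope| < 2 SE) are flagged
#' and excluded from the fold-change report.
#'
#' @param intensities Samples-x-ions tibble (linear scale; no drift/OD
#'   correction is applied in this mode).
#' @param meta Metadata with `sample_id`, `strain`, `od600` (>= 3 distinct
#'   OD600 values per strain).
#' @param mutants Character vector of mutant strain names.
#' @param control Control strain name.
#' @return Tibble `strain`, `ion`, `slope`, `control_slope`, `fold_change`,
#'   `flagged`; flagged rows carry `NA` fold-changes.
#' @export
slope_fold_change <- function(intensities, meta, mutants, control) {
  ions <- check_matrix_meta(intensities, meta)
  strains <- c(control, mutants)
  meta_use <- dplyr::filter(meta, .data$strain %in% strains)
  od_counts <- meta_use |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n_od = dplyr::n_distinct(.data$od600), .groups = "drop")
  if (any(od_counts$n_od < 3)) {
    stop_pt("Each strain needs >= 3 distinct OD600 values.",
            "peroxitools_bad_input")
  }
  slope_of <- function(strain_name, ion) {
    ids <- meta_use$sample_id[meta_use$strain == strain_name]
    rows <- match(ids, intensities$sample_id)
    od <- meta_use$od600[meta_use$strain == strain_name]
    fit <- lm(intensities[[ion]][rows] ~ od)
    cf <- summary(fit)$coefficients
    c(slope = cf["od", "Estimate"], se = cf["od", "Std. Error"])
  }
  ctrl <- vapply(ions, function(i) slope_of(control, i), numeric(2))
  purrr::map_dfr(mutants, function(m) {
    sl <- vapply(ions, function(i) slope_of(m, i), numeric(2))
    # <= catches the exactly-flat control (slope 0, SE 0)
    flagged <- abs(ctrl["slope", ]) <= 2 * ctrl["se", ]
    tibble(
      strain = m, ion = ions,
      slope = unname(sl["slope", ]),
      control_slope = unname(ctrl["slope", ]),
      fold_change = unname(ifelse(flagged, NA_real_,
                                  sl["slope", ] / ctrl["slope", ])),
      flagged = unname(flagged)
    )
  })
}

#' Run the full metabolomics normalization pipeline
#'
#' Applies the stages in their canonical order: outlier filtering, LOWESS
#' injection-order drift correction, linear OD600 correction. Each stage is
#' idempotent on already-corrected input up to numerical tolerance.
#'
#' @param intensities Samples-x-ions tibble.
#' @param meta Sample metadata.
#' @param k_mad Outlier MAD multiplier.
#' @param span LOWESS span.
#' @param reference_od Reference OD600.
#' @return List `intensities` (corrected), `meta` (filtered), `discarded`.
#' @export
normalize_metabolomics <- function(intensities, meta, k_mad = 3, span = 0.3,
                                   reference_od = 1.5) {
  filtered <- filter_outliers(intensities, meta, k_mad = k_mad)
  corrected <- lowess_drift_correct(filtered$intensities, filtered$meta,
                                    span = span)
  corrected <- od_correct(corrected, filtered$meta,
                          reference_od = reference_od,
                          detrend_span = span)
  list(intensities = corrected, meta = filtered$meta,
       discarded = filtered$discarded)
}
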