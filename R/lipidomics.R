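#' Single-point quantification against an internal standard
#'
#' Converts a lipid intensity into an amount by ratio to the co-measured
#' internal-standard intensity of known amount (single-point calibration,
#' e.g. against a SPLASH mix standard of the lipid's class).
#'
#' @param intensity Observed lipid intensity (>= 0).
#' @param standard_intensity Internal-standard intensity (> 0).
#' @param standard_amount Known amount of the internal standard.
#' @return `intensity / standard_intensity * standard_amount`.
#' @examples
#' single_point_quantify(2e5, 1e5, 10)  # twice the standard amount
#' @export
single_point_quantify <- function(intensity, standard_intensity,
                                  standard_amount = 1) {
  if (any(standard_intensity <= 0)) {
    stop_pt("`standard_intensity` must be positive.", "peroxitools_bad_input")
  }
  intensity / standard_intensity * standard_amount
}

#' Per-lipid differential test between two sample groups
#'
#' Two-sided Welch t-test on log2 amounts per lipid, with Benjamini-Hochberg
#' adjustment across lipids. The choice of test is a reconstruction: it is a
#' standard unequal-variance location test on log-scale abundances, flagged
#' as such in the output attribute `test`.
#'
#' @param lipid_table Tibble with `lipid_id`, `lipid_class` and one numeric
#'   column per sample (positive amounts or intensities).
#' @param group_a,group_b Character vectors of sample column names (>= 3
#'   each).
#' @param alpha Adjusted-p significance threshold.
#' @return Tibble `lipid_id`, `lipid_class`, `log2fc` (mean of B minus mean
#'   of A on the log2 scale), `p_value`, `p_adjusted`, `significant`.
#' @export
per_lipid_test <- function(lipid_table, group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop_pt("Need >= 3 samples per group.", "peroxitools_bad_input")
  }
  missing_cols <- setdiff(c(group_a, group_b), names(lipid_table))
  if (length(missing_cols) > 0) {
    stop_pt(paste("Sample columns not in table:",
                  paste(missing_cols, collapse = ", ")),
            "peroxitools_bad_input")
  }
  la <- log2(as.matrix(lipid_table[group_a]))
  lb <- log2(as.matrix(lipid_table[group_b]))
  if (any(!is.finite(la)) || any(!is.finite(lb))) {
    stop_pt("Amounts must be strictly positive for the log-scale test.",
            "peroxitools_bad_input")
  }
  res <- purrr::map_dfr(seq_len(nrow(lipid_table)), function(i) {
    tt <- t.test(lb[i, ], la[i, ])
    tibble(lipid_id = lipid_table$lipid_id[i],
           lipid_class = lipid_table$lipid_class[i],
           log2fc = mean(lb[i, ]) - mean(la[i, ]),
           p_value = tt$p.value)
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adjusted < alpha
  attr(res, "test") <- "Welch t-test on log2 amounts (reconstructed choice)"
  res
}

#' Lipid class enrichment among significantly changing lipids
#'
#' Tests, per lipid class, whether significantly changing lipids are
#' over-represented relative to the class's share of all annotated lipids
#' (upper-tail hypergeometric via [hypergeom_enrichment()], the same core
#' as the GO enrichment). Directionality is the sign of the mean log2
#' fold-change over the class's significant lipids.
#'
#' @param per_lipid A [per_lipid_test()] result (or any tibble with
#'   `lipid_id`, `lipid_class`, `log2fc`, `significant`).
#' @return Tibble with one row per class: counts, `enrichment_factor`,
#'   `p_value`, `direction` (+1/-1/`NA`), ranked by `p_value`. An empty
#'   significant set yields all `p_value = 1` and a `note` attribute.
#' @export
class_enrichment <- function(per_lipid) {
  need <- c("lipid_id", "lipid_class", "log2fc", "significant")
  if (!all(need %in% names(per_lipid))) {
    stop_pt(paste("`per_lipid` needs columns:", paste(need, collapse = ", ")),
            "peroxitools_bad_input")
  }
  N <- nrow(per_lipid)
  n_sig <- sum(per_lipid$significant)
  res <- per_lipid |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$significant),
      mean_sig_log2fc = if (any(.data$significant)) {
        mean(.data$log2fc[.data$significant])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  hg <- hypergeom_enrichment(res$k, n_sig, res$K, N)
  out <- dplyr::bind_cols(
    dplyr::select(res, "lipid_class"),
    dplyr::select(hg, "k", "n", "K", "N", "enrichment_factor", "p_value"),
    tibble(direction = sign(res$mean_sig_log2fc))
  ) |>
    dplyr::arrange(.data$p_value)
  if (n_sig == 0) {
    attr(out, "note") <- "No significant lipids; all class p-values are 1."
  }
  out
}

#' @rdname class_enrichment
#' @param enrichment A `class_enrichment()` result.
#' @return `plot_class_enrichment()`: a ggplot bar chart of -log10 p by
#'   class, arrows encoding fold-change direction.
#' @export
plot_class_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = stats::reorder(.data$lipid_class,
                                                  -.data$p_value),
                               y = -log10(.data$p_value),
                               fill = factor(.data$direction,
                                             levels = c(-1, 1),
                                             labels = c("down", "up")))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  fill = "Direction",
                  title = "Lipid class enrichment of changing lipids")
}
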