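# Readers/writers for the plain-text formats used around the pipeline.
# Distance tables travel as TSV, everything else as CSV.

#' Read and write per-contact distance tables
#'
#' Distance tables are tab-separated with columns `time_ps`, `contact_id`,
#' `distance_nm` and optionally `trajectory_id` (defaulted to `"traj1"` on
#' read when absent).
#'
#' @param path File path.
#' @return `read_distances()`: a distance tibble; `write_distances()`:
#'   `path`, invisibly.
#' @export
read_distances <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"trajectory_id" %in% names(out)) out$trajectory_id <- "traj1"
  check_distance_table(out)
  out
}

#' @rdname read_distances
#' @param distances Distance tibble (`time_ps`, `contact_id`,
#'   `trajectory_id`, `distance_nm`).
#' @export
write_distances <- function(distances, path) {
  check_distance_table(distances)
  readr::write_tsv(distances, path)
  invisible(path)
}

#' Read a contact-spec table from CSV
#'
#' Columns: `contact_id`, `receptor_residue`, `receptor_atom`,
#' `peptide_position`, `peptide_atom`, `aggregation`, optional `pair_id`,
#' `excluded` (logical). Each row is validated through [contact_spec()].
#'
#' @param path CSV path.
#' @return Contact-spec tibble.
#' @export
read_contact_specs <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  purrr::pmap_dfr(raw, function(contact_id, receptor_residue, receptor_atom,
                                peptide_position, peptide_atom,
                                aggregation = "individual",
                                pair_id = NA_character_, excluded = FALSE,
                                ...) {
    contact_spec(contact_id, receptor_residue, receptor_atom,
                 peptide_position, peptide_atom, aggregation,
                 pair_id, excluded)
  })
}

#' Read and write samples-x-ions intensity matrices
#'
#' CSV with a `sample_id` column followed by one numeric column per ion.
#'
#' @param path CSV path.
#' @return `read_intensity_csv()`: intensity tibble;
#'   `write_intensity_csv()`: `path`, invisibly.
#' @export
read_intensity_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_intensity_csv
#' @param intensities Samples-x-ions tibble.
#' @export
write_intensity_csv <- function(intensities, path) {
  readr::write_csv(intensities, path)
  invisible(path)
}

#' Occupancy bar chart
#'
#' @param occ An occupancy tibble from [hbond_occupancy()] or
#'   [pool_trajectories()].
#' @return A ggplot object: occupancy percent per contact, faceted by
#'   window when several are present.
#' @export
plot_occupancy <- function(occ) {
  p <- ggplot2::ggplot(occ, ggplot2::aes(x = .data$contact_id,
                                         y = .data$occupancy_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "H-bond occupancy (%)")
  if (length(unique(occ$window)) > 1) {
    p <- p + ggplot2::facet_wrap(~window)
  }
  p
}

#' Dendrogram plot of a metabolome clustering
#'
#' @param clusters A [cluster_profiles()] result.
#' @param ... Passed to [graphics::plot()].
#' @return The `hclust` tree, invisibly.
#' @export
plot_profile_dendrogram <- function(clusters, ...) {
  tree <- attr(clusters, "hclust")
  if (is.null(tree)) {
    stop_pt("No hclust tree attached to this cluster assignment.",
            "peroxitools_bad_input")
  }
  graphics::plot(tree, xlab = "", sub = "",
                 main = "Ward clustering of metabolome profiles", ...)
  invisible(tree)
}
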