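#' Hydrogen-bond detector
#'
#' A donor--acceptor pair is counted as hydrogen bonded when their distance
#' is at or below the cutoff (0.35 nm by default, boundary inclusive). No
#' angular term is applied: directional judgments (such as excluding
#' arginine N-H contacts whose geometry cannot form a hydrogen bond) are
#' encoded as explicit contact exclusions, see [apply_exclusions()].
#'
#' @param distance_nm Donor--acceptor distance(s) in nm; must be positive.
#' @param cutoff_nm Distance cutoff in nm (default 0.35).
#' @return Logical vector, `TRUE` where bonded.
#' @examples
#' is_bonded(c(0.35, 0.3501, 0.10))
#' @export
is_bonded <- function(distance_nm, cutoff_nm = 0.35) {
  if (any(!is.finite(distance_nm)) || any(distance_nm <= 0)) {
    stop_pt("Distances must be positive and finite.", "peroxitools_bad_input")
  }
  distance_nm <= cutoff_nm
}

#' Analysis window covering the last part of each trajectory
#'
#' The first part of each trajectory is discarded as equilibration: the
#' `last90` window keeps the final 90 ns of a run, `last50` the final 50 ns.
#' Window boundaries are closed (frames on either boundary are included).
#'
#' @param label `"last90"`, `"last50"`, or `"custom"`.
#' @param length_ns Window length in ns; inferred from the label unless
#'   `label = "custom"`.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(label = c("last90", "last50", "custom"),
                            length_ns = NULL) {
  label <- match.arg(label)
  length_ns <- length_ns %||% switch(label, last90 = 90, last50 = 50,
                                     stop_pt("Custom window needs `length_ns`.",
                                             "peroxitools_bad_input"))
  if (length_ns <= 0) {
    stop_pt("`length_ns` must be positive.", "peroxitools_bad_input")
  }
  structure(list(label = label, length_ns = length_ns),
            class = "analysis_window")
}

#' Per-contact hydrogen-bond occupancy within an analysis window
#'
#' Computes, for each contact and trajectory, the percentage of frames in
#' the analysis window whose donor--acceptor distance is at or below the
#' cutoff. The window is anchored at the end of each trajectory
#' (`[t_max - length, t_max]`, closed on both sides), so trajectories of
#' different lengths are handled per trajectory.
#'
#' @param distances Tibble with columns `time_ps`, `contact_id`,
#'   `trajectory_id`, `distance_nm` (one row per frame per contact).
#' @param window An [analysis_window()] (default: last 90 ns).
#' @param cutoff_nm Hydrogen-bond distance cutoff in nm.
#' @return A tibble with one row per contact x trajectory: `contact_id`,
#'   `trajectory_id`, `window`, `occupancy_pct` (in \[0, 100\]), `n_frames`,
#'   `window_ns`.
#' @examples
#' d <- sim_distance_series(0.8, n_frames = 1000, seed = 1)
#' hbond_occupancy(d, analysis_window("last90"))
#' @export
hbond_occupancy <- function(distances, window = analysis_window("last90"),
                            cutoff_nm = 0.35) {
  stopifnot(inherits(window, "analysis_window"))
  check_distance_table(distances)
  win_label <- window$label
  win_ns <- window$length_ns
  out <- distances |>
    dplyr::group_by(.data$contact_id, .data$trajectory_id) |>
    dplyr::group_modify(function(df, key) {
      t_end <- max(df$time_ps)
      t_start <- t_end - window$length_ns * 1000
      in_win <- df$time_ps >= t_start & df$time_ps <= t_end
      if (!any(in_win)) {
        stop_pt(sprintf("Window '%s' contains no frames for contact %s.",
                        window$label, key$contact_id[1]),
                "peroxitools_empty_window")
      }
      d <- df$distance_nm[in_win]
      tibble(occupancy_pct = 100 * mean(is_bonded(d, cutoff_nm)),
             n_frames = sum(in_win))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(window = win_label, window_ns = win_ns,
                  .after = "trajectory_id")
  out
}

check_distance_table <- function(distances) {
  need <- c("time_ps", "contact_id", "trajectory_id", "distance_nm")
  if (!all(need %in% names(distances))) {
    stop_pt(paste("Distance table needs columns:",
                  paste(need, collapse = ", ")), "peroxitools_bad_input")
  }
  invisible(distances)
}

#' Merge candidate acceptor contacts by per-frame minimum distance
#'
#' Backbone nitrogen atoms donate a single hydrogen bond, so when several
#' acceptors compete for one donor only the shortest distance in each frame
#' is relevant. This merges the candidate contact series into one series
#' holding the per-frame minimum, which is then scored by
#' [hbond_occupancy()].
#'
#' @param distances Tibble in the distance-table format containing the
#'   candidate contacts (two or more `contact_id` values per trajectory,
#'   all on identical time grids).
#' @param merged_id `contact_id` given to the merged series.
#' @return A distance tibble with one row per frame per trajectory.
#' @export
min_distance_merge <- function(distances, merged_id = "min_distance") {
  check_distance_table(distances)
  distances |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_modify(function(df, key) {
      grids <- df |>
        dplyr::group_by(.data$contact_id) |>
        dplyr::summarise(grid = list(sort(.data$time_ps)), .groups = "drop")
      ref <- grids$grid[[1]]
      same <- vapply(grids$grid, function(g) identical(g, ref), logical(1))
      if (!all(same)) {
        stop_pt("Candidate contacts are not on identical time grids.",
                "peroxitools_grid_mismatch")
      }
      df |>
        dplyr::group_by(.data$time_ps) |>
        dplyr::summarise(distance_nm = min(.data$distance_nm),
                         .groups = "drop")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(contact_id = merged_id) |>
    dplyr::select("time_ps", "contact_id", "trajectory_id", "distance_nm") |>
    dplyr::arrange(.data$trajectory_id, .data$time_ps)
}

#' Summed occupancy of a backbone-oxygen contact pair
#'
#' Backbone oxygens accept two (or more) hydrogen bonds; the per-position
#' stability of such an oxygen is the arithmetic sum of its two contact
#' occupancies. The sum may exceed 100% when both bonds are present in the
#' same frames; the admissible range is \[0, 200\].
#'
#' @param occ_a,occ_b Occupancy percentages in \[0, 100\].
#' @return `occ_a + occ_b`.
#' @examples
#' summed_pair_occupancy(60, 30)
#' @export
summed_pair_occupancy <- function(occ_a, occ_b) {
  if (any(occ_a < 0 | occ_a > 100) || any(occ_b < 0 | occ_b > 100)) {
    stop_pt("Occupancies must lie in [0, 100].", "peroxitools_bad_input")
  }
  occ_a + occ_b
}

#' Contact specification for occupancy accounting
#'
#' Describes one tracked receptor--peptide contact: which receptor atom it
#' involves, which peptide backbone atom at which position (counted from the
#' C-terminus, -1 most C-terminal), how it enters the per-position
#' aggregation, and whether it is excluded from hydrogen-bond accounting.
#' The C-terminal carboxylate oxygens (OT1/OT2) exist only at position -1;
#' minimum-distance aggregation applies only to backbone nitrogen donors.
#'
#' @param contact_id Unique contact label.
#' @param receptor_residue,receptor_atom Receptor-side labels (e.g.
#'   `"Asn378"`, `"Nd2"`).
#' @param peptide_position Negative integer (<= -1).
#' @param peptide_atom One of `"backbone_O"`, `"OT1"`, `"OT2"`,
#'   `"backbone_N"`.
#' @param aggregation One of `"individual"`, `"summed_pair"`,
#'   `"min_distance"`.
#' @param pair_id Shared label linking the two members of a `summed_pair`.
#' @param excluded Exclude this contact from occupancy accounting (kept in a
#'   distance-report side channel), e.g. arginine N-H contacts whose bond
#'   direction cannot form a hydrogen bond.
#' @return One-row tibble; rows from multiple calls can be bound into a
#'   contact-spec table.
#' @export
contact_spec <- function(contact_id, receptor_residue, receptor_atom,
                         peptide_position, peptide_atom,
                         aggregation = "individual", pair_id = NA_character_,
                         excluded = FALSE) {
  peptide_atom <- match.arg(peptide_atom,
                            c("backbone_O", "OT1", "OT2", "backbone_N"))
  aggregation <- match.arg(aggregation,
                           c("individual", "summed_pair", "min_distance"))
  if (peptide_position > -1) {
    stop_pt("`peptide_position` must be <= -1.", "peroxitools_bad_input")
  }
  if (peptide_atom %in% c("OT1", "OT2") && peptide_position != -1) {
    stop_pt("OT1/OT2 atoms exist only at position -1.",
            "peroxitools_bad_input")
  }
  if (aggregation == "min_distance" && peptide_atom != "backbone_N") {
    stop_pt("min_distance aggregation applies only to backbone_N donors.",
            "peroxitools_bad_input")
  }
  tibble(contact_id = contact_id, receptor_residue = receptor_residue,
         receptor_atom = receptor_atom, peptide_position = peptide_position,
         peptide_atom = peptide_atom, aggregation = aggregation,
         pair_id = pair_id, excluded = excluded)
}

#' Drop excluded contacts from occupancy accounting
#'
#' Removes contacts flagged `excluded` (for example arginine Ne/Nh contacts
#' to the position -2 backbone oxygen, whose N-H bond direction is
#' inadequate for hydrogen bonding even when the distance criterion is met).
#' Excluded contacts are retained in the `"excluded"` attribute as a
#' distance-report side channel.
#'
#' @param contacts Contact-spec tibble (see [contact_spec()]).
#' @return The included contacts; excluded rows in `attr(, "excluded")`.
#'   Warns if every contact is excluded.
#' @export
apply_exclusions <- function(contacts) {
  if (!"excluded" %in% names(contacts)) {
    stop_pt("Contact table needs an `excluded` column.",
            "peroxitools_bad_input")
  }
  kept <- dplyr::filter(contacts, !.data$excluded)
  if (nrow(kept) == 0 && nrow(contacts) > 0) {
    warn("All contacts are excluded; occupancy table will be empty.")
  }
  attr(kept, "excluded") <- dplyr::filter(contacts, .data$excluded)
  kept
}

#' Pool per-trajectory occupancies across replicate trajectories
#'
#' Replicate trajectories of the same complex are analyzed together: the
#' pooled occupancy is the frame-weighted mean of per-trajectory
#' occupancies, and the analyzed duration is the sum of the window lengths
#' over trajectories (two 100 ns runs under the last-90-ns window pool to a
#' combined 180 ns of analyzed simulation).
#'
#' @param occ Occupancy tibble from [hbond_occupancy()] (one window label
#'   only; mixing windows is rejected).
#' @return A tibble with one row per contact: `contact_id`, `window`,
#'   `occupancy_pct`, `n_frames`, `n_trajectories`, `analyzed_ns`.
#' @examples
#' d <- dplyr::bind_rows(
#'   sim_distance_series(0.9, n_frames = 2000, trajectory_id = "t1", seed = 1),
#'   sim_distance_series(0.9, n_frames = 2000, trajectory_id = "t2", seed = 2))
#' pool_trajectories(hbond_occupancy(d, analysis_window("custom", 15)))
#' @export
pool_trajectories <- function(occ) {
  if (length(unique(occ$window)) > 1) {
    stop_pt("Cannot pool occupancies from different window labels.",
            "peroxitools_bad_input")
  }
  if (nrow(occ) == 0) {
    stop_pt("Empty occupancy table.", "peroxitools_bad_input")
  }
  occ |>
    dplyr::group_by(.data$contact_id, .data$window) |>
    dplyr::summarise(
      occupancy_pct = weighted.mean(.data$occupancy_pct, .data$n_frames),
      n_frames = sum(.data$n_frames),
      n_trajectories = dplyr::n(),
      analyzed_ns = sum(.data$window_ns),
      .groups = "drop"
    )
}

#' Time dependence of contact stability between two analysis windows
#'
#' Compares pooled occupancies computed over the last 50 ns against the last
#' 90 ns of the same trajectories. Small deltas indicate that the contact
#' statistics are stationary after the discarded equilibration phase; the
#' result is flagged `minor` when the largest absolute delta stays below the
#' threshold (5 percentage points by default).
#'
#' @param pooled_long Pooled occupancy table for the longer window (e.g.
#'   last90).
#' @param pooled_short Pooled table for the shorter window (e.g. last50),
#'   same contacts.
#' @param threshold Percentage-point threshold for the `minor` flag.
#' @return A tibble `contact_id`, `occupancy_long`, `occupancy_short`,
#'   `delta_pct` (short minus long); attribute `minor` is `TRUE` when
#'   `max(|delta|) < threshold`.
#' @export
time_dependence <- function(pooled_long, pooled_short, threshold = 5) {
  if (!setequal(pooled_long$contact_id, pooled_short$contact_id)) {
    stop_pt("The two windows cover different contact sets.",
            "peroxitools_bad_input")
  }
  out <- dplyr::inner_join(
    dplyr::select(pooled_long, "contact_id", occupancy_long = "occupancy_pct"),
    dplyr::select(pooled_short, "contact_id",
                  occupancy_short = "occupancy_pct"),
    by = "contact_id"
  ) |>
    dplyr::mutate(delta_pct = .data$occupancy_short - .data$occupancy_long)
  attr(out, "minor") <- max(abs(out$delta_pct)) < threshold
  out
}

#' Average hydrogen-bond stability per peptide position
#'
#' Combines pooled contact occupancies with a contact-spec table into the
#' per-position averaged stabilities used for cargo classification.
#' Exclusions are applied first; `summed_pair` contacts contribute the sum
#' of their pair (so a position -3 backbone oxygen enters as one aggregate
#' that can exceed 100%); `individual` and `min_distance` contacts
#' contribute their own occupancy. The position stability is the arithmetic
#' mean of these aggregates.
#'
#' @param pooled Pooled occupancy table from [pool_trajectories()].
#' @param contacts Contact-spec tibble matching `pooled$contact_id`.
#' @return A tibble `peptide_position`, `avg_stability_pct`, `n_aggregates`.
#' @export
position_stability <- function(pooled, contacts) {
  contacts <- apply_exclusions(contacts)
  joined <- dplyr::inner_join(pooled, contacts, by = "contact_id")
  if (nrow(joined) == 0) {
    stop_pt("No included contacts with occupancy values.",
            "peroxitools_bad_input")
  }
  aggregates <- joined |>
    dplyr::mutate(agg_key = dplyr::if_else(
      .data$aggregation == "summed_pair" & !is.na(.data$pair_id),
      paste0("pair:", .data$pair_id), .data$contact_id)) |>
    dplyr::group_by(.data$peptide_position, .data$agg_key) |>
    dplyr::summarise(value = sum(.data$occupancy_pct), .groups = "drop")
  aggregates |>
    dplyr::group_by(.data$peptide_position) |>
    dplyr::summarise(avg_stability_pct = position_average(.data$value),
                     n_aggregates = dplyr::n(), .groups = "drop")
}
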