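#' C-terminal hexapeptide of a protein sequence
#'
#' PTS1 recognition is carried by the extreme C-terminus; simulations and
#' binding assays use the final six residues of each candidate protein.
#'
#' @param protein_sequence Character vector of amino-acid sequences
#'   (one-letter codes), each of length >= 6.
#' @return Character vector of 6-residue peptides, C-terminus last.
#' @examples
#' cterm_hexapeptide("RKRVLGVAYL")
#' @export
cterm_hexapeptide <- function(protein_sequence) {
  len <- nchar(protein_sequence)
  if (any(len < 6)) {
    stop_pt("Protein sequence shorter than 6 residues; cannot take the C-terminal hexapeptide.",
            "peroxitools_bad_input")
  }
  substr(protein_sequence, len - 5, len)
}

#' Arithmetic mean of a position's aggregated contact stabilities
#'
#' @param aggregates Numeric vector of aggregated contact occupancies
#'   (percent; summed pairs may exceed 100). Must be non-empty.
#' @return The mean, in percent.
#' @examples
#' position_average(c(80, 80, 80, 80))
#' @export
position_average <- function(aggregates) {
  if (length(aggregates) == 0 || any(!is.finite(aggregates))) {
    stop_pt("Need a non-empty set of finite aggregate stabilities.",
            "peroxitools_bad_input")
  }
  mean(aggregates)
}

#' Known-cargo stability envelope at peptide positions -1 and -3
#'
#' Builds the reference ranges used for cargo classification: the minimum
#' and maximum of the averaged hydrogen-bond stabilities at positions -1
#' and -3 over a set of known cargo peptides. The most stable backbone
#' hydrogen bonds of canonical PTS1 cargos are formed at these two
#' positions, and their observed range over known cargos separates cargos
#' from known non-cargos.
#'
#' @param known Tibble with columns `peptide_id`, `stability_m1`,
#'   `stability_m3` (averaged stabilities at positions -1 and -3, percent),
#'   one row per known cargo; >= 2 cargos required.
#' @return Tibble of class `reference_ranges` with columns `position`
#'   (`-1`, `-3`), `min`, `max`; attribute `n_cargos`.
#' @export
build_reference_ranges <- function(known) {
  need <- c("peptide_id", "stability_m1", "stability_m3")
  if (!all(need %in% names(known))) {
    stop_pt(paste("`known` needs columns:", paste(need, collapse = ", ")),
            "peroxitools_bad_input")
  }
  if (nrow(known) < 2) {
    stop_pt("Need at least 2 known cargos to build reference ranges.",
            "peroxitools_bad_input")
  }
  out <- tibble(
    position = c(-1L, -3L),
    min = c(min(known$stability_m1), min(known$stability_m3)),
    max = c(max(known$stability_m1), max(known$stability_m3))
  )
  attr(out, "n_cargos") <- nrow(known)
  class(out) <- c("reference_ranges", class(out))
  out
}

#' Classify candidate peptides against the known-cargo envelope
#'
#' A candidate passes a position when its averaged stability reaches that
#' position's range minimum (ties inclusive, mirroring the inclusive
#' distance cutoff); it is called a binder when both positions pass. The
#' default pass rule is one-sided (`>= min`), so a candidate more stable
#' than every known cargo still passes; `strict_interval = TRUE` instead
#' requires the stability to fall inside `[min, max]`.
#'
#' @param candidates Tibble with columns `peptide_id`, `stability_m1`,
#'   `stability_m3`.
#' @param ranges A [build_reference_ranges()] result.
#' @param strict_interval Require stabilities within `[min, max]` rather
#'   than `>= min`.
#' @return Tibble with per-position pass flags, margins to the range
#'   minimum (percentage points; negative = below the envelope), and the
#'   `binder` verdict (`pass_m1 & pass_m3`).
#' @examples
#' known <- tibble::tibble(peptide_id = c("a", "b"),
#'                         stability_m1 = c(70, 90), stability_m3 = c(50, 60))
#' rng <- build_reference_ranges(known)
#' classify_binders(tibble::tibble(peptide_id = "x", stability_m1 = 80,
#'                                 stability_m3 = 55), rng)
#' @export
classify_binders <- function(candidates, ranges, strict_interval = FALSE) {
  stopifnot(inherits(ranges, "reference_ranges"))
  rng <- function(pos, what) ranges[[what]][ranges$position == pos]
  pass <- function(x, pos) {
    if (strict_interval) x >= rng(pos, "min") & x <= rng(pos, "max")
    else x >= rng(pos, "min")
  }
  candidates |>
    dplyr::mutate(
      pass_m1 = pass(.data$stability_m1, -1L),
      pass_m3 = pass(.data$stability_m3, -3L),
      margin_m1 = .data$stability_m1 - rng(-1L, "min"),
      margin_m3 = .data$stability_m3 - rng(-3L, "min"),
      binder = .data$pass_m1 & .data$pass_m3
    )
}
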