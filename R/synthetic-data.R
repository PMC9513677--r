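#' Simulate a donor--acceptor distance series for one trajectory
#'
#' Generates the per-frame distance table a molecular-dynamics run would
#' export for one receptor--peptide contact. Each frame is bonded
#' (distance = `bonded_distance`) with probability `target_occupancy` and
#' unbonded (`unbonded_distance`) otherwise, so the designed hydrogen-bond
#' occupancy is known exactly. Frames are independent by default; setting
#' `persistence > 0` switches to a two-state Markov chain with the same
#' stationary occupancy, emulating the autocorrelation of real trajectories.
#'
#' @param target_occupancy Fraction of frames in the bonded state, in
#'   \[0, 1\].
#' @param n_frames Number of frames (positive integer).
#' @param frame_step Time between frames in ps (positive).
#' @param bonded_distance,unbonded_distance Distances (nm) emitted for bonded
#'   and unbonded frames. Must satisfy `bonded_distance <= 0.35 <
#'   unbonded_distance` so the designed occupancy is recovered by the 0.35 nm
#'   detector.
#' @param contact_id,trajectory_id Labels carried into the output table.
#' @param persistence Markov persistence in \[0, 1); 0 gives i.i.d. frames.
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#'
#' @return A tibble with columns `time_ps`, `contact_id`, `trajectory_id`,
#'   `distance_nm`. Frame times are `frame_step, 2*frame_step, ...`, so the
#'   trajectory spans `n_frames * frame_step` ps.
#' @examples
#' sim_distance_series(0.855, n_frames = 100, seed = 1)
#' @export
sim_distance_series <- function(target_occupancy,
                                n_frames = 10000L,
                                frame_step = 10,
                                bonded_distance = 0.29,
                                unbonded_distance = 0.45,
                                contact_id = "contact",
                                trajectory_id = "traj1",
                                persistence = 0,
                                seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 1 || n_frames != floor(n_frames)) {
    stop_pt("`n_frames` must be a positive integer.", "peroxitools_bad_input")
  }
  if (!is.numeric(frame_step) || frame_step <= 0) {
    stop_pt("`frame_step` must be positive.", "peroxitools_bad_input")
  }
  if (target_occupancy < 0 || target_occupancy > 1) {
    stop_pt("`target_occupancy` must lie in [0, 1].", "peroxitools_bad_input")
  }
  if (!(bonded_distance <= 0.35 && 0.35 < unbonded_distance)) {
    stop_pt("Need bonded_distance <= 0.35 < unbonded_distance.",
            "peroxitools_bad_input")
  }
  if (persistence < 0 || persistence >= 1) {
    stop_pt("`persistence` must lie in [0, 1).", "peroxitools_bad_input")
  }
  n <- as.integer(n_frames)
  p <- target_occupancy
  bonded <- withr_seed(seed, {
    if (persistence == 0 || p %in% c(0, 1)) {
      runif(n) < p
    } else {
      # two-state chain with stay-probability rho + (1 - rho) * pi_state,
      # stationary distribution (1 - p, p)
      state <- logical(n)
      state[1] <- runif(1) < p
      u <- runif(n)
      for (i in seq_len(n)[-1]) {
        p_bond <- persistence * state[i - 1] + (1 - persistence) * p
        state[i] <- u[i] < p_bond
      }
      state
    }
  })
  tibble(
    time_ps = seq_len(n) * frame_step,
    contact_id = contact_id,
    trajectory_id = trajectory_id,
    distance_nm = ifelse(bonded, bonded_distance, unbonded_distance)
  )
}

# Evaluate `code` under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Draws anisotropy readings from the one-site binding-saturation model
#' ([one_site_model()]) plus Gaussian noise, with the replicate-within-
#' experiment structure of a plate-reader assay (each concentration measured
#' in triplicate, several independent experiments).
#'
#' @param kd True dissociation constant (uM), positive.
#' @param a_free,a_bound Anisotropy of the free and bound probe (arbitrary
#'   units, typically mA); must differ.
#' @param concentrations Receptor concentrations (uM), non-negative. Default
#'   is 12 points log-spaced over 0.5--60 uM, which brackets uM-scale Kd
#'   values on both sides of half-saturation.
#' @param noise_sd Gaussian noise SD in anisotropy units.
#' @param n_replicates Technical replicates per concentration per experiment.
#' @param n_experiments Independent experiments.
#' @param probe_nM Probe concentration (nM), recorded for depletion-corrected
#'   fitting.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `experiment_id`, `replicate_id`,
#'   `receptor_uM`, `anisotropy`, `probe_nM`, sorted by concentration within
#'   replicate. The true parameters are attached as attribute `truth`.
#' @examples
#' sim_titration(kd = 5.5, seed = 1)
#' @export
sim_titration <- function(kd,
                          a_free = 60,
                          a_bound = 160,
                          concentrations = titration_grid(),
                          noise_sd = 2,
                          n_replicates = 3L,
                          n_experiments = 3L,
                          probe_nM = 10,
                          seed = 1L) {
  if (kd <= 0) stop_pt("`kd` must be positive.", "peroxitools_bad_input")
  if (a_bound == a_free) {
    stop_pt("`a_bound` must differ from `a_free`.", "peroxitools_bad_input")
  }
  if (length(concentrations) == 0) {
    stop_pt("`concentrations` must be non-empty.", "peroxitools_bad_input")
  }
  if (any(concentrations < 0)) {
    stop_pt("`concentrations` must be non-negative.", "peroxitools_bad_input")
  }
  grid <- tidyr::expand_grid(
    experiment_id = sprintf("exp%d", seq_len(n_experiments)),
    replicate_id = sprintf("rep%d", seq_len(n_replicates)),
    receptor_uM = sort(concentrations)
  )
  mu <- one_site_model(grid$receptor_uM, kd, a_free, a_bound)
  eps <- withr_seed(seed, rnorm(nrow(grid), sd = noise_sd))
  out <- dplyr::mutate(grid, anisotropy = mu + eps, probe_nM = probe_nM)
  attr(out, "truth") <- list(kd = kd, a_free = a_free, a_bound = a_bound,
                             noise_sd = noise_sd)
  out
}

#' Default log-spaced titration concentration grid
#'
#' @param from,to Range in uM.
#' @param n Number of points.
#' @return Numeric vector of concentrations (uM).
#' @export
titration_grid <- function(from = 0.5, to = 60, n = 12L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate a flow-injection metabolomics plate with designed ground truth
#'
#' Builds a samples-by-ions intensity matrix with the nuisance structure a
#' flow-injection time-of-flight run accumulates: a smooth injection-order
#' drift, a linear OD600 dependence, planted strain-specific log2
#' fold-changes, i.i.d. Gaussian noise on the log scale, and a designated
#' fraction of outlier samples (extreme OD600 or total ion current). Every
#' planted quantity is recorded in a truth ledger so downstream corrections
#' can be scored against it.
#'
#' The model on the log2 scale is
#' `log2 I = baseline(ion) + drift(injection index) + od_slope * OD600 +
#'  planted effect(strain, ion) + noise`,
#' with `drift(i) = drift_amplitude * (0.6 sin(pi i / n) + 0.8 (i/n - 1/2))`
#' -- a smooth low-order curve a LOWESS smoother can capture.
#'
#' @param n_strains Number of mutant strains (a control strain named
#'   `"control"` is added on top).
#' @param n_ions Number of annotated ions.
#' @param n_replicates Replicate cultures per strain.
#' @param drift_amplitude Drift amplitude, log2-intensity units per plate.
#' @param od_slope OD600 effect, log2-intensity units per OD unit.
#' @param planted_effects Tibble with columns `strain`, `ion`, `log2fc`
#'   naming the planted strain-by-ion effects, or `NULL` for none. Rows
#'   referencing unknown strains or ions are rejected.
#' @param noise_sd Log2-intensity noise SD (positive).
#' @param outlier_fraction Fraction of samples turned into outliers, in
#'   \[0, 0.5); half get an extreme OD600, half an extreme total ion current.
#' @param od_mean,od_sd OD600 at harvest: normal around the 1.5 target.
#' @param baseline_log2 Mean ion baseline (log2 intensity).
#' @param background_tic Ratio of unannotated to annotated total signal.
#'   Recorded total ion current is the annotated ion sum plus an
#'   unannotated background this many times larger, sharing the drift, OD
#'   and failure structure -- as in a real full-spectrum acquisition, where
#'   annotated ions are a small fraction of the TIC and single-metabolite
#'   biology does not move it.
#' @param condition Growth condition label recorded in the metadata.
#' @param seed Integer seed.
#'
#' @return A list with elements `intensities` (tibble, `sample_id` plus one
#'   column per ion, linear scale), `meta` (tibble: `sample_id`, `strain`,
#'   `condition`, `mutation_type`, `od600`, `injection_index`,
#'   `total_ion_current`) and `truth` (list: planted effects, drift table,
#'   `od_slope`, outlier sample ids with reasons, baselines).
#' @examples
#' plate <- sim_metabolomics_plate(n_strains = 4, n_ions = 10, seed = 1)
#' names(plate)
#' @export
sim_metabolomics_plate <- function(n_strains = 20L,
                                   n_ions = 50L,
                                   n_replicates = 4L,
                                   drift_amplitude = 0.6,
                                   od_slope = 0.5,
                                   planted_effects = NULL,
                                   noise_sd = 0.25,
                                   outlier_fraction = 0,
                                   od_mean = 1.5,
                                   od_sd = 0.15,
                                   baseline_log2 = 14,
                                   background_tic = 20,
                                   condition = "glucose",
                                   seed = 1L) {
  if (noise_sd <= 0) stop_pt("`noise_sd` must be > 0.", "peroxitools_bad_input")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop_pt("`outlier_fraction` must lie in [0, 0.5).", "peroxitools_bad_input")
  }
  strains <- c("control", sprintf("mut%02d", seq_len(n_strains)))
  ions <- sprintf("ion%03d", seq_len(n_ions))
  if (!is.null(planted_effects)) {
    bad <- !(planted_effects$strain %in% strains) |
      !(planted_effects$ion %in% ions)
    if (any(bad)) {
      stop_pt("`planted_effects` references unknown strains or ions.",
              "peroxitools_bad_input")
    }
  }
  meta <- tidyr::expand_grid(strain = strains,
                             replicate = seq_len(n_replicates))
  n_samples <- nrow(meta)

  withr_seed(seed, {
    meta <- dplyr::mutate(
      meta,
      sample_id = sprintf("s%03d", dplyr::row_number()),
      condition = condition,
      mutation_type = ifelse(.data$strain == "control", "control", "deletion"),
      od600 = pmax(0.05, rnorm(n_samples, od_mean, od_sd)),
      injection_index = sample.int(n_samples)
    )

    n_out <- floor(outlier_fraction * n_samples)
    out_idx <- if (n_out > 0) sample.int(n_samples, n_out) else integer()
    od_out <- out_idx[seq_len(ceiling(n_out / 2))]
    tic_out <- setdiff(out_idx, od_out)
    meta$od600[od_out] <- 4 * od_mean   # overgrown culture, far past 3 MAD

    baselines <- rnorm(n_ions, baseline_log2, 1.5)
    drift_curve <- drift_amplitude *
      (0.6 * sin(pi * seq_len(n_samples) / n_samples) +
         0.8 * (seq_len(n_samples) / n_samples - 0.5))

    logi <- matrix(rnorm(n_samples * n_ions, sd = noise_sd),
                   n_samples, n_ions, dimnames = list(meta$sample_id, ions))
    logi <- logi + rep(baselines, each = n_samples)
    logi <- logi + drift_curve[meta$injection_index]
    logi <- logi + od_slope * meta$od600
    if (!is.null(planted_effects)) {
      for (r in seq_len(nrow(planted_effects))) {
        rows <- meta$strain == planted_effects$strain[r]
        logi[rows, planted_effects$ion[r]] <-
          logi[rows, planted_effects$ion[r]] + planted_effects$log2fc[r]
      }
    }
    tic_rows <- meta$sample_id %in% meta$sample_id[tic_out]
    logi[tic_rows, ] <- logi[tic_rows, ] + log2(10)  # 10x total ion current

    # unannotated spectrum background: dominates the recorded TIC and
    # shares the run-level structure (drift, OD dependence, failures)
    bg_mod <- drift_curve[meta$injection_index] + od_slope * meta$od600 +
      rnorm(n_samples, sd = noise_sd / 4) + ifelse(tic_rows, log2(10), 0)
  })

  intens <- 2^logi
  bg0 <- background_tic * median(rowSums(intens)) / 2^median(bg_mod)
  meta$total_ion_current <- rowSums(intens) + bg0 * 2^bg_mod
  intensities <- dplyr::bind_cols(
    tibble(sample_id = meta$sample_id),
    as_tibble(intens)
  )
  meta <- dplyr::select(meta, "sample_id", "strain", "condition",
                        "mutation_type", "od600", "injection_index",
                        "total_ion_current")
  truth <- list(
    planted_effects = planted_effects %||%
      tibble(strain = character(), ion = character(), log2fc = double()),
    drift = tibble(injection_index = seq_len(n_samples),
                   drift_log2 = drift_amplitude *
                     (0.6 * sin(pi * seq_len(n_samples) / n_samples) +
                        0.8 * (seq_len(n_samples) / n_samples - 0.5))),
    od_slope = od_slope,
    outliers = tibble(
      sample_id = meta$sample_id[sort(c(od_out, tic_out))],
      reason = ifelse(meta$sample_id[sort(c(od_out, tic_out))] %in%
                        meta$sample_id[od_out], "od600", "tic")
    ),
    baselines = setNames(baselines, ions)
  )
  list(intensities = intensities, meta = meta, truth = truth)
}

#' Simulate an OD600 time-course for slope-based fold-changes
#'
#' Emulates the experimental design used for focused mutant analyses in which
#' cultures are sampled across OD600 values between 0 and ~1.5 and the slope
#' of ion intensity with respect to OD600 carries the signal. Each strain's
#' per-ion slope is a designed multiple of the control slope.
#'
#' @param slope_multipliers Named numeric vector mapping strain name to the
#'   multiplier applied to each ion's control slope; must contain
#'   `"control" = 1`.
#' @param n_ions Number of ions.
#' @param od_values OD600 sampling points (>= 3 distinct values).
#' @param n_series Replicate sampling series per strain.
#' @param base_slope_range Range the per-ion control slopes are drawn from
#'   (linear intensity units per OD unit).
#' @param intercept Baseline linear intensity at OD 0.
#' @param noise_cv Multiplicative noise coefficient of variation on linear
#'   intensities.
#' @param seed Integer seed.
#'
#' @return A list with `intensities` (tibble, `sample_id` + ion columns,
#'   linear scale), `meta` (tibble with `sample_id`, `strain`, `od600`,
#'   `series`) and `truth` (per-ion control slopes and the multiplier table).
#' @export
sim_od_course <- function(slope_multipliers = c(control = 1, mutant = 0.5),
                          n_ions = 10L,
                          od_values = seq(0.15, 1.5, length.out = 6),
                          n_series = 3L,
                          base_slope_range = c(2000, 6000),
                          intercept = 1000,
                          noise_cv = 0.05,
                          seed = 1L) {
  if (!"control" %in% names(slope_multipliers)) {
    stop_pt("`slope_multipliers` must include a \"control\" entry.",
            "peroxitools_bad_input")
  }
  if (length(unique(od_values)) < 3) {
    stop_pt("Need >= 3 distinct OD600 values.", "peroxitools_bad_input")
  }
  ions <- sprintf("ion%03d", seq_len(n_ions))
  meta <- tidyr::expand_grid(strain = names(slope_multipliers),
                             series = seq_len(n_series),
                             od600 = od_values)
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  withr_seed(seed, {
    base_slopes <- runif(n_ions, base_slope_range[1], base_slope_range[2])
    mu <- outer(meta$od600, base_slopes) *
      slope_multipliers[meta$strain] + intercept
    noise <- matrix(rnorm(length(mu), mean = 1, sd = noise_cv), nrow(mu))
    intens <- pmax(mu * noise, 0)
  })
  colnames(intens) <- ions
  list(
    intensities = dplyr::bind_cols(tibble(sample_id = meta$sample_id),
                                   as_tibble(intens)),
    meta = dplyr::select(meta, "sample_id", "strain", "series", "od600"),
    truth = list(base_slopes = setNames(base_slopes, ions),
                 slope_multipliers = slope_multipliers)
  )
}

#' Simulate a lipid intensity table with one planted enriched class
#'
#' Generates per-sample lipid intensities for two groups in which only lipids
#' of `planted_class` carry a log2 fold-change; all other lipids are null.
#' Class labels follow the standard lipidomics abbreviations (PC, PE, PI, PS,
#' PG, PA, lyso species, FA, DAG, AcCa), with lyso species distinct classes
#' from their parent phospholipids.
#'
#' @param n_classes Number of lipid classes used (taken from the standard
#'   list in order).
#' @param lipids_per_class Lipids per class (>= 2).
#' @param planted_class Class carrying the effect; must be among the classes
#'   used. Use `effect_log2fc = 0` for a global null table.
#' @param effect_log2fc Planted log2 fold-change (group B relative to
#'   group A) for every lipid of `planted_class`.
#' @param n_per_group Samples per group (>= 3 for downstream testing).
#' @param noise_sd Log2-scale noise SD.
#' @param baseline_log2 Mean lipid baseline (log2 intensity).
#' @param seed Integer seed.
#'
#' @return A list with `table` (tibble: `lipid_id`, `lipid_class`, one column
#'   per sample, linear intensities), `groups` (tibble: `sample_id`,
#'   `group` in `"A"`/`"B"`) and `truth` (planted class and effect).
#' @examples
#' sim_lipid_table(n_classes = 3, planted_class = "PC", seed = 1)$truth
#' @export
sim_lipid_table <- function(n_classes = 8L,
                            lipids_per_class = 6L,
                            planted_class = "PC",
                            effect_log2fc = 0,
                            n_per_group = 4L,
                            noise_sd = 0.3,
                            baseline_log2 = 12,
                            seed = 1L) {
  all_classes <- c("PC", "PE", "PI", "PS", "PG", "PA", "LPC", "LPG",
                   "FA", "DAG", "AcCa")
  if (n_classes < 1 || n_classes > length(all_classes)) {
    stop_pt("`n_classes` must be between 1 and 11.", "peroxitools_bad_input")
  }
  if (lipids_per_class < 2) {
    stop_pt("Need at least 2 lipids per class.", "peroxitools_bad_input")
  }
  classes <- all_classes[seq_len(n_classes)]
  if (effect_log2fc != 0 && !planted_class %in% classes) {
    stop_pt("`planted_class` is not among the classes used.",
            "peroxitools_bad_input")
  }
  lipids <- tidyr::expand_grid(lipid_class = classes,
                               idx = seq_len(lipids_per_class))
  lipids$lipid_id <- sprintf("%s_%02d", lipids$lipid_class, lipids$idx)
  samples <- c(sprintf("A%d", seq_len(n_per_group)),
               sprintf("B%d", seq_len(n_per_group)))
  groups <- tibble(sample_id = samples,
                   group = rep(c("A", "B"), each = n_per_group))
  n_lip <- nrow(lipids)
  withr_seed(seed, {
    base <- rnorm(n_lip, baseline_log2, 1)
    logi <- matrix(rnorm(n_lip * length(samples), sd = noise_sd),
                   n_lip, length(samples), dimnames = list(NULL, samples))
    logi <- logi + base
    b_cols <- groups$group == "B"
    planted <- lipids$lipid_class == planted_class
    logi[planted, b_cols] <- logi[planted, b_cols] + effect_log2fc
  })
  tbl <- dplyr::bind_cols(
    tibble(lipid_id = lipids$lipid_id, lipid_class = lipids$lipid_class),
    as_tibble(2^logi)
  )
  list(
    table = tbl,
    groups = groups,
    truth = list(planted_class = if (effect_log2fc != 0) planted_class else NA,
                 effect_log2fc = effect_log2fc,
                 planted_lipids = lipids$lipid_id[planted])
  )
}
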