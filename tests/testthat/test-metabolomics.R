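make_plate <- function(...) sim_metabolomics_plate(...)

test_that("outlier filter flags exactly the designated samples", {
  pl <- make_plate(n_strains = 8, n_ions = 10, outlier_fraction = 0.1,
                   seed = 5)
  res <- filter_outliers(pl$intensities, pl$meta)
  expect_setequal(res$discarded$sample_id, pl$truth$outliers$sample_id)
  expect_false(any(res$meta$sample_id %in% res$discarded$sample_id))
})

test_that("outlier filter is the identity without planted outliers or with k = Inf", {
  pl <- make_plate(n_strains = 5, n_ions = 8, outlier_fraction = 0, seed = 6)
  res <- filter_outliers(pl$intensities, pl$meta)
  expect_equal(nrow(res$discarded), 0)
  expect_equal(res$intensities, pl$intensities)

  pl2 <- make_plate(n_strains = 5, n_ions = 8, outlier_fraction = 0.2,
                    seed = 7)
  res2 <- filter_outliers(pl2$intensities, pl2$meta, k_mad = Inf)
  expect_equal(nrow(res2$discarded), 0)
})

test_that("drift correction is a near no-op when no drift is planted", {
  pl <- make_plate(n_strains = 6, n_ions = 8, drift_amplitude = 0,
                   od_slope = 0, noise_sd = 0.2, seed = 8)
  corr <- lowess_drift_correct(pl$intensities, pl$meta)
  delta <- abs(log2(as.matrix(corr[-1])) -
                 log2(as.matrix(pl$intensities[-1])))
  # only the flat trend minus the median moves values; stays within noise
  expect_lt(max(delta), 3 * 0.2)
  expect_true(all(as.matrix(corr[-1]) > 0))
})

test_that("drift correction removes the injection-order dependence", {
  pl <- make_plate(n_strains = 10, n_ions = 10, drift_amplitude = 1.5,
                   od_slope = 0, noise_sd = 0.1, seed = 9)
  before <- max_drift_rho(pl$intensities, pl$meta)
  expect_gt(before, 0.5)
  corr <- lowess_drift_correct(pl$intensities, pl$meta)
  expect_lt(max_drift_rho(corr, pl$meta), 0.1)
})

test_that("strain effects survive drift correction", {
  effects <- tibble::tibble(strain = "mut02", ion = "ion004", log2fc = 1.2)
  pl <- make_plate(n_strains = 8, n_ions = 8, drift_amplitude = 1.5,
                   od_slope = 0, noise_sd = 0.05, n_replicates = 6,
                   planted_effects = effects, seed = 10)
  corr <- lowess_drift_correct(pl$intensities, pl$meta)
  est <- direct_log2fc(corr, pl$meta, "mut02", "ion004")
  expect_lt(abs(est - 1.2), 0.1)
})

test_that("OD correction equalizes a pure linear OD effect exactly", {
  set.seed(11)
  n <- 12
  od <- seq(0.8, 2.2, length.out = n)
  base <- 10
  slope <- 0.7
  intens <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           ionA = 2^(base + slope * od))
  meta <- tibble::tibble(sample_id = intens$sample_id, od600 = od)
  corr <- od_correct(intens, meta, reference_od = 1.5)
  expect_equal(log2(corr$ionA), rep(base + slope * 1.5, n), tolerance = 1e-9)
})

test_that("OD correction warns and passes through on constant OD", {
  intens <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           ionA = runif(6, 100, 200))
  meta <- tibble::tibble(sample_id = intens$sample_id, od600 = rep(1.5, 6))
  expect_warning(out <- od_correct(intens, meta))
  expect_equal(out, intens)
})

test_that("drift-then-OD correction does not double-count injection-smooth OD signal", {
  # give OD600 a component that is smooth in injection order: the drift
  # smoother absorbs it, so a naive OD regression would subtract it twice
  set.seed(33)
  n <- 240
  idx <- sample(n)
  od <- 1.5 + 0.25 * sin(pi * idx / n) + rnorm(n, 0, 0.08)
  ions <- sprintf("ion%02d", 1:6)
  logi <- sapply(ions, function(i) 12 + 0.8 * od + rnorm(n, 0, 0.1))
  intens <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", 1:n)),
    tibble::as_tibble(2^logi))
  meta <- tibble::tibble(sample_id = intens$sample_id, od600 = od,
                         injection_index = idx)
  dr <- lowess_drift_correct(intens, meta)
  corr <- od_correct(dr, meta, detrend_span = 0.3)
  rho <- vapply(ions, function(i) {
    abs(cor(rank(corr[[i]]), rank(idx)))
  }, numeric(1))
  expect_lt(max(rho), 0.1)
  # without the covariate detrend the leftover structure is visible
  naive <- od_correct(dr, meta)
  rho_naive <- vapply(ions, function(i) {
    abs(cor(rank(naive[[i]]), rank(idx)))
  }, numeric(1))
  expect_gt(max(rho_naive), max(rho))
})

test_that("strain effects are recovered after OD correction", {
  effects <- tibble::tibble(strain = "mut01", ion = "ion002", log2fc = -1)
  pl <- make_plate(n_strains = 6, n_ions = 6, drift_amplitude = 0,
                   od_slope = 1, noise_sd = 0.05, n_replicates = 6,
                   planted_effects = effects, seed = 12)
  corr <- od_correct(pl$intensities, pl$meta)
  est <- direct_log2fc(corr, pl$meta, "mut01", "ion002")
  expect_lt(abs(est - (-1)), 0.1)
})

test_that("profiles are strain-averaged and z-scored per ion", {
  pl <- make_plate(n_strains = 7, n_ions = 5, seed = 13)
  prof <- metabolome_profiles(pl$intensities, pl$meta)
  ions <- setdiff(names(prof), "strain")
  for (ion in ions) {
    expect_equal(mean(prof[[ion]]), 0, tolerance = 1e-12)
    expect_equal(sd(prof[[ion]]), 1, tolerance = 1e-12)
  }
  # two strains, one ion: z-scores are +/- same magnitude
  two <- make_plate(n_strains = 1, n_ions = 1, seed = 14)
  p2 <- metabolome_profiles(two$intensities, two$meta)
  expect_equal(sum(p2$ion001), 0, tolerance = 1e-12)
  # two points z-scored with the n-1 SD: +/- 1/sqrt(2)
  expect_equal(abs(p2$ion001), rep(sqrt(1 / 2), 2))
})

test_that("identical strains give all-zero profiles with a flag", {
  intens <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                           ionA = rep(100, 4))
  meta <- tibble::tibble(sample_id = intens$sample_id,
                         strain = c("a", "a", "b", "b"))
  prof <- metabolome_profiles(intens, meta)
  expect_equal(prof$ionA, c(0, 0))
  expect_equal(attr(prof, "zero_sd_ions"), "ionA")
  expect_error(metabolome_profiles(intens,
                                   dplyr::mutate(meta, strain = "a")),
               class = "peroxitools_bad_input")
})

test_that("Ward/Manhattan clustering recovers planted opposite profiles", {
  set.seed(15)
  strains <- sprintf("mut%02d", 1:12)
  group <- rep(c(1, 2), each = 6)
  ions <- sprintf("ion%03d", 1:20)
  prof_mat <- matrix(rnorm(12 * 20, sd = 0.3), 12, 20,
                     dimnames = list(strains, ions))
  prof_mat[group == 1, 1:10] <- prof_mat[group == 1, 1:10] + 2
  prof_mat[group == 2, 1:10] <- prof_mat[group == 2, 1:10] - 2
  prof <- dplyr::bind_cols(tibble::tibble(strain = strains),
                           tibble::as_tibble(prof_mat))
  class(prof) <- c("profile_matrix", class(prof))
  cl <- cluster_profiles(prof, k = 2)
  expect_gte(ari(cl$cluster, group), 0.9)
})

test_that("clustering edge cases: singletons, duplicates, bad k", {
  set.seed(16)
  prof <- dplyr::bind_cols(
    tibble::tibble(strain = sprintf("s%d", 1:5)),
    tibble::as_tibble(matrix(rnorm(5 * 6), 5, 6,
                             dimnames = list(NULL, paste0("i", 1:6)))))
  class(prof) <- c("profile_matrix", class(prof))
  cl_all <- cluster_profiles(prof, k = 5)
  expect_equal(sort(unique(cl_all$cluster)), 1:5)

  dup <- prof
  dup[2, -1] <- dup[1, -1]  # duplicate profile
  for (k in 2:4) {
    cl <- cluster_profiles(dup, k = k)
    expect_equal(cl$cluster[1], cl$cluster[2])
  }
  expect_error(cluster_profiles(prof, k = 6),
               class = "peroxitools_bad_input")
})

test_that("dendrogram exports as a readable Newick tree", {
  set.seed(17)
  prof <- dplyr::bind_cols(
    tibble::tibble(strain = sprintf("s%d", 1:6)),
    tibble::as_tibble(matrix(rnorm(6 * 4), 6, 4,
                             dimnames = list(NULL, paste0("i", 1:4)))))
  class(prof) <- c("profile_matrix", class(prof))
  cl <- cluster_profiles(prof, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, prof$strain)
})

test_that("hypergeometric p equals exact subset enumeration on small backgrounds", {
  cases <- list(c(2, 4, 5, 12), c(3, 5, 6, 20), c(1, 3, 10, 15),
                c(4, 6, 8, 25), c(0, 4, 6, 18))
  for (cs in cases) {
    got <- hypergeom_enrichment(cs[1], cs[2], cs[3], cs[4])$p_value
    expect_equal(got, enum_hyper_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # larger background: combinatorial-sum oracle
  expect_equal(hypergeom_enrichment(4, 5, 10, 100)$p_value,
               sum_hyper_p(4, 5, 10, 100), tolerance = 1e-12)
  expect_error(hypergeom_enrichment(6, 5, 10, 100),
               class = "peroxitools_bad_input")
})

test_that("GO term selection follows the largest-enrichment-factor rule", {
  background <- sprintf("g%02d", 1:40)
  sets <- list(
    whole_background = background,          # EF 1, never selected
    tight = background[1:4],
    broad = background[1:16]
  )
  genes <- background[1:6]
  res <- go_enrichment(genes, sets, background)
  expect_equal(res$enrichment_factor[res$term == "whole_background"], 1)
  expect_false(res$selected[res$term == "whole_background"])
  eligible <- res$p_adjusted < 0.05
  if (any(eligible)) {
    best <- res$term[eligible][which.max(res$enrichment_factor[eligible])]
    expect_equal(res$term[res$selected], best)
  }
  # genes outside background rejected
  expect_error(go_enrichment(c("g01", "zzz"), sets, background),
               class = "peroxitools_bad_input")
  # nothing significant -> nothing selected
  null_res <- go_enrichment(background[c(1, 20, 35)],
                            list(a = background[1:20]), background)
  expect_true(is.na(attr(null_res, "selected_term")))
})

test_that("BH adjustment preserves the order of raw p-values", {
  background <- sprintf("g%02d", 1:30)
  sets <- lapply(1:8, function(i) sample(background, 5 + i))
  names(sets) <- paste0("t", 1:8)
  res <- go_enrichment(background[1:7], sets, background)
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
})

test_that("slope fold-changes recover designed slope ratios", {
  oc <- sim_od_course(slope_multipliers = c(control = 1, mutA = 0.5,
                                            mutB = 2),
                      n_ions = 8, noise_cv = 0.03, seed = 18)
  sfc <- slope_fold_change(oc$intensities, oc$meta,
                           mutants = c("mutA", "mutB"), control = "control")
  fc_a <- sfc$fold_change[sfc$strain == "mutA" & !sfc$flagged]
  fc_b <- sfc$fold_change[sfc$strain == "mutB" & !sfc$flagged]
  expect_lt(abs(mean(fc_a) - 0.5) / 0.5, 0.1)
  expect_lt(abs(mean(fc_b) - 2) / 2, 0.1)
})

test_that("proportional series give exact fold-changes; flat controls are flagged", {
  od <- rep(c(0.3, 0.6, 0.9, 1.2), 2)
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                         strain = rep(c("control", "mut"), each = 4),
                         od600 = od)
  intens <- tibble::tibble(
    sample_id = meta$sample_id,
    ion_prop = c(1000 * od[1:4], 2000 * od[5:8]),  # mutant exactly 2x
    ion_flat = c(rep(500, 4), 1000 * od[5:8])      # flat control
  )
  # noiseless series make lm warn about a perfect fit; that is the point
  suppressWarnings(
    sfc <- slope_fold_change(intens, meta, mutants = "mut",
                             control = "control"))
  expect_equal(sfc$fold_change[sfc$ion == "ion_prop"], 2, tolerance = 1e-9)
  expect_true(sfc$flagged[sfc$ion == "ion_flat"])
  expect_true(is.na(sfc$fold_change[sfc$ion == "ion_flat"]))

  # < 3 distinct OD values rejected
  meta2 <- dplyr::mutate(meta, od600 = rep(c(0.5, 1), 4))
  expect_error(slope_fold_change(intens, meta2, "mut", "control"),
               class = "peroxitools_bad_input")
})

test_that("full pipeline recovers planted effects and is idempotent", {
  effects <- tibble::tibble(strain = c("mut01", "mut01", "mut02"),
                            ion = c("ion001", "ion005", "ion003"),
                            log2fc = c(1.5, -1.2, 2))
  pl <- make_plate(n_strains = 10, n_ions = 12, n_replicates = 5,
                   noise_sd = 0.1, outlier_fraction = 0.05,
                   planted_effects = effects, seed = 19)
  norm <- normalize_metabolomics(pl$intensities, pl$meta)
  # every planted outlier is caught; the robust screen is allowed a small
  # false-alarm count on top (3-MAD rules flag ~1 clean sample per ~50)
  expect_true(all(pl$truth$outliers$sample_id %in%
                    norm$discarded$sample_id))
  expect_lte(nrow(norm$discarded), nrow(pl$truth$outliers) + 2)
  for (r in seq_len(nrow(effects))) {
    est <- direct_log2fc(norm$intensities, norm$meta,
                         effects$strain[r], effects$ion[r])
    expect_lt(abs(est - effects$log2fc[r]), 0.15)
  }
  # idempotence: re-running the full pipeline changes little; the robust
  # outlier screen may churn at most a couple of borderline samples
  again <- normalize_metabolomics(norm$intensities, norm$meta)
  expect_lte(nrow(again$discarded), ceiling(0.02 * nrow(norm$meta)))
  common <- intersect(again$intensities$sample_id,
                      norm$intensities$sample_id)
  m1 <- as.matrix(norm$intensities[match(common, norm$intensities$sample_id), -1])
  m2 <- as.matrix(again$intensities[match(common, again$intensities$sample_id), -1])
  # a second smoother pass chases noise at the scale noise_sd / sqrt(f * n)
  expect_lt(max(abs(log2(m2) - log2(m1))),
            6 * 0.1 / sqrt(0.3 * length(common)))
})
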