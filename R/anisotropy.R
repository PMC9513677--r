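#' One-site binding-saturation model
#'
#' Expected anisotropy of a labelled probe at receptor concentration `R`:
#' `A(R) = a_free + (a_bound - a_free) * R / (kd + R)`. Free receptor is
#' approximated by total receptor (no ligand depletion), valid when the
#' probe concentration (nM scale) is far below the dissociation constant
#' (uM scale); see [fit_one_site()] for the depletion-corrected variant.
#'
#' @param receptor_uM Receptor concentration(s), uM, non-negative.
#' @param kd Dissociation constant, uM, positive.
#' @param a_free,a_bound Anisotropy of free and fully bound probe.
#' @return Anisotropy value(s).
#' @examples
#' one_site_model(5.5, kd = 5.5, a_free = 60, a_bound = 160)  # half-saturation
#' @export
one_site_model <- function(receptor_uM, kd, a_free, a_bound) {
  if (any(kd <= 0)) stop_pt("`kd` must be positive.", "peroxitools_bad_input")
  if (any(receptor_uM < 0)) {
    stop_pt("`receptor_uM` must be non-negative.", "peroxitools_bad_input")
  }
  a_free + (a_bound - a_free) * receptor_uM / (kd + receptor_uM)
}

# Fraction bound under ligand depletion (quadratic solution), probe in uM.
depletion_fraction_bound <- function(receptor_uM, kd, probe_uM) {
  s <- probe_uM + receptor_uM + kd
  (s - sqrt(s^2 - 4 * probe_uM * receptor_uM)) / (2 * probe_uM)
}

#' Fit the one-site binding-saturation model to anisotropy titrations
#'
#' Joint nonlinear least squares over all supplied replicates and
#' experiments, with `kd`, `a_free` and `a_bound` shared (replicates are not
#' averaged first, preserving the error structure; set
#' `average_first = TRUE` to fit concentration means instead). Starting
#' values are derivative-free: plateaus from the 10th/90th anisotropy
#' percentiles, `kd` from the concentration nearest half-signal; on
#' non-convergence the fit is restarted from scaled `kd` starts before
#' giving up.
#'
#' @param curves Tibble with columns `receptor_uM`, `anisotropy` (and
#'   optionally `experiment_id`, `replicate_id`, `probe_nM`).
#' @param depletion_corrected Replace the hyperbolic fraction bound with the
#'   quadratic ligand-depletion solution (needs the probe concentration).
#' @param probe_nM Probe concentration (nM) for the depletion correction;
#'   taken from the data when present.
#' @param average_first Average replicate anisotropies per concentration
#'   before fitting.
#' @return An object of class `one_site_fit`: fields `kd`, `kd_stderr`,
#'   `a_free`, `a_bound`, `converged`, `residual_sd`, `n_points`, plus the
#'   underlying `nls` fit. Degenerate input (no dynamic range) returns a
#'   non-converged object with `NA` estimates rather than an error.
#' @examples
#' tc <- sim_titration(kd = 5.5, noise_sd = 0, seed = 1)
#' fit_one_site(tc)
#' @export
fit_one_site <- function(curves, depletion_corrected = FALSE,
                         probe_nM = NULL, average_first = FALSE) {
  need <- c("receptor_uM", "anisotropy")
  if (!all(need %in% names(curves))) {
    stop_pt("`curves` needs columns receptor_uM and anisotropy.",
            "peroxitools_bad_input")
  }
  if (length(unique(curves$receptor_uM)) < 4) {
    stop_pt("Need >= 4 distinct receptor concentrations.",
            "peroxitools_bad_input")
  }
  if (average_first) {
    curves <- curves |>
      dplyr::group_by(.data$receptor_uM) |>
      dplyr::summarise(anisotropy = mean(.data$anisotropy), .groups = "drop")
  }
  a <- curves$anisotropy
  r <- curves$receptor_uM
  rng <- quantile(a, c(0.1, 0.9), names = FALSE)
  if (diff(range(a)) < sqrt(.Machine$double.eps) * max(1, abs(mean(a)))) {
    warn("Anisotropy has no dynamic range; returning a non-converged fit.")
    return(new_one_site_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                            NA_real_, nrow(curves), NULL, curves))
  }
  half <- mean(range(a))
  kd0 <- r[which.min(abs(a - half))]
  if (kd0 <= 0) kd0 <- median(r[r > 0])
  probe_uM <- (probe_nM %||% if ("probe_nM" %in% names(curves)) {
    curves$probe_nM[1]
  } else {
    10
  }) / 1000

  model <- if (depletion_corrected) {
    anisotropy ~ a_free + (a_bound - a_free) *
      depletion_fraction_bound(receptor_uM, kd, probe_uM)
  } else {
    anisotropy ~ a_free + (a_bound - a_free) * receptor_uM / (kd + receptor_uM)
  }
  dat <- tibble(receptor_uM = r, anisotropy = a)
  fit <- NULL
  for (mult in c(1, 0.3, 3, 0.1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        model, data = dat,
        start = list(kd = kd0 * mult, a_free = rng[1], a_bound = rng[2]),
        lower = c(kd = .Machine$double.eps, a_free = -Inf, a_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    warn("One-site fit did not converge after restarts.")
    return(new_one_site_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                            NA_real_, nrow(curves), NULL, curves))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  new_one_site_fit(unname(est["kd"]), se, unname(est["a_free"]),
                   unname(est["a_bound"]), TRUE,
                   sd(resid(fit)), nrow(curves), fit, curves)
}

new_one_site_fit <- function(kd, kd_stderr, a_free, a_bound, converged,
                             residual_sd, n_points, fit, data) {
  structure(
    list(kd = kd, kd_stderr = kd_stderr, a_free = a_free, a_bound = a_bound,
         converged = converged, residual_sd = residual_sd,
         n_points = n_points, fit = fit, data = data),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site binding-saturation fit\n")
  if (!x$converged) {
    cat("  did not converge (", x$n_points, " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  Kd      = %.2f +/- %.2f uM\n", x$kd, x$kd_stderr))
  cat(sprintf("  a_free  = %.2f   a_bound = %.2f\n", x$a_free, x$a_bound))
  cat(sprintf("  %d points, residual SD %.3f\n", x$n_points, x$residual_sd))
  invisible(x)
}

#' @rdname fit_one_site
#' @param x A `one_site_fit`.
#' @param ... Unused.
#' @export
tidy.one_site_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("kd", "a_free", "a_bound"),
                  estimate = NA_real_, std.error = NA_real_))
  }
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = unname(cf[, "Estimate"]),
         std.error = unname(cf[, "Std. Error"]))
}

#' @rdname fit_one_site
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble(kd = x$kd, kd_stderr = x$kd_stderr, a_free = x$a_free,
         a_bound = x$a_bound, residual_sd = x$residual_sd,
         n_points = x$n_points, converged = x$converged)
}

#' Normalize a titration to fraction bound
#'
#' Maps anisotropy onto \[0, 1\] via `(A - a_free) / (a_bound - a_free)`
#' using the fitted plateaus, so curves from different experiments share a
#' scale. Errors when the plateaus are degenerate (no signal).
#'
#' @param curves Titration tibble (`receptor_uM`, `anisotropy`, ...).
#' @param fit A converged [fit_one_site()] object supplying the plateaus.
#' @return `curves` with an added `fraction_bound` column; row order
#'   preserved.
#' @export
normalize_titration <- function(curves, fit) {
  stopifnot(inherits(fit, "one_site_fit"))
  if (!fit$converged || !is.finite(fit$a_free) ||
      isTRUE(all.equal(fit$a_free, fit$a_bound))) {
    stop_pt("Degenerate plateaus: cannot normalize a curve with no signal.",
            "peroxitools_no_signal")
  }
  dplyr::mutate(curves, fraction_bound =
                  (.data$anisotropy - fit$a_free) / (fit$a_bound - fit$a_free))
}

#' @export
autoplot.one_site_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$receptor_uM,
                                         y = .data$anisotropy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Receptor (uM)", y = "Anisotropy",
                  title = if (object$converged) {
                    sprintf("One-site fit: Kd = %.2f +/- %.2f uM",
                            object$kd, object$kd_stderr)
                  } else {
                    "One-site fit (not converged)"
                  })
  if (object$converged) {
    grid <- tibble(receptor_uM = exp(seq(log(max(min(dat$receptor_uM),
                                                 1e-3)),
                                         log(max(dat$receptor_uM)),
                                         length.out = 200)))
    grid$anisotropy <- one_site_model(grid$receptor_uM, object$kd,
                                      object$a_free, object$a_bound)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
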