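#' Run the full factorial isotoxic-prescription sweep
#'
#' For every combination of GTV diameter, GTV-PTV margin and beam
#' arrangement in the benchmark plan-quality table: look up the nominal
#' PTV-size-based prescription, calibrate the radial plan model, evaluate
#' the nominal healthy-brain V12Gy, renormalise isotoxically for the
#' single-, three- and five-fraction constraints, and predict the TCP of
#' each isotoxic scheme. The default sweep covers 8 diameters x 3 margins
#' x 2 beam arrangements = 48 plans.
#'
#' @param protocol A [prescription_protocol()].
#' @param quality_table A [plan_quality_table()].
#' @param constraints Named list of [constraint()]s (default
#'   [srs_constraints()]).
#' @param tcp_mod A [tcp_model()] (default [default_tcp_model()]).
#' @param diameters,margins,beams Factor levels of the sweep.
#' @return A data.frame with one row per configuration: geometry, PTV
#'   volume, nominal prescription and V12Gy, and per scheme the isotoxic
#'   total dose (`idp_gy_*`) and predicted TCP (`tcp_*`). Configurations
#'   missing from the quality table are skipped with a warning.
#' @export
run_sweep <- function(protocol = prescription_protocol(),
                      quality_table = plan_quality_table(),
                      constraints = srs_constraints(),
                      tcp_mod = default_tcp_model(),
                      diameters = seq(0.5, 4, by = 0.5),
                      margins = c(0, 1, 2),
                      beams = c("coplanar", "noncoplanar")) {
  rows <- list()
  for (b in beams) for (m in margins) for (d in diameters) {
    q <- lookup_plan_quality(quality_table, d, m, b)
    if (is.null(q)) next
    tgt <- spherical_target(d, m)
    rx <- prescribe_by_ptv_size(tgt$ptv_volume, protocol)
    nominal <- calibrate_radial_model(tgt, q, rx)
    row <- list(gtv_diameter_cm = d, margin_mm = m, beams = b,
                ptv_volume_cm3 = tgt$ptv_volume,
                nominal_rx_gy = rx,
                nominal_v12_cm3 = healthy_brain_volume_at_dose(nominal, 12))
    for (nm in names(constraints)) {
      res <- idp_dose_analytic(tgt, q, constraints[[nm]], nominal_rx = rx)
      row[[paste0("idp_gy_", nm)]] <- res$idp_dose
      row[[paste0("tcp_", nm)]] <- tcp(tcp_mod, res$scheme)
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Fit an exponential-decay dose-volume relationship
#'
#' Least-squares fit of \eqn{D(V) = d_\infty + d_0 e^{-V / v_0}} to
#' (PTV volume, isotoxic dose) points, the empirical summary of how the
#' achievable isotoxic dose decays with target volume. Three fixed starting
#' points for the decay scale are tried and the converged fit with the
#' smallest residual sum of squares is kept.
#'
#' @param volume PTV volumes in cm^3 (>= 4 points).
#' @param dose Isotoxic doses in Gy.
#' @return An object of class `exp_decay_fit` with elements `coefficients`
#'   (`d_inf`, `d0`, `v0`), `residuals`, `sigma` (residual SD) and the
#'   data.
#' @export
fit_exp_decay <- function(volume, dose) {
  if (length(volume) != length(dose) || length(volume) < 4)
    stop("need at least 4 (volume, dose) points")
  df <- data.frame(v = volume, d = dose)
  spread <- max(dose) - min(dose)
  best <- NULL
  for (v0 in c(2, 10, 30)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        d ~ d_inf + d0 * exp(-v / v0), data = df,
        start = list(d_inf = min(dose), d0 = max(spread, 1e-3), v0 = v0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    if (spread < 1e-8) {  # degenerate flat data: no decay component
      cf <- c(d_inf = mean(dose), d0 = 0, v0 = 1)
      res <- dose - mean(dose)
      return(structure(list(coefficients = cf, residuals = res,
                            sigma = stats::sd(res), volume = volume,
                            dose = dose),
                       class = "exp_decay_fit"))
    }
    stop("exponential decay fit did not converge from any start")
  }
  cf <- stats::coef(best$fit)[c("d_inf", "d0", "v0")]
  res <- stats::resid(best$fit)
  structure(list(coefficients = cf, residuals = as.numeric(res),
                 sigma = stats::sd(as.numeric(res)),
                 volume = volume, dose = dose),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "Exponential decay fit: D(V) = %.3f + %.3f * exp(-V / %.3f) Gy (resid SD %.3f)\n",
    cf["d_inf"], cf["d0"], cf["v0"], x$sigma))
  invisible(x)
}

#' @export
predict.exp_decay_fit <- function(object, volume, ...) {
  cf <- object$coefficients
  unname(cf["d_inf"] + cf["d0"] * exp(-volume / cf["v0"]))
}

#' Compare two exponential-decay fits
#'
#' Two complementary checks that cohort B is described by the curve fitted
#' to cohort A:
#' * a Pearson chi-squared goodness-of-fit statistic
#'   \eqn{\sum (D_B - \hat D_A(V_B))^2 / \hat D_A(V_B)} of B's doses
#'   against A's curve, referred to a chi-squared distribution with
#'   `nrow(B) - 3` degrees of freedom; and
#' * a seed-controlled bootstrap Wald test that the coefficient difference
#'   between the two fits is zero: both datasets are resampled with
#'   replacement, both curves refitted, and the observed coefficient
#'   difference is referred to a chi-squared(3) via the bootstrap
#'   covariance (Moore-Penrose inverse for near-singular cases).
#'
#' The bootstrap is included because a Pearson statistic on continuous
#' doses is a heuristic rather than a calibrated test.
#'
#' @param fitA,fitB [fit_exp_decay()] results.
#' @param dataA,dataB Data.frames with columns `volume` and `dose`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `fit_comparison`: `chisq_stat`, `chisq_df`,
#'   `chisq_p`, `coef_diff`, `wald_stat`, `wald_p`, `n_boot_used`.
#' @export
compare_fits <- function(fitA, fitB, dataA, dataB, n_boot = 2000, seed = 1) {
  stopifnot(inherits(fitA, "exp_decay_fit"), inherits(fitB, "exp_decay_fit"))
  predA <- predict(fitA, dataB$volume)
  if (any(predA <= 0)) stop("predicted doses must be positive for the statistic")
  chisq_stat <- sum((dataB$dose - predA)^2 / predA)
  chisq_df <- nrow(dataB) - 3
  chisq_p <- stats::pchisq(chisq_stat, chisq_df, lower.tail = FALSE)

  dhat <- fitB$coefficients - fitA$coefficients
  deltas <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      ia <- sample.int(nrow(dataA), replace = TRUE)
      ib <- sample.int(nrow(dataB), replace = TRUE)
      fa <- tryCatch(fit_exp_decay(dataA$volume[ia], dataA$dose[ia]),
                     error = function(e) NULL)
      fb <- tryCatch(fit_exp_decay(dataB$volume[ib], dataB$dose[ib]),
                     error = function(e) NULL)
      if (!is.null(fa) && !is.null(fb))
        out[b, ] <- fb$coefficients - fa$coefficients
    }
    out[stats::complete.cases(out), , drop = FALSE]
  })
  if (nrow(deltas) < 10) {
    wald_stat <- NA_real_; wald_p <- NA_real_
  } else {
    S <- stats::cov(deltas)
    wald_stat <- drop(t(dhat) %*% MASS::ginv(S) %*% dhat)
    wald_p <- stats::pchisq(wald_stat, df = 3, lower.tail = FALSE)
  }
  structure(list(chisq_stat = chisq_stat, chisq_df = chisq_df,
                 chisq_p = chisq_p, coef_diff = dhat,
                 wald_stat = wald_stat, wald_p = wald_p,
                 n_boot_used = nrow(deltas)),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: %.3f on %d df, p = %.4f\n",
              x$chisq_stat, x$chisq_df, x$chisq_p))
  if (!is.na(x$wald_stat))
    cat(sprintf("Bootstrap Wald on coefficient difference: %.3f, p = %.4f (%d resamples)\n",
                x$wald_stat, x$wald_p, x$n_boot_used))
  invisible(x)
}

#' Export study results
#'
#' Writes the sweep table as CSV (fixed column order) and, optionally,
#' fitted curves as JSON and summary figures (V12Gy vs diameter by margin
#' and beams; isotoxic dose and TCP vs diameter; TCP by fractionation
#' scheme). Figures require ggplot2 and are skipped with a message when it
#' is unavailable.
#'
#' @param table A [run_sweep()] result.
#' @param dir Output directory (created if missing).
#' @param fits Optional named list of [fit_exp_decay()] results.
#' @param figures Write PNG figures (default FALSE).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(table, dir, fits = NULL, figures = FALSE) {
  if (!nrow(table)) stop("empty results table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("gtv_diameter_cm", "margin_mm", "beams", "ptv_volume_cm3",
            "nominal_rx_gy", "nominal_v12_cm3")
  cols <- c(cols, sort(setdiff(names(table), cols)))
  paths <- file.path(dir, "sweep_results.csv")
  utils::write.csv(table[, cols], paths[1], row.names = FALSE)
  if (!is.null(fits)) {
    fp <- file.path(dir, "exp_decay_fits.json")
    jsonlite::write_json(
      lapply(fits, function(f)
        list(coefficients = as.list(f$coefficients), sigma = f$sigma)),
      fp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, fp)
  }
  if (figures) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      message("ggplot2 not available; figures skipped")
    } else {
      paths <- c(paths, write_study_figures(table, dir))
    }
  }
  invisible(paths)
}

write_study_figures <- function(table, dir) {
  g <- ggplot2::ggplot
  a <- ggplot2::aes
  tab <- table
  tab$margin <- factor(tab$margin_mm)
  p1 <- g(tab, a(x = gtv_diameter_cm, y = nominal_v12_cm3,
                 colour = margin, linetype = beams)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 10, linetype = 3) +
    ggplot2::labs(x = "GTV diameter (cm)",
                  y = expression(V[12 * Gy] ~ (cm^3)),
                  colour = "margin (mm)")
  p2 <- g(tab, a(x = gtv_diameter_cm, y = idp_gy_fx1,
                 colour = margin, linetype = beams)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "GTV diameter (cm)",
                  y = "single-fraction isotoxic dose (Gy)",
                  colour = "margin (mm)")
  long <- do.call(rbind, lapply(c("fx1", "fx3", "fx5"), function(nm)
    data.frame(tab[c("gtv_diameter_cm", "margin_mm", "beams")],
               scheme = nm, tcp = tab[[paste0("tcp_", nm)]],
               margin = tab$margin)))
  p3 <- g(long, a(x = gtv_diameter_cm, y = tcp,
                  colour = scheme, linetype = beams)) +
    ggplot2::geom_line() + ggplot2::facet_wrap(~margin) +
    ggplot2::labs(x = "GTV diameter (cm)", y = "predicted TCP")
  paths <- file.path(dir, c("v12_vs_diameter.png",
                            "idp_dose_vs_diameter.png",
                            "tcp_by_scheme.png"))
  for (i in seq_along(paths))
    ggplot2::ggsave(paths[i], list(p1, p2, p3)[[i]],
                    width = 7, height = 5, dpi = 150)
  paths
}
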