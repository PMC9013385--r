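#' Ordinary least-squares agreement of automated on manual volumes
#'
#' Fits `auto ~ manual` by OLS and reports slope, intercept and R^2 —
#' the regression panel of a method-comparison figure. Perfect agreement is
#' slope 1, intercept 0, R^2 = 1; a slope above 1 with the line above
#' identity indicates proportional overestimation by the automated method.
#'
#' @param manual,auto Equal-length numeric vectors of volumes (mL), n >= 3.
#' @return One-row tibble `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_agreement <- function(manual, auto) {
  if (length(manual) != length(auto)) abort("`manual` and `auto` lengths differ.")
  if (length(manual) < 3L) abort("need at least 3 paired volumes.")
  if (sd(manual) == 0) abort("`manual` volumes have zero variance; regression is degenerate.")
  fit <- lm(auto ~ manual, data = data.frame(manual = manual, auto = auto))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((auto - mean(auto))^2)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    n = length(manual)
  )
}

#' Bland-Altman agreement statistics
#'
#' Differences are `auto - manual`, so a positive bias means the automated
#' method reads high. The 95% limits of agreement use the conventional
#' normal quantile: `bias +/- 1.96 * SD(d)` with the sample (n-1) SD. The
#' paired significance test on the differences is a paired t-test.
#'
#' @param manual,auto Equal-length numeric vectors (mL), n >= 3.
#' @return Object of class `agreement_stats`: tibble row with `slope`,
#'   `intercept`, `r_squared`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `p_value`, `n`, plus the paired data as an attribute for plotting.
#' @export
bland_altman <- function(manual, auto) {
  if (length(manual) != length(auto)) abort("`manual` and `auto` lengths differ.")
  if (length(manual) < 3L) abort("need at least 3 paired volumes.")
  d <- auto - manual
  bias <- mean(d)
  sd_d <- sd(d)
  p <- if (sd_d == 0) {
    if (abs(bias) > 0) 0 else 1  # identical pairs carry no evidence of a shift
  } else {
    t.test(d)$p.value
  }
  reg <- if (sd(manual) > 0) {
    linear_agreement(manual, auto)
  } else {
    tibble::tibble(slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, n = length(manual))
  }
  out <- tibble::tibble(
    slope = reg$slope, intercept = reg$intercept, r_squared = reg$r_squared,
    bias = bias, sd_diff = sd_d,
    loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
    p_value = p, n = length(manual)
  )
  structure(out, class = c("agreement_stats", class(out)),
            pairs = tibble::tibble(manual = manual, auto = auto))
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d  slope=%.3f  intercept=%.3f  R2=%.3f\n  bias=%.3f mL  95%% LoA [%.3f, %.3f] mL  p=%.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$bias, x$loa_low, x$loa_high,
    x$p_value
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x An `agreement_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.agreement_stats <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.agreement_stats <- function(x, ...) tidy.agreement_stats(x)

#' Per-structure agreement report with figures
#'
#' Joins manual and automated volumetry tables on `(case_id, structure)`,
#' computes one [bland_altman()] row per structure, and (optionally) writes a
#' regression scatter and a Bland-Altman plot per structure plus a stats CSV.
#'
#' @param manual_tbl,auto_tbl Volumetry tibbles (`case_id`, `structure`,
#'   `volume_mL`), e.g. from [volumetry_table()].
#' @param structures Structures to analyse (default all four).
#' @param outdir Directory for `agreement_stats.csv` and figures; `NULL`
#'   skips writing.
#' @return Tibble with one row per structure (all [bland_altman()] columns).
#' @export
agreement_report <- function(manual_tbl, auto_tbl, structures = STRUCTURES,
                             outdir = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(manual_tbl, "case_id", "structure", manual = "volume_mL"),
    dplyr::select(auto_tbl, "case_id", "structure", auto = "volume_mL"),
    by = c("case_id", "structure")
  )
  stats <- purrr::map_dfr(structures, function(s) {
    sub <- dplyr::filter(joined, .data$structure == s)
    expected <- unique(manual_tbl$case_id)
    have <- sub$case_id
    missing <- setdiff(expected, have)
    if (length(missing)) {
      abort(paste0("structure `", s, "` lacks paired volumes for cases: ",
                   paste(missing, collapse = ", ")))
    }
    dplyr::bind_cols(tibble::tibble(structure = s),
                     tidy(bland_altman(sub$manual, sub$auto)))
  })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(stats, file.path(outdir, "agreement_stats.csv"))
    for (s in structures) {
      sub <- dplyr::filter(joined, .data$structure == s)
      ba <- bland_altman(sub$manual, sub$auto)
      ggplot2::ggsave(file.path(outdir, paste0("regression_", s, ".png")),
                      plot_regression(ba), width = 5, height = 5, dpi = 120)
      ggplot2::ggsave(file.path(outdir, paste0("bland_altman_", s, ".png")),
                      plot_bland_altman(ba), width = 5, height = 5, dpi = 120)
    }
  }
  stats
}

#' Regression scatter for an agreement result
#'
#' @param x An `agreement_stats` object.
#' @return A ggplot: automated vs manual volumes with the OLS line and the
#'   identity line.
#' @export
plot_regression <- function(x) {
  pairs <- attr(x, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$manual, y = .data$auto)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(
      x = "Manual volume (mL)", y = "Automated volume (mL)",
      title = sprintf("slope = %.3f, intercept = %.2f, R² = %.3f",
                      x$slope, x$intercept, x$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for an agreement result
#'
#' @param x An `agreement_stats` object.
#' @return A ggplot: per-case differences against means with bias and 95%
#'   limits of agreement.
#' @export
plot_bland_altman <- function(x) {
  pairs <- attr(x, "pairs")
  df <- tibble::tibble(mean = (pairs$manual + pairs$auto) / 2,
                       diff = pairs$auto - pairs$manual)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = x$bias, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = c(x$loa_low, x$loa_high),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(
      x = "Mean of methods (mL)", y = "Automated - manual (mL)",
      title = sprintf("bias = %.2f mL, 95%% LoA [%.2f, %.2f] mL",
                      x$bias, x$loa_low, x$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_stats <- function(object, type = c("bland_altman", "regression"),
                                     ...) {
  type <- match.arg(type)
  if (type == "bland_altman") plot_bland_altman(object) else plot_regression(object)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
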