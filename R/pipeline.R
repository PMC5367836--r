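#' Run the full generate-gate-fit-summarise pipeline
#'
#' For every design group, simulates `n_mice` synthetic flow-cytometry
#' samples (event-level data with dead cells), gates them into dot-plot
#' triplets, fits the kinetic model to each sample, and aggregates per-group
#' means and standard deviations. Fully deterministic for a given seed:
#' per-sample sub-seeds are derived as
#' `seed + 7919 * design_row + 104729 * mouse`.
#'
#' @param designs Design tibble, one row per group; see
#'   [signature_presets()].
#' @param protocol Protocol tibble.
#' @param control Fitting settings from [fit_control()].
#' @param dt_h Integration step, hours.
#' @param seed Master integer seed.
#' @param gates Gate boundaries, see [default_gates()].
#' @param ci Compute per-sample confidence intervals (default TRUE).
#'
#' @return A list with `fits` (one row per mouse: metadata, gated triplet,
#'   gating counts, fitted and derived columns) and `groups` (per-group
#'   means/SDs of the reported kinetics, mean labelled percentage and mean
#'   EdU+/dead ratio).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(signature_presets(n_mice = 1, n_events = 20000)[1:2, ],
#'                     control = fit_control(grid_n = 25), seed = 1)
#' res$groups
#' }
run_pipeline <- function(designs = signature_presets(),
                         protocol = default_study_protocol(),
                         control = fit_control(), dt_h = 0.01, seed = 1,
                         gates = default_gates(), ci = TRUE) {
  if (nrow(designs) == 0) {
    empty <- tibble()
    return(list(fits = empty, groups = empty))
  }
  samples <- purrr::map_dfr(seq_len(nrow(designs)), function(d) {
    design <- designs[d, ]
    purrr::map_dfr(seq_len(design$n_mice), function(m) {
      sub_seed <- (seed + 7919L * d + 104729L * m) %% .Machine$integer.max
      events <- generate_events(design, protocol, seed = sub_seed, dt_h = dt_h)
      gated <- gate_events(events, gates)
      bind_cols(
        tibble(sample_id = sprintf("%s_%sM_%s_%s_m%d",
                                   design$strain, design$age_months,
                                   design$organ, design$population, m),
               mouse = m),
        design |> select("strain", "age_months", "organ", "population",
                         "true_a_g", "true_a_m"),
        gated
      )
    })
  })
  fits <- fit_table(samples, protocol, control, dt_h, ci = ci)
  groups <- fits |>
    group_by(.data$strain, .data$age_months, .data$organ, .data$population) |>
    summarise(
      n = n(),
      p_mean_pct_day = mean(.data$p_pct_per_day),
      p_sd_pct_day = stats::sd(.data$p_pct_per_day),
      g1_mean_h = mean(.data$g1_h),
      g1_sd_h = stats::sd(.data$g1_h),
      g2m_mean_h = mean(.data$g2m_h),
      g2m_sd_h = stats::sd(.data$g2m_h),
      intermitotic_mean_days = mean(.data$intermitotic_days),
      intermitotic_sd_days = stats::sd(.data$intermitotic_days),
      pct_edu_mean = mean(.data$pct_labelled),
      edu_dead_ratio_mean = mean(.data$edu_dead_ratio, na.rm = TRUE),
      .groups = "drop"
    )
  list(fits = fits, groups = groups)
}

#' Regress fitted proliferation rate on the labelled percentage
#'
#' Ordinary least squares of the fitted proliferation rate, in fraction of
#' the population per day, on the observed percentage of EdU-positive cells
#' (0-100 scale) at sacrifice. On data from the default 16.5-h protocol this
#' relation is near-functional, which is what makes the labelled percentage
#' alone a usable rate predictor (see [edu_to_rate()]).
#'
#' @param fits Fit table with columns `pct_labelled` and `p_pct_per_day`
#'   (as produced by [fit_table()] or [run_pipeline()]).
#' @return Object of class `edu_regression`: list with `slope` (fraction/day
#'   per percentage point), `intercept` (fraction/day), `r2` and the
#'   underlying `lm` fit.
#' @export
rate_vs_edu_regression <- function(fits) {
  stopifnot(all(c("pct_labelled", "p_pct_per_day") %in% names(fits)))
  if (nrow(fits) < 3 || length(unique(round(fits$pct_labelled, 10))) < 3) {
    abort("need >= 3 samples with distinct labelled percentages",
          class = "edupulse_invalid_parameter")
  }
  if (stats::var(fits$pct_labelled) == 0) {
    abort("labelled percentage has zero variance", class = "edupulse_invalid_parameter")
  }
  d <- tibble(x = fits$pct_labelled, y = fits$p_pct_per_day / 100)
  m <- lm(y ~ x, data = d)
  structure(
    list(slope = unname(coef(m)["x"]),
         intercept = unname(coef(m)["(Intercept)"]),
         r2 = summary(m)$r.squared,
         model = m, data = d),
    class = "edu_regression"
  )
}

#' @export
print.edu_regression <- function(x, ...) {
  cat("<edu_regression> rate (fraction/day) ~ %EdU+\n")
  cat(sprintf("  rate = %.6g + %.6g * pct_edu   (r^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r2, nrow(x$data)))
  invisible(x)
}

#' @rdname rate_vs_edu_regression
#' @param x An `edu_regression`.
#' @param ... Unused.
#' @method tidy edu_regression
#' @export
tidy.edu_regression <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname rate_vs_edu_regression
#' @method glance edu_regression
#' @export
glance.edu_regression <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = nrow(x$data))
}

#' Simulate the single-pulse validation experiment
#'
#' Runs the 1-h pulse / 19-h chase protocol with a cohort initialised as
#' 100% labelled S-phase cells and returns the phase composition within the
#' labelled cells over the 20 h, the readout of the classic whole-thymocyte
#' BrdU chase experiment used to validate the fitted parameters.
#'
#' @inheritParams apply_hypotheses
#' @param dt_h Integration step, hours.
#' @return Tibble `time_h`, `pct_g_labelled`, `pct_s_labelled`,
#'   `pct_m_labelled` (rows sum to 100).
#' @export
#' @examples
#' curves <- baron_validation(0.015, 0.5)
#' curves[curves$time_h == 19, ]
baron_validation <- function(a_g, a_m, dt_h = 0.01) {
  within_labelled_composition(apply_hypotheses(a_g, a_m), baron_protocol(),
                              dt_h = dt_h)
}
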