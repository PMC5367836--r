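#' Fitting configuration
#'
#' Controls the two-dimensional search for `(a_G, a_M)`: a log-spaced grid
#' over a search box followed by optional Nelder-Mead refinement from the
#' best grid node.
#'
#' @param grid_min,grid_max Per-hour bounds of the search box (defaults
#'   `1e-4` and `1`).
#' @param grid_n Grid points per axis, log-spaced (default 60).
#' @param refine Run local Nelder-Mead polish after the grid (default TRUE).
#' @param distance_warn Flag fits whose final Euclidean distance exceeds this
#'   bound (default 0.05, the fit-quality bound the method expects).
#'
#' @return A list of class `edu_fit_control`.
#' @export
fit_control <- function(grid_min = 1e-4, grid_max = 1, grid_n = 60,
                        refine = TRUE, distance_warn = 0.05) {
  if (!(grid_min > 0 && grid_min < grid_max && grid_n >= 2)) {
    abort("need 0 < grid_min < grid_max and grid_n >= 2",
          class = "edupulse_invalid_parameter")
  }
  structure(
    list(grid_min = grid_min, grid_max = grid_max, grid_n = grid_n,
         refine = refine, distance_warn = distance_warn),
    class = "edu_fit_control"
  )
}

as_target_triplet <- function(pct_g_unlabelled, pct_m_unlabelled, pct_labelled) {
  tgt <- c(pct_g_unlabelled, pct_m_unlabelled, pct_labelled)
  if (anyNA(tgt) || any(tgt < 0)) {
    abort("target percentages must be non-negative", class = "edupulse_invalid_parameter")
  }
  if (abs(sum(tgt) - 100) > 0.5) {
    warn(sprintf("target sums to %.2f; renormalising to 100", sum(tgt)))
  }
  100 * tgt / sum(tgt)
}

#' Distance between model and observed dot-plot triplets
#'
#' Simulates the protocol from the unlabelled steady-state initial condition
#' at `(a_g, a_m)` under the hypothesis constraints and returns the Euclidean
#' distance, in percent units, between the simulated and observed triplets
#' `(G unlabelled, G2/M unlabelled, labelled)`.
#'
#' @inheritParams apply_hypotheses
#' @param target One-row data frame (or named list) with `pct_g_unlabelled`,
#'   `pct_m_unlabelled`, `pct_labelled`.
#' @param protocol Protocol tibble from [build_protocol()].
#' @param dt_h Integration step, hours.
#' @return Euclidean distance (percent units).
#' @export
fit_objective <- function(a_g, a_m, target, protocol = default_study_protocol(),
                          dt_h = 0.01) {
  tgt <- as_target_triplet(target$pct_g_unlabelled, target$pct_m_unlabelled,
                           target$pct_labelled)
  sim <- endpoint_triplet(apply_hypotheses(a_g, a_m), protocol, dt_h)
  sqrt(sum((sim - tgt)^2))
}

# log-spaced (a_g, a_m) grid and the endpoint triplet at each node;
# computed once per protocol/control and reused across samples
fit_grid <- function(protocol, control, dt_h) {
  ax <- exp(seq(log(control$grid_min), log(control$grid_max),
                length.out = control$grid_n))
  nodes <- expand.grid(a_g = ax, a_m = ax, KEEP.OUT.ATTRS = FALSE)
  trip <- matrix(NA_real_, nrow(nodes), 3)
  for (i in seq_len(nrow(nodes))) {
    trip[i, ] <- endpoint_triplet(hyp_rates_list(nodes$a_g[i], nodes$a_m[i]),
                                  protocol, dt_h)
  }
  list(nodes = nodes, triplets = trip, axis = ax)
}

# squared-distance objective on log parameters, with a soft box penalty;
# squared distance is smooth at a perfect fit, the reported distance is its root
fit_nll <- function(log_par, tgt, protocol, ctrl, dt_h) {
  par <- exp(log_par)
  lo <- ctrl$grid_min
  hi <- ctrl$grid_max
  pen <- sum(pmax(0, log(lo) - log_par)^2) + sum(pmax(0, log_par - log(hi))^2)
  par <- pmin(pmax(par, lo), hi)
  sim <- endpoint_triplet(hyp_rates_list(par[1], par[2]), protocol, dt_h)
  sum((sim - tgt)^2) + 1e4 * pen
}

fit_one <- function(tgt, protocol, control, dt_h, grid) {
  d2 <- colSums((t(grid$triplets) - tgt)^2)
  # lexicographic tie-break toward the smallest (a_g, a_m)
  best <- order(d2, grid$nodes$a_g, grid$nodes$a_m)[1]
  par <- c(grid$nodes$a_g[best], grid$nodes$a_m[best])
  value <- d2[best]
  if (control$refine) {
    lp <- log(par)
    for (pass in 1:2) { # restart once: Nelder-Mead stalls near machine zero
      opt <- optim(lp, fit_nll, tgt = tgt, protocol = protocol, ctrl = control,
                   dt_h = dt_h, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 500))
      lp <- opt$par
    }
    par <- pmin(pmax(exp(lp), control$grid_min), control$grid_max)
    value <- fit_nll(log(par), tgt, protocol, control, dt_h)
  }
  boundary <- tgt[3] <= 0 ||
    par[1] <= control$grid_min * 1.0001 || par[1] >= control$grid_max * 0.9999 ||
    par[2] <= control$grid_min * 1.0001 || par[2] >= control$grid_max * 0.9999
  list(a_g = par[1], a_m = par[2], distance = sqrt(max(value, 0)),
       boundary_flag = boundary)
}

#' Fit the kinetic model to one dot-plot triplet
#'
#' Estimates `(a_G, a_M)` for a single sample by minimising the Euclidean
#' distance between the simulated and observed triplets: a log-spaced grid
#' search over the box in `control`, then Nelder-Mead refinement on log
#' rates. Derived kinetics (proliferation rate, phase durations,
#' inter-mitotic time) are filled in from the estimates; when `n_events` is
#' supplied, Wald confidence intervals are added via
#' [confidence_intervals()].
#'
#' A fit whose distance exceeds `control$distance_warn` is flagged (not
#' failed); a target with no labelled cells pins `a_G` to the box edge and
#' sets `boundary_flag`, marking the estimate as an upper bound.
#'
#' @param target One-row data frame with `pct_g_unlabelled`,
#'   `pct_m_unlabelled`, `pct_labelled` (percent, summing to ~100).
#' @param protocol Protocol tibble from [build_protocol()].
#' @param control Search settings from [fit_control()].
#' @param dt_h Integration step, hours.
#' @param n_events Optional flow-cytometry event count behind the target;
#'   when given, 95% confidence intervals are computed.
#' @param grid Optional precomputed grid from an earlier fit with the same
#'   protocol/control (internal reuse; normally left NULL).
#'
#' @return An object of class `edu_fit`: a list with `a_g`, `a_m`,
#'   `distance`, `kinetics` (tibble from [derived_kinetics()]), `boundary_flag`,
#'   CI fields when available, and the inputs. Use [tidy()] / [glance()] for
#'   tibble views.
#' @export
#' @examples
#' target <- endpoint_summary(simulate_protocol(apply_hypotheses(0.01, 0.25),
#'                                              default_study_protocol()))
#' fit <- fit_sample(target, control = fit_control(grid_n = 20))
#' glance(fit)
fit_sample <- function(target, protocol = default_study_protocol(),
                       control = fit_control(), dt_h = 0.01,
                       n_events = NULL, grid = NULL) {
  validate_protocol(protocol)
  tgt <- as_target_triplet(target$pct_g_unlabelled, target$pct_m_unlabelled,
                           target$pct_labelled)
  if (is.null(grid)) grid <- fit_grid(protocol, control, dt_h)
  res <- fit_one(tgt, protocol, control, dt_h, grid)
  if (res$distance > control$distance_warn) {
    warn(sprintf("fit distance %.4f exceeds %.3f", res$distance,
                 control$distance_warn))
  }
  fit <- structure(
    list(
      a_g = res$a_g, a_m = res$a_m, distance = res$distance,
      boundary_flag = res$boundary_flag,
      kinetics = derived_kinetics(res$a_g, res$a_m),
      target = tgt, protocol = protocol, control = control, dt_h = dt_h,
      se = NULL, ci = NULL, non_identifiable = FALSE, n_events = NULL
    ),
    class = "edu_fit"
  )
  if (!is.null(n_events)) fit <- confidence_intervals(fit, n_events)
  fit
}

# GLS objective for CI construction: the two free triplet components
# (G unlabelled, G2/M unlabelled) weighted by the inverse 2x2 multinomial
# covariance of the observed proportions at the fitted point. Asymptotically
# -2 log L up to a constant, so cov(theta) = 2 H^{-1}.
ci_objective <- function(par, tgt, w_inv, protocol, dt_h) {
  sim <- endpoint_triplet(hyp_rates_list(par[1], par[2]), protocol, dt_h)
  r <- sim[1:2] - tgt[1:2]
  drop(r %*% w_inv %*% r)
}

ci_hessian <- function(f, x, rel_step = 1e-3) {
  h <- pmax(abs(x) * rel_step, 1e-9)
  H <- matrix(NA_real_, 2, 2)
  f0 <- f(x)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  H[1, 2] <- H[2, 1] <-
    (f(x + e1 + e2) - f(x + e1 - e2) - f(x - e1 + e2) + f(x - e1 - e2)) /
    (4 * h[1] * h[2])
  H
}

#' Hessian-based confidence intervals for a fitted sample
#'
#' Adds 95% Wald intervals to an `edu_fit`. The objective is a generalized
#' least-squares form of the triplet misfit weighted by the multinomial
#' covariance of the observed proportions at `n_events` events; the
#' parameter covariance is twice the inverse of its numerical Hessian at the
#' optimum (variance-covariance matrix method), and the interval for the
#' proliferation rate follows by the delta method with the analytic gradient.
#'
#' @param fit An `edu_fit` from [fit_sample()].
#' @param n_events Number of flow-cytometry events behind the triplet.
#' @return The `edu_fit`, updated with `se` (named: `a_g`, `a_m`,
#'   `p_pct_per_day`) and `ci` (tibble with `term`, `conf.low`, `conf.high`).
#'   A singular Hessian sets `non_identifiable` and widens the intervals to
#'   the search box.
#' @export
confidence_intervals <- function(fit, n_events) {
  stopifnot(inherits(fit, "edu_fit"), n_events >= 1)
  p_hat <- endpoint_triplet(hyp_rates_list(fit$a_g, fit$a_m),
                            fit$protocol, fit$dt_h) / 100
  # 2x2 multinomial covariance of the two free percentage components
  V <- 100^2 / n_events *
    (diag(p_hat[1:2]) - p_hat[1:2] %o% p_hat[1:2])
  box_ci <- function() {
    fit$non_identifiable <- TRUE
    fit$se <- c(a_g = NA_real_, a_m = NA_real_, p_pct_per_day = NA_real_)
    fit$ci <- tibble(
      term = c("a_g_per_h", "a_m_per_h", "p_pct_per_day"),
      conf.low = c(fit$control$grid_min, fit$control$grid_min,
                   24 * proliferation_rate(fit$control$grid_min, fit$control$grid_min)),
      conf.high = c(fit$control$grid_max, fit$control$grid_max,
                    24 * proliferation_rate(fit$control$grid_max, fit$control$grid_max))
    )
    fit$n_events <- n_events
    fit
  }
  w_inv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(w_inv)) return(box_ci())
  f <- function(par) ci_objective(par, fit$target, w_inv, fit$protocol, fit$dt_h)
  H <- ci_hessian(f, c(fit$a_g, fit$a_m))
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) <= 0)) {
    return(box_ci())
  }
  se <- sqrt(diag(cov))
  z <- qnorm(0.975)
  g <- 24 * proliferation_rate_grad(fit$a_g, fit$a_m) # %/day gradient
  se_p <- sqrt(drop(g %*% cov %*% g))
  p_day <- fit$kinetics$p_pct_per_day
  fit$se <- c(a_g = se[1], a_m = se[2], p_pct_per_day = se_p)
  fit$ci <- tibble(
    term = c("a_g_per_h", "a_m_per_h", "p_pct_per_day"),
    conf.low = c(fit$a_g - z * se[1], fit$a_m - z * se[2], p_day - z * se_p),
    conf.high = c(fit$a_g + z * se[1], fit$a_m + z * se[2], p_day + z * se_p)
  )
  fit$n_events <- n_events
  fit
}

#' Fit every sample of a triplet table
#'
#' Data-frame-first batch interface: takes one row per sample with the gated
#' triplet columns (`pct_g_unlabelled`, `pct_m_unlabelled`, `pct_labelled`,
#' optionally `n_events` for confidence intervals, plus any metadata) and
#' appends the fitted and derived columns. The simulation grid is evaluated
#' once and shared across samples.
#'
#' @param data Data frame of samples.
#' @inheritParams fit_sample
#' @param ci Compute confidence intervals when an `n_events` column is
#'   present (default TRUE).
#' @return The input tibble with columns `a_g_per_h`, `a_m_per_h`,
#'   `distance`, `p_pct_per_day`, `p_se`, `p_ci_low`, `p_ci_high`, `g1_h`,
#'   `g2m_h`, `s_h`, `intermitotic_days`, `boundary_flag` appended.
#' @export
fit_table <- function(data, protocol = default_study_protocol(),
                      control = fit_control(), dt_h = 0.01, ci = TRUE) {
  stopifnot(all(c("pct_g_unlabelled", "pct_m_unlabelled", "pct_labelled") %in%
                  names(data)))
  grid <- fit_grid(protocol, control, dt_h)
  with_events <- ci && "n_events" %in% names(data)
  rows <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    fit <- fit_sample(data[i, ], protocol, control, dt_h,
                      n_events = if (with_events) data$n_events[i] else NULL,
                      grid = grid)
    k <- fit$kinetics
    tibble(
      a_g_per_h = fit$a_g, a_m_per_h = fit$a_m, distance = fit$distance,
      p_pct_per_day = k$p_pct_per_day,
      p_se = if (is.null(fit$se)) NA_real_ else unname(fit$se["p_pct_per_day"]),
      p_ci_low = if (is.null(fit$ci)) NA_real_ else
        fit$ci$conf.low[fit$ci$term == "p_pct_per_day"],
      p_ci_high = if (is.null(fit$ci)) NA_real_ else
        fit$ci$conf.high[fit$ci$term == "p_pct_per_day"],
      g1_h = k$g1_duration_h, g2m_h = k$g2m_duration_h, s_h = k$s_duration_h,
      intermitotic_days = k$intermitotic_days,
      boundary_flag = fit$boundary_flag
    )
  })
  bind_cols(as_tibble(data), rows)
}

#' Predict proliferation rate from the labelled fraction
#'
#' Shortcut calibration for the default 16.5-h pulse-chase-pulse protocol:
#' the near-linear relation between the percentage of EdU-positive cells at
#' sacrifice and the fitted proliferation rate,
#' `rate = -0.000884 + 0.0119 * pct_edu` (rate in fraction of the population
#' per day, `pct_edu` on the 0-100 scale). Valid only for this protocol
#' duration; inputs outside [0, 100] warn and extrapolate.
#'
#' @param pct_edu Percentage of EdU-positive cells (0-100). Vectorised.
#' @return Predicted proliferation rate, fraction per day.
#' @export
#' @examples
#' edu_to_rate(38) # ~0.45/day, i.e. ~45 %/day
edu_to_rate <- function(pct_edu) {
  if (any(pct_edu < 0 | pct_edu > 100, na.rm = TRUE)) {
    warn("`pct_edu` outside [0, 100]; extrapolating the calibration line")
  }
  -0.000884 + 0.0119 * pct_edu
}

#' @export
print.edu_fit <- function(x, ...) {
  cat("<edu_fit>\n")
  cat(sprintf("  a_G = %.5g /h, a_M = %.5g /h (distance %.3g)\n",
              x$a_g, x$a_m, x$distance))
  cat(sprintf("  proliferation %.3g %%/day, inter-mitotic %.3g days\n",
              x$kinetics$p_pct_per_day, x$kinetics$intermitotic_days))
  if (x$boundary_flag) cat("  [estimate at search-box boundary]\n")
  if (x$non_identifiable) cat("  [non-identifiable: intervals set to box]\n")
  invisible(x)
}

#' Tidy a fitted sample
#'
#' One row per estimated or derived quantity (`a_g_per_h`, `a_m_per_h`,
#' `p_pct_per_day`) with standard errors and 95% confidence bounds when
#' available.
#'
#' @param x An `edu_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy edu_fit
#' @export
tidy.edu_fit <- function(x, ...) {
  est <- c(x$a_g, x$a_m, x$kinetics$p_pct_per_day)
  out <- tibble(
    term = c("a_g_per_h", "a_m_per_h", "p_pct_per_day"),
    estimate = est,
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se)
  )
  if (!is.null(x$ci)) out <- left_join(out, x$ci, by = "term")
  out
}

#' Model-level summary of a fitted sample
#'
#' @param x An `edu_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fit distance, derived kinetics and flags.
#' @method glance edu_fit
#' @export
glance.edu_fit <- function(x, ...) {
  bind_cols(
    tibble(distance = x$distance, boundary_flag = x$boundary_flag,
           non_identifiable = x$non_identifiable),
    x$kinetics
  )
}
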