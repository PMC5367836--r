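#' Full kinetic parameter set for the six-compartment cycle model
#'
#' Assembles the twelve per-hour cycle rates plus the two labelling parameters
#' into a one-row tibble, the parameter container consumed by
#' [simulate_protocol()] and friends. Unprimed columns describe unlabelled
#' cells in G0/G1, S and G2/M; the `*p` columns are the EdU-labelled
#' counterparts. `a_*` are rates of entry into the next phase, `d_*` rates of
#' exit from the population (death, differentiation, migration).
#'
#' @param a_g,a_s,a_m Entry rates of unlabelled G0/G1, S, G2/M cells into the
#'   next phase, per hour.
#' @param d_g,d_s,d_m Exit rates of unlabelled cells, per hour.
#' @param a_gp,a_sp,a_mp,d_gp,d_sp,d_mp Labelled-cell counterparts; default to
#'   the unlabelled values (labelling assumed kinetically neutral).
#' @param alpha Proportion (0 to 1) of labelled G2/M cells shedding label at
#'   division.
#' @param beta Labelling rate of S-phase cells during a pulse, per hour.
#'   `Inf` selects instant labelling (all S-phase cells transfer to the
#'   labelled compartment at pulse onset).
#'
#' @return A one-row tibble with the 12 rate columns plus `alpha` and `beta`.
#' @seealso [apply_hypotheses()] for the constrained two-parameter version.
#' @export
#' @examples
#' cycle_rates(a_g = 0.01, a_s = 1 / 6.5, a_m = 0.25, d_g = 0.01)
cycle_rates <- function(a_g, a_s, a_m,
                        d_g = 0, d_s = 0, d_m = 0,
                        a_gp = a_g, a_sp = a_s, a_mp = a_m,
                        d_gp = d_g, d_sp = d_s, d_mp = d_m,
                        alpha = 0, beta = Inf) {
  r <- tibble(
    a_g = a_g, a_s = a_s, a_m = a_m,
    d_g = d_g, d_s = d_s, d_m = d_m,
    a_gp = a_gp, a_sp = a_sp, a_mp = a_mp,
    d_gp = d_gp, d_sp = d_sp, d_mp = d_mp,
    alpha = alpha, beta = beta
  )
  validate_rates(r)
  r
}

validate_rates <- function(r) {
  rate_cols <- c("a_g", "a_s", "a_m", "d_g", "d_s", "d_m",
                 "a_gp", "a_sp", "a_mp", "d_gp", "d_sp", "d_mp")
  vals <- unlist(r[rate_cols])
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    abort("all cycle rates must be finite and >= 0", class = "edupulse_invalid_parameter")
  }
  if (is.na(r$alpha) || r$alpha < 0 || r$alpha > 1) {
    abort("`alpha` must lie in [0, 1]", class = "edupulse_invalid_parameter")
  }
  if (is.na(r$beta) || r$beta <= 0) {
    abort("`beta` must be > 0 (use Inf for instant labelling)",
          class = "edupulse_invalid_parameter")
  }
  invisible(r)
}

#' Constrain the model to the study hypotheses
#'
#' Reduces the 14-parameter model to the two free rates `(a_G, a_M)` under the
#' standard constraints: labelling is kinetically neutral (primed = unprimed),
#' S phase lasts 6.5 h (`a_S = 1/6.5`), steady state forces the G0/G1 exit
#' rate to equal the S-entry rate (`d_G = a_G`), no exit during S or G2/M
#' (`d_S = d_M = 0`), no label shedding (`alpha = 0`), and instant labelling
#' (`beta = Inf`).
#'
#' @param a_g Rate of entry into S phase from G0/G1, per hour. Must be > 0.
#' @param a_m Rate of division (exit from G2/M), per hour. Must be > 0.
#' @param s_duration_h Fixed S-phase duration in hours; 6.5 by default.
#'
#' @return A one-row rates tibble as from [cycle_rates()].
#' @export
#' @examples
#' apply_hypotheses(a_g = 0.01, a_m = 0.25)
apply_hypotheses <- function(a_g, a_m, s_duration_h = 6.5) {
  if (!is.numeric(a_g) || !is.numeric(a_m) || length(a_g) != 1 || length(a_m) != 1 ||
      !is.finite(a_g) || !is.finite(a_m) || a_g <= 0 || a_m <= 0) {
    abort("`a_g` and `a_m` must be finite positive scalars",
          class = "edupulse_invalid_parameter")
  }
  cycle_rates(
    a_g = a_g, a_s = 1 / s_duration_h, a_m = a_m,
    d_g = a_g, d_s = 0, d_m = 0,
    alpha = 0, beta = Inf
  )
}

#' Steady-state cell-cycle phase occupancy
#'
#' Closed-form steady-state percentages of cells in each phase (labelled plus
#' unlabelled pooled), on the 0-100 scale:
#' \deqn{(G+G')_{ss} = \frac{200 a_M (a_S + d_S)}{D},\quad
#'       (S+S')_{ss} = \frac{200 a_M a_G}{D},\quad
#'       (M+M')_{ss} = \frac{100 (a_G + d_G)(a_S + d_S)}{D},}
#' with \eqn{D = 2 a_M (a_S + d_S) + 2 a_M a_G + (a_G + d_G)(a_S + d_S)}.
#' The three components sum to 100 by construction.
#'
#' @param rates A rates tibble from [cycle_rates()] or [apply_hypotheses()].
#'
#' @return A one-row tibble with `pct_g`, `pct_s`, `pct_m` (percent of all
#'   cells in G0/G1, S, G2/M).
#' @export
#' @examples
#' steady_state(apply_hypotheses(0.01, 0.25))
steady_state <- function(rates) {
  r <- rates
  den <- 2 * r$a_m * (r$a_s + r$d_s) + 2 * r$a_m * r$a_g +
    (r$a_g + r$d_g) * (r$a_s + r$d_s)
  if (!is.finite(den) || den <= 0) {
    abort("degenerate rates: steady-state denominator is not positive",
          class = "edupulse_degenerate_rates")
  }
  tibble(
    pct_g = 200 * r$a_m * (r$a_s + r$d_s) / den,
    pct_s = 200 * r$a_m * r$a_g / den,
    pct_m = 100 * (r$a_g + r$d_g) * (r$a_s + r$d_s) / den
  )
}

#' Population state at unlabelled steady state
#'
#' Initial condition used for fitting: unlabelled compartments at their
#' steady-state occupancy, labelled compartments empty.
#'
#' @inheritParams steady_state
#' @return Named numeric vector over `G, S, M, Gp, Sp, Mp`, summing to 100.
#' @export
steady_state_initial <- function(rates) {
  ss <- steady_state(rates)
  setNames(c(ss$pct_g, ss$pct_s, ss$pct_m, 0, 0, 0), .compartments)
}

#' Proliferation rate under the study hypotheses
#'
#' The proliferation rate is the percentage of cells completing division per
#' hour, \eqn{p = a_M M + a_{M'} M'}. Under the hypothesis constraints it has
#' the closed form
#' \deqn{p = \frac{200\, a_M a_G}{2 a_M + 13\, a_M a_G + 2 a_G}}
#' (the factor 13 is twice the 6.5-h S-phase duration). Vectorised over both
#' arguments.
#'
#' @inheritParams apply_hypotheses
#' @return Proliferation rate in percent of cells dividing per hour.
#' @export
#' @examples
#' proliferation_rate(0.01, 0.25)        # ~0.905 %/h, i.e. ~21.7 %/day
#' 24 * proliferation_rate(1 / 6.5, 1 / 6.5)
proliferation_rate <- function(a_g, a_m) {
  if (any(!is.finite(a_g)) || any(!is.finite(a_m)) || any(a_g <= 0) || any(a_m <= 0)) {
    abort("`a_g` and `a_m` must be positive", class = "edupulse_invalid_parameter")
  }
  200 * a_m * a_g / (2 * a_m + 13 * a_m * a_g + 2 * a_g)
}

# analytic gradient of proliferation_rate (percent/h) wrt (a_g, a_m);
# p is symmetric in its arguments, hence the mirrored expressions
proliferation_rate_grad <- function(a_g, a_m) {
  den <- (2 * a_m + 13 * a_m * a_g + 2 * a_g)^2
  c(d_a_g = 400 * a_m^2 / den, d_a_m = 400 * a_g^2 / den)
}

#' Derived cell-cycle kinetics
#'
#' Converts the two fitted rates into the quantities reported per sample:
#' proliferation rate per hour and per day, mean phase durations
#' (`1/a_G`, `1/a_M`, fixed S duration) and the inter-mitotic time
#' `100 / p` in days (mean time between successive divisions). Vectorised.
#'
#' @inheritParams apply_hypotheses
#' @return Tibble with `p_pct_per_hour`, `p_pct_per_day`, `g1_duration_h`,
#'   `g2m_duration_h`, `s_duration_h`, `intermitotic_days`.
#' @export
#' @examples
#' derived_kinetics(0.01, 0.25)
derived_kinetics <- function(a_g, a_m, s_duration_h = 6.5) {
  p_h <- proliferation_rate(a_g, a_m)
  tibble(
    p_pct_per_hour = p_h,
    p_pct_per_day = 24 * p_h,
    g1_duration_h = 1 / a_g,
    g2m_duration_h = 1 / a_m,
    s_duration_h = s_duration_h,
    intermitotic_days = 100 / (24 * p_h)
  )
}
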