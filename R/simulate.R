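# Flow matrix A of the six-compartment linear system dx/dt = A x for one
# protocol window. Compartment order: G, S, M, Gp, Sp, Mp.
#
#   dG/dt  = 2 a_M M + 2 alpha a_M' M' - (a_G + d_G) G
#   dS/dt  = a_G G - (a_S + d_S) S - [0, beta] S
#   dM/dt  = a_S S - (a_M + d_M) M
#   dG'/dt = 2 (1 - alpha) a_M' M' - (a_G' + d_G') G'
#   dS'/dt = a_G' G' - (a_S' + d_S') S' + [0, beta] S
#   dM'/dt = a_S' S' - (a_M' + d_M') M'
#
# In instant-labelling mode (beta = Inf) the pulse-window matrix reroutes the
# a_G G influx into S' and leaves S without inflow (S is emptied by the
# transfer event at pulse onset and must stay empty).
flow_matrix <- function(rates, label_on) {
  r <- rates
  # compartment indices: 1 G, 2 S, 3 M, 4 Gp, 5 Sp, 6 Mp
  A <- matrix(0, 6, 6)
  A[1, 3] <- 2 * r$a_m
  A[1, 6] <- 2 * r$alpha * r$a_mp
  A[1, 1] <- -(r$a_g + r$d_g)
  A[2, 2] <- -(r$a_s + r$d_s)
  A[3, 2] <- r$a_s
  A[3, 3] <- -(r$a_m + r$d_m)
  A[4, 6] <- 2 * (1 - r$alpha) * r$a_mp
  A[4, 4] <- -(r$a_gp + r$d_gp)
  A[5, 4] <- r$a_gp
  A[5, 5] <- -(r$a_sp + r$d_sp)
  A[6, 5] <- r$a_sp
  A[6, 6] <- -(r$a_mp + r$d_mp)
  if (label_on && is.infinite(r$beta)) {
    A[5, 1] <- r$a_g
  } else if (label_on) {
    A[2, 1] <- r$a_g
    A[2, 2] <- A[2, 2] - r$beta
    A[5, 2] <- r$beta
  } else {
    A[2, 1] <- r$a_g
  }
  A
}

# One classical 4th-order Runge-Kutta step of the linear system is the matrix
# polynomial T = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24 applied to the state.
rk4_step_matrix <- function(A, dt_h) {
  hA <- dt_h * A
  T <- diag(6)
  P <- diag(6)
  for (k in 1:4) {
    P <- (P %*% hA) / k
    T <- T + P
  }
  T
}

mat_pow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

# instant-labelling transfer: all S moves to Sp
instant_transfer <- function(state) {
  state["Sp"] <- state["Sp"] + state["S"]
  state["S"] <- 0
  state
}

window_steps <- function(protocol, dt_h) {
  len <- protocol$end_h - protocol$start_h
  k <- round(len / dt_h)
  if (any(abs(k * dt_h - len) > 1e-6) || any(k < 1)) {
    abort("`dt_h` must divide every protocol window length",
          class = "edupulse_invalid_parameter")
  }
  k
}

check_state <- function(state, time_h) {
  if (min(state) < -1e-9) {
    abort(
      sprintf("negative compartment (%.3g) at t = %.3f h: integration unstable, reduce `dt_h`",
              min(state), time_h),
      class = "edupulse_numerical_instability"
    )
  }
  pmax(state, 0)
}

#' Simulate the labelling experiment through a protocol
#'
#' Integrates the six-compartment model with classical fixed-step 4th-order
#' Runge-Kutta (default step 0.01 h) piecewise over the protocol windows. In
#' instant-labelling mode (`beta = Inf` in `rates`) every label-on window
#' starts with a discrete transfer of all unlabelled S cells into the
#' labelled S compartment, and during the window the G0/G1 outflux feeds the
#' labelled S compartment directly; with finite `beta` the continuous
#' `beta * S` transfer term applies instead.
#'
#' @param rates One-row rates tibble from [cycle_rates()] or
#'   [apply_hypotheses()] (includes `alpha` and `beta`).
#' @param protocol Protocol tibble from [build_protocol()].
#' @param initial Named state vector over `G, S, M, Gp, Sp, Mp` in percent
#'   units; defaults to [steady_state_initial()] of `rates`.
#' @param dt_h Integration step in hours (default 0.01, i.e. 36 s); must
#'   divide every window length.
#' @param keep `"trajectory"` (default) returns the state at every step;
#'   `"endpoint"` returns only the first and final states, computed with
#'   binary powers of the per-window one-step matrix (the same scheme,
#'   evaluated without materialising intermediate states).
#'
#' @return A tibble of class `edu_trajectory` with columns `time_h`, `G`,
#'   `S`, `M`, `Gp`, `Sp`, `Mp` (percent of initial total).
#' @export
#' @examples
#' traj <- simulate_protocol(apply_hypotheses(0.01, 0.25), default_study_protocol())
#' endpoint_summary(traj)
simulate_protocol <- function(rates, protocol,
                              initial = NULL, dt_h = 0.01,
                              keep = c("trajectory", "endpoint")) {
  keep <- match.arg(keep)
  validate_rates(rates)
  validate_protocol(protocol)
  if (is.null(initial)) initial <- steady_state_initial(rates)
  state <- setNames(as.numeric(initial[.compartments]), .compartments)
  if (anyNA(state) || min(state) < 0) {
    abort("`initial` must be non-negative over G, S, M, Gp, Sp, Mp",
          class = "edupulse_invalid_parameter")
  }
  instant <- is.infinite(rates$beta)
  steps <- window_steps(protocol, dt_h)

  if (keep == "endpoint") {
    for (w in seq_len(nrow(protocol))) {
      if (instant && protocol$label_on[w]) state <- instant_transfer(state)
      T1 <- rk4_step_matrix(flow_matrix(rates, protocol$label_on[w]), dt_h)
      state <- drop(mat_pow(T1, steps[w]) %*% state)
      names(state) <- .compartments
      state <- check_state(state, protocol$end_h[w])
    }
    both <- rbind(as.numeric(initial[.compartments]), state)
    colnames(both) <- .compartments
    out <- bind_cols(
      tibble(time_h = c(0, protocol_sacrifice_h(protocol))),
      as_tibble(both)
    )
    class(out) <- c("edu_trajectory", class(out))
    return(out)
  }

  n_total <- sum(steps) + 1
  states <- matrix(NA_real_, n_total, 6, dimnames = list(NULL, .compartments))
  times <- numeric(n_total)
  states[1, ] <- state
  times[1] <- 0
  row <- 1
  for (w in seq_len(nrow(protocol))) {
    if (instant && protocol$label_on[w]) {
      state <- instant_transfer(state)
      states[row, ] <- state # transfer is part of the pulse-onset instant
    }
    T1 <- rk4_step_matrix(flow_matrix(rates, protocol$label_on[w]), dt_h)
    for (i in seq_len(steps[w])) {
      state <- drop(T1 %*% state)
      names(state) <- .compartments
      state <- check_state(state, protocol$start_h[w] + i * dt_h)
      row <- row + 1
      states[row, ] <- state
      times[row] <- protocol$start_h[w] + i * dt_h
    }
  }
  out <- bind_cols(tibble(time_h = times), as_tibble(states))
  class(out) <- c("edu_trajectory", class(out))
  out
}

#' Endpoint dot-plot triplet of a simulated trajectory
#'
#' Collapses the final state into the three percentages gated on an
#' EdU-by-DNA dot plot: unlabelled G0/G1 (`pct_g_unlabelled`), unlabelled
#' G2/M (`pct_m_unlabelled`) and all EdU-labelled cells (`pct_labelled`,
#' `G' + S' + M'`). When the protocol ends during a pulse the unlabelled S
#' compartment is empty, so the three percentages account for all cells.
#'
#' @param traj Trajectory tibble from [simulate_protocol()].
#' @return One-row tibble `pct_g_unlabelled`, `pct_m_unlabelled`,
#'   `pct_labelled`.
#' @export
endpoint_summary <- function(traj) {
  if (nrow(traj) == 0) abort("empty trajectory", class = "edupulse_invalid_parameter")
  fin <- traj[nrow(traj), ]
  tibble(
    pct_g_unlabelled = fin$G,
    pct_m_unlabelled = fin$M,
    pct_labelled = fin$Gp + fin$Sp + fin$Mp
  )
}

# hypothesis-mode rate set as a plain list (hot-path companion of
# apply_hypotheses, skipping tibble construction)
hyp_rates_list <- function(a_g, a_m, s_duration_h = 6.5) {
  a_s <- 1 / s_duration_h
  list(a_g = a_g, a_s = a_s, a_m = a_m, d_g = a_g, d_s = 0, d_m = 0,
       a_gp = a_g, a_sp = a_s, a_mp = a_m, d_gp = a_g, d_sp = 0, d_mp = 0,
       alpha = 0, beta = Inf)
}

# fast path used by the fitting objective: endpoint triplet (G unlabelled,
# G2/M unlabelled, labelled) as a plain length-3 numeric. `rates` may be the
# usual one-row tibble or a plain list; no tibble is materialised.
endpoint_triplet <- function(rates, protocol, dt_h = 0.01) {
  r <- as.list(rates)
  den <- 2 * r$a_m * (r$a_s + r$d_s) + 2 * r$a_m * r$a_g +
    (r$a_g + r$d_g) * (r$a_s + r$d_s)
  state <- c(200 * r$a_m * (r$a_s + r$d_s), 200 * r$a_m * r$a_g,
             100 * (r$a_g + r$d_g) * (r$a_s + r$d_s), 0, 0, 0) / den
  instant <- is.infinite(r$beta)
  steps <- round((protocol$end_h - protocol$start_h) / dt_h)
  for (w in seq_along(steps)) {
    if (instant && protocol$label_on[w]) {
      state[5] <- state[5] + state[2]
      state[2] <- 0
    }
    T1 <- rk4_step_matrix(flow_matrix(r, protocol$label_on[w]), dt_h)
    state <- drop(mat_pow(T1, steps[w]) %*% state)
  }
  c(state[1], state[3], state[4] + state[5] + state[6])
}

#' Phase composition within the labelled cohort over time
#'
#' Starts a cohort as 100% labelled S-phase cells and tracks the percentage
#' of the labelled cells found in G0/G1, S and G2/M through the protocol --
#' the quantity reported in single-pulse BrdU chase experiments.
#'
#' @inheritParams simulate_protocol
#' @return Tibble with `time_h`, `pct_g_labelled`, `pct_s_labelled`,
#'   `pct_m_labelled`, each row summing to 100.
#' @export
#' @examples
#' within_labelled_composition(apply_hypotheses(0.015, 0.5), baron_protocol())
within_labelled_composition <- function(rates, protocol, dt_h = 0.01) {
  initial <- setNames(c(0, 0, 0, 0, 100, 0), .compartments)
  traj <- simulate_protocol(rates, protocol, initial = initial, dt_h = dt_h)
  total <- traj$Gp + traj$Sp + traj$Mp
  if (any(total <= 0)) {
    abort("labelled cohort is empty: composition undefined",
          class = "edupulse_undefined_composition")
  }
  tibble(
    time_h = traj$time_h,
    pct_g_labelled = 100 * traj$Gp / total,
    pct_s_labelled = 100 * traj$Sp / total,
    pct_m_labelled = 100 * traj$Mp / total
  )
}
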