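# shared fixtures built in code

# forward-simulated noiseless triplet at hypothesis-mode rates
hyp_triplet <- function(a_g, a_m, protocol = default_study_protocol(),
                        dt_h = 0.01) {
  endpoint_summary(simulate_protocol(apply_hypotheses(a_g, a_m), protocol,
                                     dt_h = dt_h, keep = "endpoint"))
}

# the default-protocol fit grid is expensive enough to share across tests
.grid_cache <- new.env(parent = emptyenv())
default_fit_grid <- function() {
  if (is.null(.grid_cache$grid)) {
    .grid_cache$grid <- edupulse:::fit_grid(default_study_protocol(),
                                            fit_control(), 0.01)
  }
  .grid_cache$grid
}

# independent forward-Euler integration of the hypothesis-mode system,
# written from the rate equations (not via the package's flow matrices):
# instant labelling transfers all S to S' at each pulse onset, and during a
# pulse the G0/G1 outflux enters labelled S
euler_oracle_endpoint <- function(a_g, a_m, protocol, dt = 1e-4) {
  a_s <- 1 / 6.5
  ss_den <- 2 * a_m * a_s + 2 * a_m * a_g + 2 * a_g * a_s
  st <- c(G = 200 * a_m * a_s, S = 200 * a_m * a_g, M = 100 * 2 * a_g * a_s,
          Gp = 0, Sp = 0, Mp = 0) / ss_den
  for (w in seq_len(nrow(protocol))) {
    pulse <- protocol$label_on[w]
    if (pulse) {
      st["Sp"] <- st["Sp"] + st["S"]
      st["S"] <- 0
    }
    n <- round((protocol$end_h[w] - protocol$start_h[w]) / dt)
    for (i in seq_len(n)) {
      d <- c(
        G = 2 * a_m * st[["M"]] - 2 * a_g * st[["G"]],
        S = (if (pulse) 0 else a_g * st[["G"]]) - a_s * st[["S"]],
        M = a_s * st[["S"]] - a_m * st[["M"]],
        Gp = 2 * a_m * st[["Mp"]] - 2 * a_g * st[["Gp"]],
        Sp = a_g * st[["Gp"]] + (if (pulse) a_g * st[["G"]] else 0) - a_s * st[["Sp"]],
        Mp = a_s * st[["Sp"]] - a_m * st[["Mp"]]
      )
      st <- st + dt * d
    }
  }
  st
}
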