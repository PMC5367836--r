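#' Solve for the G0/G1 exit rate giving a target proliferation rate
#'
#' Inverts the closed-form proliferation rate for `a_G` at a chosen division
#' rate `a_M`: useful to construct parameter pairs with a prescribed
#' percent-per-day proliferation.
#'
#' @param p_pct_per_day Target proliferation rate, percent of cells per day.
#' @param a_m Division rate, per hour.
#' @return `a_g` in per hour.
#' @export
#' @examples
#' a_g <- rate_for_p_day(32, a_m = 0.5)
#' 24 * proliferation_rate(a_g, 0.5)
rate_for_p_day <- function(p_pct_per_day, a_m) {
  den <- 4800 * a_m - p_pct_per_day * (13 * a_m + 2)
  if (any(den <= 0) || any(p_pct_per_day <= 0) || any(a_m <= 0)) {
    abort("target proliferation is unattainable at this `a_m`",
          class = "edupulse_invalid_parameter")
  }
  2 * p_pct_per_day * a_m / den
}

#' Kinetic signatures of the study design groups
#'
#' Strain-by-age-by-organ-by-population parameter presets spanning the
#' observed kinetic range (roughly 1 to 45 percent of cells dividing per
#' day): fast-cycling young B6 thymocytes (whole thymus ~32 %/day, mature
#' CD8 single-positives ~45 %/day), slow old FVB thymus (~9 %/day), quiet
#' young spleens (~3 %/day) that speed up with age in B6 (~13 %/day), near
#' quiescent naive (CD44lo) T cells, active regulatory T cells, and the
#' early thymic progenitor (DN1) floor around 1 %/day. `true_a_m` encodes
#' plausible G2/M durations (2 h in young B6 thymus up to ~63 h in quiescent
#' splenocytes); `true_a_g` is solved so each group hits its nominal rate.
#'
#' @param n_mice Mice per group (default 4).
#' @param n_events Flow-cytometry events per sample (default 50000).
#' @return Tibble with columns `strain`, `age_months`, `organ`, `population`,
#'   `p_nominal_pct_day`, `true_a_g`, `true_a_m`, `n_mice`, `n_events`,
#'   `dead_frac_apoptotic`, `dead_frac_engulfed`.
#' @export
signature_presets <- function(n_mice = 4, n_events = 50000) {
  d <- dplyr::tribble(
    ~strain, ~age_months, ~organ,   ~population,   ~p_nominal_pct_day, ~true_a_m,
    "B6",    2,  "thymus", "Total",       32,   0.5,
    "B6",    18, "thymus", "Total",       17,   0.3,
    "FVB",   2,  "thymus", "Total",       17,   0.25,
    "FVB",   18, "thymus", "Total",       9,    0.15,
    "B6",    2,  "thymus", "TN",          10,   0.2,
    "FVB",   18, "thymus", "DN1",         1.2,  0.05,
    "B6",    2,  "thymus", "DP CD3lo",    35,   0.5,
    "B6",    2,  "thymus", "DP CD3hi",    20,   0.3,
    "B6",    2,  "thymus", "CD4",         15,   0.25,
    "B6",    2,  "thymus", "CD8",         45,   0.5,
    "B6",    18, "thymus", "CD8",         21,   0.4,
    "FVB",   2,  "thymus", "CD8",         3,    0.1,
    "B6",    2,  "spleen", "Total",       3,    0.05,
    "FVB",   2,  "spleen", "Total",       3,    1 / 30,
    "B6",    18, "spleen", "Total",       13,   0.2,
    "FVB",   18, "spleen", "Total",       7,    0.1,
    "B6",    2,  "spleen", "CD4 CD44lo",  0.9,  1 / 40,
    "B6",    2,  "spleen", "CD8 CD44lo",  0.8,  1 / 63,
    "B6",    2,  "spleen", "CD4 CD44hi",  7,    0.12,
    "B6",    2,  "spleen", "CD8 CD44hi",  8,    0.15,
    "B6",    2,  "spleen", "Treg",        21,   0.3,
    "FVB",   2,  "spleen", "Treg",        1.4,  1 / 40,
    "FVB",   18, "spleen", "CD4 CD44hi",  3,    0.06
  )
  d |>
    mutate(
      true_a_g = rate_for_p_day(.data$p_nominal_pct_day, .data$true_a_m),
      n_mice = n_mice,
      n_events = n_events,
      dead_frac_apoptotic = ifelse(.data$organ == "thymus",
                                   ifelse(grepl("^DP", .data$population), 0.10, 0.02),
                                   0.01),
      dead_frac_engulfed = ifelse(.data$organ == "thymus", 0.01, 0.005)
    )
}

#' Expected dot-plot triplet for a design group
#'
#' Forward-composes the model: hypothesis rates at the group's true
#' parameters, unlabelled steady-state initial condition, simulation through
#' the protocol, endpoint triplet.
#'
#' @param design One-row design tibble (needs `true_a_g`, `true_a_m`).
#' @param protocol Protocol tibble.
#' @param dt_h Integration step, hours.
#' @return One-row triplet tibble as from [endpoint_summary()].
#' @export
expected_triplet <- function(design, protocol = default_study_protocol(),
                             dt_h = 0.01) {
  rates <- apply_hypotheses(design$true_a_g, design$true_a_m)
  endpoint_summary(simulate_protocol(rates, protocol, dt_h = dt_h,
                                     keep = "endpoint"))
}

#' Multinomial counting noise on a triplet
#'
#' One multinomial draw of `n_events` cells over the three dot-plot classes,
#' returned as percentages: the sampling noise a cytometer's finite event
#' count imposes on the gated proportions.
#'
#' @param expected One-row triplet tibble (percent, ~100 total).
#' @param n_events Events to draw.
#' @param seed Integer seed (the draw leaves the global RNG untouched).
#' @return One-row tibble with the three percentage columns plus `n_events`.
#' @export
sample_triplet <- function(expected, n_events, seed) {
  stopifnot(n_events >= 1)
  probs <- c(expected$pct_g_unlabelled, expected$pct_m_unlabelled,
             expected$pct_labelled)
  probs <- probs / sum(probs)
  counts <- with_seed(as.integer(seed), rmultinom(1, n_events, probs)[, 1])
  tibble(
    pct_g_unlabelled = 100 * counts[1] / n_events,
    pct_m_unlabelled = 100 * counts[2] / n_events,
    pct_labelled = 100 * counts[3] / n_events,
    n_events = n_events
  )
}

#' Default gate boundaries for synthetic events
#'
#' DNA content is in linear arbitrary units with 2N at 1 and 4N at 2; EdU
#' intensity is on a log10 scale. Live singlet windows: G0/G1 in
#' `[0.8, 1.2]`, S in `(1.2, 1.8)`, G2/M in `[1.8, 2.2]`; below 0.7 is
#' sub-G0/G1 apoptotic, above 4 is the >4N engulfed-cell region, and
#' `(2.2, 4]` is discarded as aggregates (the stand-in for doublet
#' exclusion). The EdU threshold sits midway between the unlabelled and
#' labelled log-intensity modes.
#'
#' @return Named list of gate boundaries.
#' @export
default_gates <- function() {
  list(
    dna_apoptotic_max = 0.7,
    dna_g1_lo = 0.8, dna_g1_hi = 1.2,
    dna_g2m_lo = 1.8, dna_g2m_hi = 2.2,
    dna_engulfed_min = 4,
    edu_threshold = 1.6
  )
}

# log10-intensity modes of the synthetic EdU signal (>= 10x separation)
.edu_mode_unlabelled <- 1.0
.edu_mode_labelled <- 2.2
.edu_mode_sd <- 0.2
.dna_cv <- 0.05

#' Generate synthetic flow-cytometry events for one sample
#'
#' Draws per-cell (DNA content, EdU intensity) records with the structure
#' the gating assumes: live cells allocated multinomially across the six
#' model compartments at their simulated end-of-protocol proportions, DNA
#' content bell-shaped around 1 (G0/G1) and 2 (G2/M) and spread across
#' (1, 2) for S phase with 5% coefficient-of-variation measurement noise,
#' EdU intensity bimodal in log space, plus sub-G0/G1 apoptotic and >4N
#' engulfed dead events at the design fractions.
#'
#' @param design One-row design tibble (needs `true_a_g`, `true_a_m`,
#'   `n_events`, `dead_frac_apoptotic`, `dead_frac_engulfed`).
#' @param protocol Protocol tibble.
#' @param seed Integer seed; the global RNG is left untouched.
#' @param dt_h Integration step, hours.
#' @return Tibble with `event_id`, `dna_content`, `edu_intensity` (log10
#'   units) and `true_class` (one of G, S, M, Gp, Sp, Mp, apoptotic,
#'   engulfed).
#' @export
generate_events <- function(design, protocol = default_study_protocol(),
                            seed = 1, dt_h = 0.01) {
  rates <- apply_hypotheses(design$true_a_g, design$true_a_m)
  traj <- simulate_protocol(rates, protocol, dt_h = dt_h, keep = "endpoint")
  fin <- traj[nrow(traj), ]
  live_prop <- c(G = fin$G, S = fin$S, M = fin$M,
                 Gp = fin$Gp, Sp = fin$Sp, Mp = fin$Mp)
  live_prop <- pmax(live_prop, 0)
  n_events <- design$n_events
  n_apop <- round(n_events * design$dead_frac_apoptotic)
  n_eng <- round(n_events * design$dead_frac_engulfed)
  n_live <- n_events - n_apop - n_eng

  with_seed(as.integer(seed), {
    counts <- rmultinom(1, n_live, live_prop / sum(live_prop))[, 1]
    cls <- rep(c(names(live_prop), "apoptotic", "engulfed"),
               times = c(counts, n_apop, n_eng))
    n <- length(cls)
    dna <- numeric(n)
    g_like <- cls %in% c("G", "Gp")
    s_like <- cls %in% c("S", "Sp")
    m_like <- cls %in% c("M", "Mp")
    dna[g_like] <- 1 * (1 + .dna_cv * rnorm(sum(g_like)))
    dna[s_like] <- runif(sum(s_like), 1, 2) * (1 + .dna_cv * rnorm(sum(s_like)))
    dna[m_like] <- 2 * (1 + .dna_cv * rnorm(sum(m_like)))
    dna[cls == "apoptotic"] <- runif(sum(cls == "apoptotic"), 0.25, 0.65)
    dna[cls == "engulfed"] <- runif(sum(cls == "engulfed"), 4.2, 6)
    labelled <- cls %in% c("Gp", "Sp", "Mp")
    edu <- rnorm(n, .edu_mode_unlabelled, .edu_mode_sd)
    edu[labelled] <- rnorm(sum(labelled), .edu_mode_labelled, .edu_mode_sd)
    perm <- sample.int(n)
    tibble(
      event_id = seq_len(n),
      dna_content = pmax(dna[perm], 0.01),
      edu_intensity = edu[perm],
      true_class = cls[perm]
    )
  })
}

#' Gate an event table into the dot-plot triplet and death counts
#'
#' Reproduces the manual gating: events below the sub-G0/G1 boundary are
#' apoptotic, above the >4N boundary engulfed, and in `(g2m_hi, engulfed_min]`
#' discarded as aggregates. Among the remaining live events, those above the
#' EdU threshold are labelled regardless of DNA content; unlabelled events
#' are assigned to G0/G1 or G2/M by their DNA windows (unlabelled events in
#' no window are left out of the triplet, as in manual gating). The
#' EdU+/dead ratio -- a performance index of cell expansion -- is the
#' labelled count over the total dead count, `NA` when no dead event exists.
#'
#' @param events Event tibble from [generate_events()] (needs `dna_content`
#'   and `edu_intensity`).
#' @param gates Gate boundaries, see [default_gates()].
#' @return One-row tibble: `pct_g_unlabelled`, `pct_m_unlabelled`,
#'   `pct_labelled`, `n_events` (events behind the triplet), `n_total`,
#'   `n_apoptotic`, `n_engulfed`, `n_aggregate`, `n_unclassified`,
#'   `edu_dead_ratio`.
#' @export
gate_events <- function(events, gates = default_gates()) {
  stopifnot(nrow(events) > 0)
  dna <- events$dna_content
  edu <- events$edu_intensity
  apop <- dna < gates$dna_apoptotic_max
  eng <- dna > gates$dna_engulfed_min
  agg <- !apop & !eng & dna > gates$dna_g2m_hi
  live <- !(apop | eng | agg)
  if (!any(live)) abort("all events are dead or discarded: nothing to gate",
                        class = "edupulse_empty_live")
  lab <- live & edu >= gates$edu_threshold
  g_un <- live & !lab & dna >= gates$dna_g1_lo & dna <= gates$dna_g1_hi
  m_un <- live & !lab & dna >= gates$dna_g2m_lo & dna <= gates$dna_g2m_hi
  n_gated <- sum(lab) + sum(g_un) + sum(m_un)
  n_dead <- sum(apop) + sum(eng)
  tibble(
    pct_g_unlabelled = 100 * sum(g_un) / n_gated,
    pct_m_unlabelled = 100 * sum(m_un) / n_gated,
    pct_labelled = 100 * sum(lab) / n_gated,
    n_events = n_gated,
    n_total = nrow(events),
    n_apoptotic = sum(apop),
    n_engulfed = sum(eng),
    n_aggregate = sum(agg),
    n_unclassified = sum(live) - n_gated,
    edu_dead_ratio = if (n_dead == 0) NA_real_ else sum(lab) / n_dead
  )
}
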