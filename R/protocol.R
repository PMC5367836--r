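#' Build a pulse-chase protocol from an injection schedule
#'
#' Each label injection keeps the label bioavailable for `availability_h`
#' hours (a square window; intra-peritoneal EdU is bioavailable for about one
#' hour). Overlapping or touching windows merge, windows truncate at the
#' sacrifice time, and the gaps between them are chase (label-off) windows.
#' Intervals are half-open `[start, end)`: labelling-onset transfers fire at
#' pulse start.
#'
#' @param injection_times_h Strictly increasing injection times, hours.
#' @param availability_h Hours each injection keeps label bioavailable
#'   (default 1).
#' @param sacrifice_h End of the experiment, hours; must be at or after the
#'   last injection.
#'
#' @return A tibble of contiguous windows with columns `start_h`, `end_h`,
#'   `label_on`, covering `[0, sacrifice_h]` exactly, adjacent windows
#'   alternating in `label_on`.
#' @export
#' @examples
#' # two-hour pulse, fourteen-hour chase, thirty-minute pulse:
#' build_protocol(c(0, 1, 16), availability_h = 1, sacrifice_h = 16.5)
build_protocol <- function(injection_times_h, availability_h = 1, sacrifice_h) {
  t <- injection_times_h
  if (length(t) < 1 || anyNA(t) || any(diff(t) <= 0)) {
    abort("`injection_times_h` must be non-empty and strictly increasing",
          class = "edupulse_invalid_schedule")
  }
  if (availability_h <= 0) {
    abort("`availability_h` must be > 0", class = "edupulse_invalid_schedule")
  }
  if (sacrifice_h < max(t)) {
    abort("`sacrifice_h` must be at or after the last injection",
          class = "edupulse_invalid_schedule")
  }
  on_start <- t
  on_end <- pmin(t + availability_h, sacrifice_h)
  # merge overlapping / touching label-on intervals
  merged <- list(c(on_start[1], on_end[1]))
  for (i in seq_along(on_start)[-1]) {
    last <- merged[[length(merged)]]
    if (on_start[i] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], on_end[i]))
    } else {
      merged[[length(merged)]] <- last
      merged[[length(merged) + 1]] <- c(on_start[i], on_end[i])
    }
  }
  on <- do.call(rbind, merged)
  # interleave chase gaps over [0, sacrifice_h]
  windows <- list()
  cursor <- 0
  for (i in seq_len(nrow(on))) {
    if (on[i, 1] > cursor) {
      windows[[length(windows) + 1]] <- c(cursor, on[i, 1], 0)
    }
    if (on[i, 2] > on[i, 1]) {
      windows[[length(windows) + 1]] <- c(on[i, 1], on[i, 2], 1)
    }
    cursor <- on[i, 2]
  }
  if (cursor < sacrifice_h) {
    windows[[length(windows) + 1]] <- c(cursor, sacrifice_h, 0)
  }
  w <- do.call(rbind, windows)
  tibble(start_h = w[, 1], end_h = w[, 2], label_on = as.logical(w[, 3]))
}

#' The study's default pulse-chase-pulse protocol
#'
#' Injections at 0, 1 and 16 h with 1 h of label bioavailability each and
#' sacrifice half an hour after the last injection: a two-hour pulse, a
#' fourteen-hour chase, and a final thirty-minute pulse ending at 16.5 h.
#'
#' @return A protocol tibble as from [build_protocol()].
#' @export
default_study_protocol <- function() {
  build_protocol(c(0, 1, 16), availability_h = 1, sacrifice_h = 16.5)
}

#' Single-pulse validation protocol
#'
#' One injection at time zero (1-h pulse) followed by a nineteen-hour chase,
#' the classic whole-thymocyte BrdU pulse-chase design used to validate the
#' model against historical data.
#'
#' @return A protocol tibble as from [build_protocol()].
#' @export
baron_protocol <- function() {
  build_protocol(0, availability_h = 1, sacrifice_h = 20)
}

protocol_sacrifice_h <- function(protocol) {
  protocol$end_h[nrow(protocol)]
}

validate_protocol <- function(protocol) {
  stopifnot(all(c("start_h", "end_h", "label_on") %in% names(protocol)))
  if (nrow(protocol) == 0 || protocol$start_h[1] != 0 ||
      any(abs(protocol$end_h[-nrow(protocol)] - protocol$start_h[-1]) > 1e-12) ||
      any(protocol$end_h <= protocol$start_h)) {
    abort("protocol windows must be contiguous, non-empty and start at 0",
          class = "edupulse_invalid_schedule")
  }
  invisible(protocol)
}
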