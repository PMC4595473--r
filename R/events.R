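#' Detect Ca2+ release events in a cluster simulation
#'
#' An event is a maximal interval during which at least one channel is
#' open, with all-closed gaps shorter than \code{t_sep_s} bridged into
#' the same event.  Events with a peak of one simultaneously open channel
#' are blips; events recruiting two or more channels are puffs.  The
#' life time of an event runs from its start to its end; the termination
#' time runs from the first moment the maximum number of channels is open
#' to the end.
#'
#' @param run An \code{"ip3r_cluster_run"}, or a list with \code{t_s} and
#'   \code{n_open} sampled at a fixed interval.
#' @param t_sep_s Maximum all-closed gap bridged within one event (s);
#'   default 0.02.
#' @return Data frame of class \code{"ip3r_events"} with columns
#'   \code{kind} ("puff"/"blip"), \code{start_s}, \code{end_s},
#'   \code{life_ms}, \code{termination_ms}, \code{max_open},
#'   \code{amplitude_ca_uM} and \code{amplitude_dye_uM} (peak Ca2+ and
#'   peak bound dye at the cluster center during the event, when the run
#'   carries those series).  Attribute \code{duration_s} stores the
#'   record length for frequency computations.
#' @export
detect_events <- function(run, t_sep_s = 0.02) {
  t <- run$t_s; n <- run$n_open
  stopifnot(length(t) == length(n), length(t) >= 2L)
  dt <- t[2] - t[1]
  total_dur <- t[length(t)] - t[1] + dt

  act <- n > 0L
  ## bridge all-closed gaps shorter than t_sep_s
  r <- rle(act)
  gap_len <- r$lengths * dt
  bridge <- !r$values & gap_len < t_sep_s
  ## never bridge leading/trailing rest
  if (length(bridge) > 0L) bridge[c(1L, length(bridge))] <- FALSE
  r$values[bridge] <- TRUE
  act2 <- inverse.rle(r)

  r2 <- rle(act2)
  ends <- cumsum(r2$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ev_ix <- which(r2$values)

  rows <- lapply(ev_ix, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- n[i0:i1]
    mo <- max(seg)
    ipk <- i0 + which.max(seg) - 1L
    life <- (i1 - i0 + 1L) * dt
    data.frame(
      kind = if (mo >= 2L) "puff" else "blip",
      start_s = t[i0], end_s = t[i1] + dt,
      life_ms = life * 1000,
      termination_ms = (t[i1] + dt - t[ipk]) * 1000,
      max_open = mo,
      amplitude_ca_uM = if (!is.null(run$ca_center_uM))
        max(run$ca_center_uM[i0:i1]) else NA_real_,
      amplitude_dye_uM = if (!is.null(run$dye_bound_center_uM))
        max(run$dye_bound_center_uM[i0:i1]) else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), start_s = numeric(), end_s = numeric(),
               life_ms = numeric(), termination_ms = numeric(),
               max_open = integer(), amplitude_ca_uM = numeric(),
               amplitude_dye_uM = numeric())
  rownames(out) <- NULL
  structure(out, duration_s = total_dur, t_sep_s = t_sep_s,
            class = c("ip3r_events", "data.frame"))
}

#' Summary statistics of detected release events
#'
#' Frequencies (events per second of record) and distribution summaries
#' of puff amplitude, life time and termination time, and of blip life
#' times, with bootstrap confidence intervals on the frequencies.
#'
#' @param events An \code{"ip3r_events"} data frame.
#' @param n_boot Bootstrap replicates (resampling events) for frequency
#'   confidence intervals.
#' @return List with \code{puff_freq_hz}, \code{blip_freq_hz}, their
#'   bootstrap 95\% intervals, counts, and per-kind summaries of
#'   \code{life_ms}, \code{termination_ms}, \code{max_open},
#'   \code{amplitude_ca_uM}.
#' @export
event_statistics <- function(events, n_boot = 500L) {
  stopifnot(inherits(events, "ip3r_events"))
  dur <- attr(events, "duration_s")
  is_puff <- events$kind == "puff"
  np <- sum(is_puff); nb <- sum(!is_puff)

  ci <- function(count) {
    if (count == 0L) return(c(0, 0))
    stats::quantile(stats::rpois(n_boot, count), c(0.025, 0.975)) / dur
  }
  summ <- function(x) {
    if (!length(x)) return(c(n = 0, mean = NA, median = NA, max = NA))
    c(n = length(x), mean = mean(x), median = stats::median(x),
      max = max(x))
  }
  list(
    duration_s = dur,
    puff_freq_hz = np / dur, blip_freq_hz = nb / dur,
    puff_freq_ci = ci(np), blip_freq_ci = ci(nb),
    n_puffs = np, n_blips = nb,
    puff_life_ms = summ(events$life_ms[is_puff]),
    puff_termination_ms = summ(events$termination_ms[is_puff]),
    puff_max_open = summ(events$max_open[is_puff]),
    puff_amplitude_ca_uM = summ(events$amplitude_ca_uM[is_puff]),
    blip_life_ms = summ(events$life_ms[!is_puff]))
}
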