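#' Burst filtering and modal segmentation parameters
#'
#' Modal segmentation assigns stretches of a gating record to the L, I or
#' H mode from the durations of channel bursts and of burst-terminating
#' gaps: closed gaps of at least \code{t_g_crit} are low-activity (L)
#' stretches; the burst between two such gaps is high-activity (H) if it
#' lasts at least \code{t_b_crit} and intermediate (I) otherwise.  Short
#' closings (ligand-independent flicker) below \code{t_short} are removed
#' first by burst filtering so they neither terminate bursts nor
#' contribute to gaps.
#'
#' @param t_b_crit Critical burst duration (ms); default 100.
#' @param t_g_crit Critical gap duration (ms); default 200.
#' @param t_short Short-closing removal threshold (ms); default 10.
#' @return A named list of the three thresholds.
#' @export
segmentation_params <- function(t_b_crit = 100, t_g_crit = 200,
                                t_short = 10) {
  stopifnot(t_b_crit > 0, t_g_crit > 0, t_short > 0)
  list(t_b_crit = t_b_crit, t_g_crit = t_g_crit, t_short = t_short)
}

## Merge closed dwells shorter than t_short into the surrounding openings.
## Leading/trailing dwells are kept as-is (there is no burst to absorb
## them into on both sides).
filter_short_closings <- function(tr, t_short) {
  con <- tr$conductance; dur <- tr$duration_ms
  n <- length(con)
  drop <- con == 0L & dur < t_short
  drop[1] <- FALSE
  if (!any(drop)) return(data.frame(conductance = con, duration_ms = dur))
  keep_con <- con[!drop]
  keep_dur <- dur
  ## fold each dropped closing into the run containing it, then re-merge
  grp <- cumsum(!drop)
  merged_dur <- as.numeric(tapply(keep_dur, grp, sum))
  con2 <- keep_con
  grp2 <- cumsum(c(1L, diff(con2) != 0L))
  data.frame(
    conductance = as.integer(tapply(con2, grp2, function(x) x[1])),
    duration_ms = as.numeric(tapply(merged_dur, grp2, sum)))
}

#' Segment a gating record into L, I and H mode stretches
#'
#' Applies burst filtering (removal of closings shorter than
#' \code{t_short}) and then the critical-duration rule: closed gaps of at
#' least \code{t_g_crit} become L-mode segments; each maximal interval
#' between gaps (a burst, including its intra-burst closings) becomes an
#' H-mode segment if its duration is at least \code{t_b_crit} and an
#' I-mode segment otherwise.  Ties at the critical duration go to the
#' longer-duration class.
#'
#' @param tr An \code{"ip3r_trace"}.
#' @param seg \code{\link{segmentation_params}}.
#' @return An object of class \code{"ip3r_segmentation"}: a data frame
#'   with columns \code{mode}, \code{start_ms}, \code{end_ms} tiling the
#'   record, with attributes \code{prevalence} (named fractions of time)
#'   and \code{mean_sojourn_ms} (mean segment duration per mode).
#' @examples
#' G <- build_generator(occupancy_params("WT"), flux_params("WT"), 1, 0.1)
#' tr <- to_idealized(simulate_trajectory(G, 20000, seed = 1))
#' segment_modes(tr, segmentation_params())
#' @export
segment_modes <- function(tr, seg = segmentation_params()) {
  validate_trace_basic(tr)
  if (!has_openings(tr)) {
    ## silent record: one quiescent (L) stretch
    out <- data.frame(mode = "L", start_ms = 0,
                      end_ms = sum(tr$duration_ms))
    return(structure(out,
                     prevalence = c(L = 1, I = 0, H = 0),
                     mean_sojourn_ms = c(L = out$end_ms, I = NA, H = NA),
                     class = c("ip3r_segmentation", "data.frame")))
  }
  f <- filter_short_closings(tr, seg$t_short)
  con <- f$conductance; dur <- f$duration_ms
  n <- length(con)
  end <- cumsum(dur); start <- end - dur

  is_gap <- con == 0L & dur >= seg$t_g_crit
  ## bursts: maximal runs of non-gap dwells
  run <- cumsum(c(1L, diff(is_gap) != 0L))
  segs <- lapply(split(seq_len(n), run), function(ix) {
    s <- start[ix[1]]; e <- end[ix[length(ix)]]
    if (is_gap[ix[1]]) {
      mode <- "L"
    } else {
      mode <- if ((e - s) >= seg$t_b_crit) "H" else "I"
    }
    data.frame(mode = mode, start_ms = s, end_ms = e)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  tot <- sum(out$end_ms - out$start_ms)
  prev <- vapply(c(L = "L", I = "I", H = "H"), function(m)
    sum((out$end_ms - out$start_ms)[out$mode == m]) / tot, numeric(1))
  msj <- vapply(c(L = "L", I = "I", H = "H"), function(m) {
    d <- (out$end_ms - out$start_ms)[out$mode == m]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  structure(out, prevalence = prev, mean_sojourn_ms = msj,
            class = c("ip3r_segmentation", "data.frame"))
}

#' Empirical gating summary of a trace ensemble
#'
#' Measures open probability (total open time over total time), mean open
#' and closed dwell times, and - when segmentation parameters are supplied
#' - modal prevalences from \code{\link{segment_modes}}, pooled over the
#' ensemble.  Standard errors come from a per-record bootstrap.
#'
#' @param traces List of \code{"ip3r_trace"} objects at one ligand
#'   condition.
#' @param seg Optional \code{\link{segmentation_params}}; if supplied,
#'   modal prevalences are measured.
#' @param n_boot Bootstrap replicates over records.
#' @return A list of class \code{"ip3r_gating_summary"} with elements
#'   \code{ca}, \code{ip3}, \code{n_records}, \code{Po}, \code{tau_o_ms},
#'   \code{tau_c_ms}, \code{prevalence} (or NULL) and \code{se} (named
#'   standard errors).
#' @export
empirical_summary <- function(traces, seg = NULL, n_boot = 200L) {
  stopifnot(length(traces) >= 1L)
  for (tr in traces) validate_trace_basic(tr)

  measure <- function(trs) {
    open_t <- sum(unlist(lapply(trs, function(x)
      x$duration_ms[x$conductance == 1L])))
    closed_t <- sum(unlist(lapply(trs, function(x)
      x$duration_ms[x$conductance == 0L])))
    od <- unlist(lapply(trs, function(x)
      x$duration_ms[x$conductance == 1L]))
    cd <- unlist(lapply(trs, function(x)
      x$duration_ms[x$conductance == 0L]))
    out <- c(Po = open_t / (open_t + closed_t),
             tau_o_ms = mean(od), tau_c_ms = mean(cd))
    if (!is.null(seg)) {
      prevs <- vapply(trs, function(x)
        attr(segment_modes(x, seg), "prevalence"), numeric(3))
      w <- vapply(trs, function(x) sum(x$duration_ms), numeric(1))
      out <- c(out, pi_L = sum(prevs["L", ] * w) / sum(w),
               pi_I = sum(prevs["I", ] * w) / sum(w),
               pi_H = sum(prevs["H", ] * w) / sum(w))
    }
    out
  }

  est <- measure(traces)
  nrec <- length(traces)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (nrec > 1L && n_boot > 0L) {
    boots <- replicate(n_boot, {
      measure(traces[sample.int(nrec, nrec, replace = TRUE)])
    })
    se <- apply(boots, 1, stats::sd)
  }

  structure(
    list(ca = attr(traces[[1]], "ca"), ip3 = attr(traces[[1]], "ip3"),
         variant = attr(traces[[1]], "variant"), n_records = nrec,
         Po = est[["Po"]], tau_o_ms = est[["tau_o_ms"]],
         tau_c_ms = est[["tau_c_ms"]],
         prevalence = if (!is.null(seg))
           c(L = est[["pi_L"]], I = est[["pi_I"]], H = est[["pi_H"]])
         else NULL,
         se = se),
    class = "ip3r_gating_summary")
}

#' @export
print.ip3r_gating_summary <- function(x, ...) {
  cat(sprintf("Gating summary (%s): %d records at Ca = %g uM, IP3 = %g uM\n",
              x$variant %||% "?", x$n_records, x$ca, x$ip3))
  cat(sprintf("  Po = %.4g (se %.2g), tau_o = %.4g ms, tau_c = %.4g ms\n",
              x$Po, x$se[["Po"]], x$tau_o_ms, x$tau_c_ms))
  if (!is.null(x$prevalence))
    cat(sprintf("  prevalence: L %.3f, I %.3f, H %.3f\n",
                x$prevalence[["L"]], x$prevalence[["I"]],
                x$prevalence[["H"]]))
  invisible(x)
}
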