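#' Simulate a stationary gating trajectory of the twelve-state chain
#'
#' Exact stochastic simulation (exponential sojourns, jump probabilities
#' proportional to the off-diagonal generator entries) at a fixed ligand
#' condition.  The initial state is drawn from the stationary
#' distribution, so the record is stationary from the first dwell.
#'
#' @param G An \code{"ip3r_generator"} (see \code{\link{build_generator}}).
#' @param duration_ms Record length (ms).
#' @param seed Optional integer seed (applied via \code{set.seed}), making
#'   the trajectory reproducible byte-for-byte.
#' @return A data frame of class \code{"ip3r_trajectory"} with columns
#'   \code{state} (name) and \code{sojourn_ms}; attributes carry the
#'   ligand condition and variant.
#' @export
simulate_trajectory <- function(G, duration_ms, seed = NULL) {
  stopifnot(inherits(G, "ip3r_generator"))
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive")
  if (!is.null(seed)) set.seed(seed)
  p0 <- G$Z / sum(G$Z)
  sim <- cpp_sim_ctmc(G$Q, p0, duration_ms)
  out <- data.frame(state = .states$state[sim$state],
                    sojourn_ms = sim$sojourn,
                    stringsAsFactors = FALSE)
  structure(out, ca = G$ca, ip3 = G$ip3, variant = G$variant,
            class = c("ip3r_trajectory", "data.frame"))
}

#' Collapse a state trajectory into an idealized dwell sequence
#'
#' Merges consecutive sojourns that share a conductance class into single
#' dwells (what an idealized single-channel current record resolves), then
#' trims the record to the closed-leading, open-trailing form expected by
#' the dwell-sequence likelihood: a leading open dwell and a trailing
#' closed dwell are dropped.
#'
#' @param traj An \code{"ip3r_trajectory"}.
#' @param record_id Identifier stored with the trace.
#' @return A data frame of class \code{"ip3r_trace"} with columns
#'   \code{conductance} (0 closed, 1 open) and \code{duration_ms},
#'   strictly alternating, starting closed and ending open.  A record
#'   with no opening at all (common at low IP3, where the long-lived
#'   low-activity states trap the channel for far longer than one
#'   record) is returned as a single all-closed dwell covering the whole
#'   record: such silent records carry real weight in empirical open
#'   probabilities and modal prevalences, but cannot enter the
#'   dwell-sequence likelihood (see \code{\link{trace_loglik}}).
#' @export
to_idealized <- function(traj, record_id = 1L) {
  stopifnot(inherits(traj, "ip3r_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory")
  op <- as.integer(.states$conductance[match(traj$state, .states$state)] ==
                     "open")
  grp <- cumsum(c(1L, diff(op) != 0L))
  dur <- as.numeric(tapply(traj$sojourn_ms, grp, sum))
  con <- as.integer(tapply(op, grp, function(x) x[1]))
  if (all(con == 0L)) {
    ## silent record: keep its full duration as one closed dwell
    return(structure(
      data.frame(conductance = 0L, duration_ms = sum(dur)),
      ca = attr(traj, "ca"), ip3 = attr(traj, "ip3"),
      variant = attr(traj, "variant"), record_id = record_id,
      class = c("ip3r_trace", "data.frame")))
  }
  ## trim to start closed, end open
  if (con[1] == 1L) { con <- con[-1]; dur <- dur[-1] }
  n <- length(con)
  if (n > 0L && con[n] == 0L) { con <- con[-n]; dur <- dur[-n] }
  if (length(con) < 2L) {
    ## opening flush against the record edges: nothing usable remains
    warning("record's only openings touch the record boundaries; ",
            "returning it as a silent record")
    return(structure(
      data.frame(conductance = 0L,
                 duration_ms = sum(traj$sojourn_ms[op == 0L])),
      ca = attr(traj, "ca"), ip3 = attr(traj, "ip3"),
      variant = attr(traj, "variant"), record_id = record_id,
      class = c("ip3r_trace", "data.frame")))
  }
  structure(data.frame(conductance = con, duration_ms = dur),
            ca = attr(traj, "ca"), ip3 = attr(traj, "ip3"),
            variant = attr(traj, "variant"), record_id = record_id,
            class = c("ip3r_trace", "data.frame"))
}

#' Does a trace contain at least one complete closed-open dwell pair?
#'
#' Silent (all-closed) records return \code{FALSE}; only records with at
#' least one opening can enter the dwell-sequence likelihood.
#'
#' @param tr An \code{"ip3r_trace"}.
#' @return Logical.
#' @export
has_openings <- function(tr) {
  any(tr$conductance == 1L)
}

#' Simulate an ensemble of idealized gating records
#'
#' Generates \code{n_records} stationary records at one ligand condition,
#' mirroring a patch-clamp gating data set.  Defaults follow the data sets
#' used for model fitting: 30 records for WT and 15 for M146L ensembles,
#' 30 s each, per ligand condition.
#'
#' @param occ,flux Parameter vectors.
#' @param ca,ip3 Ligand condition (uM).
#' @param n_records Number of records.
#' @param record_ms Length of each record (ms).
#' @param seed Integer seed for the whole ensemble.
#' @return List of \code{"ip3r_trace"} objects (records with no complete
#'   closed-open pair are dropped).
#' @export
simulate_traces <- function(occ, flux, ca, ip3,
                            n_records = if (identical(attr(occ, "variant"),
                                                      "M146L")) 15L else 30L,
                            record_ms = 30000, seed = NULL) {
  G <- build_generator(occ, flux, ca, ip3)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    out[[i]] <- to_idealized(simulate_trajectory(G, record_ms),
                             record_id = i)
  }
  out
}

#' Read and write idealized gating records as CSV
#'
#' The trace file is a CSV with columns \code{record_id},
#' \code{conductance} (0 closed / 1 open) and \code{duration_ms}; the
#' ligand condition and variant travel in a YAML sidecar file
#' (\code{<path>.yaml}).
#'
#' @param traces List of \code{"ip3r_trace"} objects sharing one ligand
#'   condition.
#' @param path CSV file path.
#' @return \code{read_traces} returns a list of traces;
#'   \code{write_traces} returns \code{path} invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(length(traces) > 0L)
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(record_id = attr(tr, "record_id"),
               conductance = tr$conductance,
               duration_ms = tr$duration_ms)))
  utils::write.csv(tab, path, row.names = FALSE)
  yaml::write_yaml(list(ca_uM = attr(traces[[1]], "ca"),
                        ip3_uM = attr(traces[[1]], "ip3"),
                        variant = attr(traces[[1]], "variant")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  lapply(split(tab, tab$record_id), function(d) {
    structure(data.frame(conductance = d$conductance,
                         duration_ms = d$duration_ms),
              ca = meta$ca_uM, ip3 = meta$ip3_uM,
              variant = meta$variant, record_id = d$record_id[1],
              class = c("ip3r_trace", "data.frame"))
  })
}

## strict form required by the dwell-sequence likelihood
validate_trace <- function(tr) {
  validate_trace_basic(tr)
  con <- tr$conductance
  if (length(con) < 2L)
    stop("trace must contain at least one closed-open pair ",
         "(silent records cannot enter the likelihood)")
  if (con[1] != 0L || con[length(con)] != 1L)
    stop("trace must start with a closed dwell and end with an open dwell")
  invisible(tr)
}

## lenient form for empirical summaries/segmentation: silent (single
## all-closed dwell) records are allowed
validate_trace_basic <- function(tr) {
  if (!inherits(tr, "ip3r_trace"))
    stop("expected an 'ip3r_trace' object")
  if (any(tr$duration_ms <= 0)) stop("dwell durations must be positive")
  if (any(diff(tr$conductance) == 0L)) stop("dwells must strictly alternate")
  invisible(tr)
}
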