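#' Fit occupancy parameters to measured gating summaries
#'
#' First stage of the two-stage fitting procedure: the occupancy
#' parameters are adjusted so that the model's equilibrium open
#' probability and modal prevalences reproduce the measured
#' (Po, pi_L, pi_I, pi_H) across the supplied ligand conditions, by
#' unweighted least squares.  Optimization runs over log10-transformed
#' free parameters (positivity by construction) with Nelder-Mead and a
#' small number of restarts from the incumbent.
#'
#' For a mutant fit the conventional free set is
#' \code{c("KC32L", "KO14I", "KO24H", "KO24I")} - the four occupancies
#' that differ between variants - with all others pinned.
#'
#' @param summaries A data frame with columns \code{ca}, \code{ip3},
#'   \code{Po}, \code{pi_L}, \code{pi_I}, \code{pi_H} (one row per ligand
#'   condition), or a list of \code{"ip3r_gating_summary"} objects
#'   measured with segmentation.
#' @param start Full occupancy parameter vector used as the starting
#'   point; pinned parameters keep these values.
#' @param free Character vector naming the free occupancy parameters.
#' @param maxit,reltol Optimizer control.
#' @param n_restarts Restarts from the incumbent with a fresh simplex.
#' @return A list of class \code{"ip3r_fit"}: \code{par} (full parameter
#'   vector with attribute \code{variant = "fitted"}), \code{objective}
#'   (final SSE), \code{convergence} (TRUE if the optimizer reported
#'   convergence), \code{iterations}, \code{free}.
#' @export
fit_occupancy <- function(summaries, start = occupancy_params("WT"),
                          free = c("KC32L", "KO14I", "KO24H", "KO24I"),
                          maxit = 5000L, reltol = 1e-10,
                          n_restarts = 3L) {
  tab <- as_summary_table(summaries)
  if (nrow(tab) * 4L < length(free))
    stop("need at least as many data values as free parameters")
  if (!all(free %in% names(start)))
    stop("unknown occupancy parameter in 'free'")
  if ("KC00L" %in% free)
    stop("KC00L is the reference state and must stay fixed at 1")

  obj <- function(logk) {
    par <- start
    par[free] <- 10^logk
    sse <- 0
    for (i in seq_len(nrow(tab))) {
      po <- open_probability(par, tab$ca[i], tab$ip3[i])
      pv <- modal_prevalences(par, tab$ca[i], tab$ip3[i])
      sse <- sse +
        (po - tab$Po[i])^2 + (pv[["L"]] - tab$pi_L[i])^2 +
        (pv[["I"]] - tab$pi_I[i])^2 + (pv[["H"]] - tab$pi_H[i])^2
    }
    sse
  }
  res <- .nm_minimize(obj, log10(start[free]), maxit, reltol, n_restarts)
  par <- start
  par[free] <- 10^res$par
  attr(par, "variant") <- "fitted"
  structure(list(par = par, objective = res$value,
                 convergence = res$convergence == 0L,
                 iterations = res$counts, free = free),
            class = "ip3r_fit")
}

as_summary_table <- function(summaries) {
  if (is.data.frame(summaries)) {
    need <- c("ca", "ip3", "Po", "pi_L", "pi_I", "pi_H")
    if (!all(need %in% names(summaries)))
      stop("summary table must have columns ", paste(need, collapse = ", "))
    return(summaries)
  }
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "ip3r_gating_summary"))
    if (is.null(s$prevalence))
      stop("gating summaries must include modal prevalences ",
           "(measure with segmentation parameters)")
    data.frame(ca = s$ca, ip3 = s$ip3, Po = s$Po,
               pi_L = s$prevalence[["L"]], pi_I = s$prevalence[["I"]],
               pi_H = s$prevalence[["H"]])
  })
  do.call(rbind, rows)
}

#' Fit flux parameters by maximum likelihood
#'
#' Second stage of the fitting procedure: with occupancy parameters held
#' fixed, the free flux parameters are adjusted to minimize the negative
#' total log-likelihood of the dwell-sequence data set
#' (\code{\link{dataset_loglik}}).  Optimization is Nelder-Mead over
#' log10-transformed parameters with restarts from the incumbent.
#'
#' For a mutant fit the conventional free set is
#' \code{c("j0414II", "j2424HH")}; the full 18-parameter fit is obtained
#' with \code{free = names(flux_params("WT"))}.
#'
#' @param traces List of \code{"ip3r_trace"} objects (may span several
#'   ligand conditions of one variant).
#' @param occ Occupancy parameters, held fixed.
#' @param start Full flux vector providing starting values and pinned
#'   values.
#' @param free Character vector naming the free flux parameters.
#' @param maxit,reltol,n_restarts Optimizer control.
#' @return A list of class \code{"ip3r_fit"} with the fitted full flux
#'   vector in \code{par}, the final negative log-likelihood in
#'   \code{objective}, and convergence information.  If the optimizer did
#'   not converge the best-so-far point is returned with
#'   \code{convergence = FALSE}.
#' @export
fit_flux <- function(traces, occ, start = flux_params("WT"),
                     free = c("j0414II", "j2424HH"),
                     maxit = 5000L, reltol = 1e-6, n_restarts = 3L) {
  n_in <- length(traces)
  traces <- Filter(has_openings, traces)
  if (length(traces) < n_in)
    message(n_in - length(traces),
            " silent record(s) excluded from the likelihood")
  if (length(traces) == 0L) stop("empty data set")
  if (!all(free %in% names(start)))
    stop("unknown flux parameter in 'free'")

  obj <- function(logj) {
    par <- start
    par[free] <- 10^logj
    ll <- tryCatch(as.numeric(dataset_loglik(traces, occ, par)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  res <- .nm_minimize(obj, log10(start[free]), maxit, reltol, n_restarts)
  par <- start
  par[free] <- 10^res$par
  attr(par, "variant") <- "fitted"
  structure(list(par = par, objective = res$value,
                 convergence = res$convergence == 0L,
                 iterations = res$counts, free = free),
            class = "ip3r_fit")
}

## Nelder-Mead with restarts from the incumbent (fresh simplex each time;
## deterministic).  One-parameter problems fall back to optimize() over a
## generous bracket, since Nelder-Mead needs dimension >= 2.
.nm_minimize <- function(obj, x0, maxit, reltol, n_restarts) {
  x0 <- as.numeric(x0)
  if (length(x0) == 1L) {
    o <- stats::optimize(function(x) obj(x), c(x0 - 3, x0 + 3),
                         tol = 1e-10)
    return(list(par = o$minimum, value = o$objective, convergence = 0L,
                counts = NA_integer_))
  }
  best <- NULL
  counts <- 0L
  for (r in 0:n_restarts) {
    st <- if (is.null(best)) x0 else best$par
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    counts <- counts + o$counts[["function"]]
    if (is.null(best) || o$value < best$value) best <- o
    if (r > 0 && o$convergence == 0L &&
        abs(o$value - best$value) <= reltol * (abs(best$value) + reltol))
      break
  }
  list(par = best$par, value = best$value, convergence = best$convergence,
       counts = counts)
}

#' @export
print.ip3r_fit <- function(x, ...) {
  cat(sprintf("IP3R parameter fit: %d free parameter(s), objective %.6g, %s\n",
              length(x$free), x$objective,
              if (isTRUE(x$convergence)) "converged" else "NOT converged"))
  print(x$par[x$free])
  invisible(x)
}
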