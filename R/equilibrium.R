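#' Unnormalized state occupancies
#'
#' Evaluates the equilibrium occupancy of each of the twelve states at a
#' ligand condition: \eqn{Z_s = K_s \mathcal{C}^m \mathcal{I}^n}, with
#' \eqn{K_s} the state's occupancy parameter and \eqn{(m, n)} its ligand
#' stoichiometry.  The total occupancy \eqn{Z = Z_o + Z_c} normalizes
#' these weights into probabilities.
#'
#' @param occ Occupancy parameters (\code{\link{occupancy_params}}).
#' @param ca,ip3 Ligand condition (uM).
#' @return Named vector of the twelve unnormalized occupancies in
#'   canonical state order, with attribute \code{Z} (their sum).
#' @examples
#' z <- state_occupancies(occupancy_params("WT"), ca = 1, ip3 = 0.1)
#' sum(z) == attr(z, "Z")
#' @export
state_occupancies <- function(occ, ca, ip3) {
  lig <- ligand_condition(ca, ip3)
  st <- .states
  z <- unname(occ[paste0("K", st$state)]) *
    lig$ca^st$ca_bound * lig$ip3^st$ip3_bound
  names(z) <- st$state
  attr(z, "Z") <- sum(z)
  z
}

#' Equilibrium open probability
#'
#' \eqn{P_o = Z_o / Z}: the summed occupancy of the three open states over
#' the total occupancy.
#'
#' @inheritParams state_occupancies
#' @return Open probability in \code{[0, 1]}.
#' @examples
#' open_probability(occupancy_params("M146L"), ca = 1, ip3 = 0.008)
#' @export
open_probability <- function(occ, ca, ip3) {
  z <- state_occupancies(occ, ca, ip3)
  sum(z[.OPEN]) / sum(z)
}

#' Equilibrium prevalences of the three gating modes
#'
#' \eqn{\pi^M = Z^M / Z}: the fraction of time the channel spends in mode
#' M (L, I or H), where \eqn{Z^M} sums the occupancies of the states in
#' that mode.
#'
#' @inheritParams state_occupancies
#' @return Named vector \code{c(L = , I = , H = )} summing to 1.
#' @export
modal_prevalences <- function(occ, ca, ip3) {
  z <- state_occupancies(occ, ca, ip3)
  Z <- sum(z)
  vapply(c(L = "L", I = "I", H = "H"),
         function(M) sum(z[.MODE_SET[[M]]]) / Z, numeric(1))
}

#' Total equilibrium open-to-closed probability flux
#'
#' The unnormalized flux J from the open aggregate to the closed
#' aggregate, \eqn{J = \sum_{s\,open} Z_s \sum_{u\,closed} Q_{su}}
#' (occupancy units per ms).  At equilibrium the reverse (closed-to-open)
#' flux is identical.
#'
#' @param G An \code{"ip3r_generator"}, or occupancy parameters (then
#'   \code{flux}, \code{ca}, \code{ip3} must be supplied and the generator
#'   is built internally).
#' @param flux,ca,ip3 Used only when \code{G} is a parameter vector.
#' @return The unnormalized flux (ms^-1 times occupancy units).
#' @export
total_flux <- function(G, flux = NULL, ca = NULL, ip3 = NULL) {
  G <- as_generator(G, flux, ca, ip3)
  sum(G$Z[.OPEN] * rowSums(G$QOC))
}

as_generator <- function(G, flux = NULL, ca = NULL, ip3 = NULL) {
  if (inherits(G, "ip3r_generator")) return(G)
  build_generator(G, flux, ca, ip3)
}

#' Mean open and closed times
#'
#' \eqn{\tau_o = Z_o / J} and \eqn{\tau_c = Z_c / J} with J the
#' unnormalized open/closed equilibrium flux, so that
#' \eqn{P_o = \tau_o / (\tau_o + \tau_c)} holds identically.  Undefined
#' when no open state is populated (IP3 = 0), where J = 0.
#'
#' @inheritParams total_flux
#' @return Named vector \code{c(tau_o = , tau_c = )} in ms.
#' @export
mean_times <- function(G, flux = NULL, ca = NULL, ip3 = NULL) {
  G <- as_generator(G, flux, ca, ip3)
  J <- total_flux(G)
  if (J <= 0)
    stop("open/closed flux is zero at this ligand condition; ",
         "mean open/closed times are undefined (requires ip3 > 0)")
  c(tau_o = sum(G$Z[.OPEN]) / J, tau_c = sum(G$Z[.CLOSED]) / J)
}

#' Mean lifetime of a state aggregate
#'
#' The mean sojourn time of the chain in an aggregate X of states,
#' \eqn{\tau^X = Z^X / J_X}, where \eqn{J_X} is the total unnormalized
#' equilibrium flux from states in X to states outside X.  With a gating
#' mode as the aggregate this is the mean modal lifetime.
#'
#' @inheritParams total_flux
#' @param states Aggregate as state names or indices, or one of
#'   \code{"L"}, \code{"I"}, \code{"H"} to select a gating mode.
#' @return Lifetime in ms.
#' @examples
#' G <- build_generator(occupancy_params("WT"), flux_params("WT"), 1, 0.1)
#' modal_lifetime(G, "H")
#' @export
modal_lifetime <- function(G, states, flux = NULL, ca = NULL, ip3 = NULL) {
  G <- as_generator(G, flux, ca, ip3)
  idx <- aggregate_indices(states)
  out <- setdiff(seq_len(12L), idx)
  if (length(out) == 0L)
    stop("aggregate covers the whole chain; nothing leaves it and the ",
         "lifetime is undefined")
  JX <- sum(G$Z[idx] * rowSums(G$Q[idx, out, drop = FALSE]))
  if (JX <= 0)
    stop("no equilibrium flux leaves the aggregate at this ligand condition")
  sum(G$Z[idx]) / JX
}

aggregate_indices <- function(states) {
  if (is.character(states) && length(states) == 1L &&
      states %in% c("L", "I", "H"))
    return(.MODE_SET[[states]])
  if (is.character(states)) {
    idx <- match(states, .states$state)
    if (anyNA(idx)) stop("unknown state name: ",
                         paste(states[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(states)
  if (any(idx < 1L | idx > 12L)) stop("state indices must be in 1..12")
  idx
}

#' Full equilibrium summary at one ligand condition
#'
#' Convenience wrapper collecting all equilibrium observables of the model
#' at one ligand condition: total/open/closed occupancies, open
#' probability, modal prevalences, open/closed flux, mean open and closed
#' times, and the three modal lifetimes.
#'
#' @param occ,flux Parameter vectors (\code{\link{occupancy_params}},
#'   \code{\link{flux_params}}).
#' @param ca,ip3 Ligand condition (uM).
#' @return An object of class \code{"ip3r_equilibrium"} (a list).
#' @export
equilibrium_summary <- function(occ, flux, ca, ip3) {
  G <- build_generator(occ, flux, ca, ip3)
  z <- G$Z
  J <- total_flux(G)
  po <- sum(z[.OPEN]) / sum(z)
  taus <- if (J > 0) mean_times(G) else c(tau_o = NA_real_, tau_c = NA_real_)
  modal <- vapply(c(L = "L", I = "I", H = "H"), function(M) {
    tryCatch(modal_lifetime(G, M), error = function(e) NA_real_)
  }, numeric(1))
  structure(
    list(ca = ca, ip3 = ip3, variant = attr(occ, "variant"),
         Z = sum(z), Zo = sum(z[.OPEN]), Zc = sum(z[.CLOSED]),
         occupancies = z, Po = po,
         prevalence = modal_prevalences(occ, ca, ip3),
         J = J, tau_o = taus[["tau_o"]], tau_c = taus[["tau_c"]],
         tau_mode = modal),
    class = "ip3r_equilibrium")
}

#' @export
print.ip3r_equilibrium <- function(x, ...) {
  cat(sprintf("IP3R equilibrium (%s) at Ca = %g uM, IP3 = %g uM\n",
              x$variant %||% "custom", x$ca, x$ip3))
  cat(sprintf("  Po = %.4g; tau_o = %.4g ms, tau_c = %.4g ms\n",
              x$Po, x$tau_o, x$tau_c))
  cat(sprintf("  prevalence: L %.3f, I %.3f, H %.3f\n",
              x$prevalence[["L"]], x$prevalence[["I"]], x$prevalence[["H"]]))
  cat(sprintf("  modal lifetimes (ms): L %.4g, I %.4g, H %.4g\n",
              x$tau_mode[["L"]], x$tau_mode[["I"]], x$tau_mode[["H"]]))
  invisible(x)
}

#' Equilibrium observables over a ligand grid
#'
#' Evaluates the equilibrium observables on the outer product of a Ca2+
#' grid and an IP3 grid, for export or plotting.
#'
#' @param occ,flux Parameter vectors.
#' @param ca,ip3 Numeric vectors of concentrations (uM).
#' @return A data frame with columns \code{variant}, \code{ca_uM},
#'   \code{ip3_uM}, \code{Po}, \code{pi_L}, \code{pi_I}, \code{pi_H},
#'   \code{tau_o_ms}, \code{tau_c_ms}, \code{tau_L_ms}, \code{tau_I_ms},
#'   \code{tau_H_ms}.
#' @export
equilibrium_sweep <- function(occ, flux, ca, ip3) {
  grid <- expand.grid(ca_uM = ca, ip3_uM = ip3, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- equilibrium_summary(occ, flux, grid$ca_uM[i], grid$ip3_uM[i])
    data.frame(variant = s$variant %||% "custom",
               ca_uM = s$ca, ip3_uM = s$ip3, Po = s$Po,
               pi_L = s$prevalence[["L"]], pi_I = s$prevalence[["I"]],
               pi_H = s$prevalence[["H"]],
               tau_o_ms = s$tau_o, tau_c_ms = s$tau_c,
               tau_L_ms = s$tau_mode[["L"]], tau_I_ms = s$tau_mode[["I"]],
               tau_H_ms = s$tau_mode[["H"]])
  })
  do.call(rbind, rows)
}
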