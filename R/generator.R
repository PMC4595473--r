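#' Harmonic combination of composite-step rates
#'
#' \code{rsr(x, y, ...)} ("reciprocal of sum of reciprocals") is the
#' effective rate of a sequence of first-order steps with rates
#' \code{x, y, ...}: \eqn{1 / (1/x + 1/y + \dots)}.  A zero argument yields
#' zero (the pathway is blocked); infinite arguments drop out.
#'
#' @param ... Positive rates.
#' @return A single rate.
#' @examples
#' rsr(2, 2)  # 1
#' @export
rsr <- function(...) {
  1 / sum(1 / c(...))
}

## The 15 reversible transition pairs of the model with their rate
## formulas.  Each rate is (pair equilibrium flux) / (occupancy of the
## source state); ligand powers common to flux and occupancy are cancelled
## analytically so rates stay finite at zero ligand, where rsr() terms with
## Inf arguments drop out and terms with 0 arguments block the pathway.
## Composite pathways (through implicit low-occupancy intermediates)
## combine their step fluxes harmonically.
##
## C04I <-> C24I and C00L <-> C20L reuse the C04I <-> C24H composite
## pathway flux; their backward rates use the occupancy of the actual
## destination state so that detailed balance with the occupancy vector
## holds exactly.
.rate_table <- function(K, j, C, I) {
  I3 <- I^3
  r0424f <- rsr(j[["j0414"]] * C, j[["j1424"]] * C^2)   # flux / I^4, fwd form
  r0424b <- rsr(j[["j0414"]] / C, j[["j1424"]])         # flux / (C^2 I^4)
  list(
    list("C04I", "C24H", r0424f / K[["KC04I"]], r0424b / K[["KC24H"]]),
    list("C24H", "O24H", j[["j2424HH"]] / K[["KC24H"]], j[["j2424HH"]] / K[["KO24H"]]),
    list("O24H", "C34L", j[["j2434"]] * C / K[["KO24H"]], j[["j2434"]] / K[["KC34L"]]),
    list("C04I", "C34L",
         rsr(j[["j0414IL"]] * C, j[["j1424IL"]] * C^2, j[["j2434IL"]] * C^3) / K[["KC04I"]],
         rsr(j[["j0414IL"]] / C^2, j[["j1424IL"]] / C, j[["j2434IL"]]) / K[["KC34L"]]),
    list("C04I", "O14I", j[["j0414II"]] * C / K[["KC04I"]], j[["j0414II"]] / K[["KO14I"]]),
    list("C24I", "O24I", j[["j2424II"]] / K[["KC24I"]], j[["j2424II"]] / K[["KO24I"]]),
    list("O24I", "O24H", j[["j2424"]] / K[["KO24I"]], j[["j2424"]] / K[["KO24H"]]),
    list("C04I", "C04L", j[["j0404"]] / K[["KC04I"]], j[["j0404"]] / K[["KC04L"]]),
    list("C32L", "C34L", j[["j3334"]] * I^2 / K[["KC32L"]], j[["j3334"]] / K[["KC34L"]]),
    list("C30L", "C32L", j[["j3132"]] * I^2 / K[["KC30L"]], j[["j3132"]] / K[["KC32L"]]),
    list("C20L", "C30L", j[["j2030"]] * C / K[["KC20L"]], j[["j2030"]] / K[["KC30L"]]),
    list("C00L", "C04I",
         rsr(j[["j0001"]] * I, j[["j0304"]] * I^4),
         rsr(j[["j0001"]] / I3, j[["j0304"]]) / K[["KC04I"]]),
    list("C20L", "C24H",
         rsr(j[["j2021"]] * I, j[["j2324"]] * I^4),
         rsr(j[["j2021"]] / I3, j[["j2324"]]) * K[["KC20L"]] / K[["KC24H"]]),
    list("C04I", "C24I", r0424f / K[["KC04I"]], r0424b / K[["KC24I"]]),
    list("C00L", "C20L", r0424f / K[["KC04I"]],
         r0424b / (K[["KC04I"]] * K[["KC20L"]]))
  )
}

#' Assemble the generator matrix of the twelve-state chain
#'
#' Builds the 12 x 12 transition-rate (generator) matrix Q of the gating
#' model at a fixed ligand condition.  Every transition rate is the
#' reversible pair's equilibrium flux divided by the occupancy of the
#' source state, \eqn{r(S \to U) = \phi_{SU} / Z_S}, so the chain
#' satisfies detailed balance with respect to the occupancy vector by
#' construction, and the stationary distribution of Q equals the
#' normalized occupancy vector exactly.  Composite pathways (transitions
#' through low-occupancy intermediate states not represented explicitly)
#' combine their single-step fluxes harmonically via \code{\link{rsr}}.
#'
#' The \code{C04I <-> C24I} and \code{C00L <-> C20L} transitions reuse the
#' composite pathway flux of \code{C04I <-> C24H}; their backward rates
#' divide by the occupancy of the true destination state (numerically
#' within 1e-4 of dividing by \code{KC24H}, since
#' \code{KC24I} \eqn{\approx} \code{KC24H} \eqn{\approx}
#' \code{KC04I * KC20L}).
#'
#' Rows and columns follow the canonical state order of
#' \code{\link{ip3r_states}} (open states first), so the open/closed block
#' partition is \code{Q[1:3, 1:3]} etc.
#'
#' @param occ Occupancy parameters (\code{\link{occupancy_params}}).
#' @param flux Flux parameters (\code{\link{flux_params}}).
#' @param ca,ip3 Ligand condition (uM).
#' @return An object of class \code{"ip3r_generator"}: a list with the
#'   matrix \code{Q} (ms^-1), blocks \code{QOO}, \code{QOC}, \code{QCO},
#'   \code{QCC}, the unnormalized occupancy vector \code{Z} evaluated at
#'   the same condition, and the ligand condition.
#' @examples
#' G <- build_generator(occupancy_params("WT"), flux_params("WT"),
#'                      ca = 1, ip3 = 0.1)
#' range(rowSums(G$Q))  # rows sum to zero
#' @export
build_generator <- function(occ, flux, ca, ip3) {
  lig <- ligand_condition(ca, ip3)
  st <- .states
  z <- state_occupancies(occ, lig$ca, lig$ip3)

  Q <- matrix(0, 12L, 12L, dimnames = list(st$state, st$state))
  for (p in .rate_table(occ, flux, lig$ca, lig$ip3)) {
    a <- p[[1]]; b <- p[[2]]; fwd <- p[[3]]; bwd <- p[[4]]
    if (!is.finite(fwd) || !is.finite(bwd) || fwd < 0 || bwd < 0)
      stop(sprintf("non-finite rate for transition %s <-> %s at ca = %g, ip3 = %g",
                   a, b, lig$ca, lig$ip3))
    Q[a, b] <- fwd
    Q[b, a] <- bwd
  }
  diag(Q) <- -rowSums(Q)

  structure(
    list(Q = Q,
         QOO = Q[.OPEN, .OPEN, drop = FALSE],
         QOC = Q[.OPEN, .CLOSED, drop = FALSE],
         QCO = Q[.CLOSED, .OPEN, drop = FALSE],
         QCC = Q[.CLOSED, .CLOSED, drop = FALSE],
         Z = z, ca = lig$ca, ip3 = lig$ip3,
         variant = attr(occ, "variant")),
    class = "ip3r_generator")
}

#' @export
print.ip3r_generator <- function(x, ...) {
  cat(sprintf("IP3R 12-state generator (%s) at Ca = %g uM, IP3 = %g uM\n",
              x$variant %||% "custom", x$ca, x$ip3))
  ex <- -diag(x$Q)
  cat(sprintf("  state exit rates (ms^-1): min %.3g, max %.3g\n",
              min(ex), max(ex)))
  invisible(x)
}

#' Stationary distribution of a generator matrix
#'
#' Computes the stationary distribution of a continuous-time Markov chain
#' by the Grassmann-Taksar-Heyman (GTH) elimination algorithm, which uses
#' no subtractions and therefore retains high componentwise relative
#' accuracy even when the stationary probabilities span many orders of
#' magnitude.  Serves as the independent cross-check that the assembled
#' generator is consistent with the occupancy vector.
#'
#' @param Q A square generator matrix (rows sum to zero) or an
#'   \code{"ip3r_generator"} object.
#' @return The stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  if (inherits(Q, "ip3r_generator")) Q <- Q$Q
  A <- as.matrix(Q)
  n <- nrow(A)
  if (n != ncol(A)) stop("Q must be square")
  diag(A) <- 0
  for (k in n:2) {
    below <- seq_len(k - 1L)
    s <- sum(A[k, below])
    if (s <= 0) stop("chain is reducible: state ", k, " has no return path")
    A[below, k] <- A[below, k] / s
    A[below, below] <- A[below, below] + A[below, k] %o% A[k, below]
    diag(A) <- 0
  }
  pi <- numeric(n)
  pi[1] <- 1
  for (k in 2:n) {
    below <- seq_len(k - 1L)
    pi[k] <- sum(pi[below] * A[below, k])
  }
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}
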