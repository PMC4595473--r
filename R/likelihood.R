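## Spectral factors of the open/closed sub-generator blocks.  The chain
## satisfies detailed balance with respect to the occupancy vector z, so
## D^{1/2} Q_AA D^{-1/2} (D = diag(z_A)) is symmetric and each block has a
## real spectral decomposition; the matrix exponentials in the likelihood
## reduce to well-conditioned symmetric eigenproblems.
.loglik_prep <- function(G) {
  stopifnot(inherits(G, "ip3r_generator"))
  zc <- G$Z[.CLOSED]; zo <- G$Z[.OPEN]
  if (any(zc <= 0) || any(zo <= 0))
    stop("likelihood requires strictly positive ligand concentrations ",
         "(all states reachable)")
  dC <- sqrt(zc); dO <- sqrt(zo)
  Sc <- G$QCC * outer(dC, 1 / dC)  # D^{1/2} Q D^{-1/2}, then symmetrize
  Sc <- (Sc + t(Sc)) / 2
  So <- G$QOO * outer(dO, 1 / dO)
  So <- (So + t(So)) / 2
  Ec <- eigen(Sc, symmetric = TRUE)
  Eo <- eigen(So, symmetric = TRUE)
  J <- total_flux(G)
  piC <- as.numeric(zo %*% G$QOC) / J
  list(piC = piC, dC = dC, Uc = Ec$vectors, lamC = Ec$values,
       Qco = G$QCO, dO = dO, Uo = Eo$vectors, lamO = Eo$values,
       Qoc = G$QOC, J = J)
}

#' Log-likelihood of an idealized dwell sequence
#'
#' Computes the aggregated-Markov log-likelihood of one record of
#' alternating closed/open dwells under the twelve-state model: the
#' closed-entry distribution at equilibrium is propagated through
#' alternating sub-generator exponentials and switching blocks,
#' \eqn{\pi_C e^{Q_{CC} t_{c1}} Q_{CO} e^{Q_{OO} t_{o1}} Q_{OC} \cdots
#' e^{Q_{OO} t_{on}} u_O}.  The final open dwell is censored by the end of
#' the record and contributes only its survival factor.  The state vector
#' is renormalized after every factor with the log norms accumulated, so
#' long records do not underflow.
#'
#' @param trace An \code{"ip3r_trace"} (strictly alternating, closed
#'   leading, open trailing).
#' @param G An \code{"ip3r_generator"} built at the trace's ligand
#'   condition.
#' @param method \code{"spectral"} (default; symmetrized eigenbasis, fast)
#'   or \code{"expm"} (direct scaling-and-squaring matrix exponential per
#'   dwell; reference implementation used for cross-checking).
#' @return The log-likelihood (a finite number for valid inputs).
#' @export
trace_loglik <- function(trace, G, method = c("spectral", "expm")) {
  method <- match.arg(method)
  validate_trace(trace)
  tc <- trace$duration_ms[trace$conductance == 0L]
  to <- trace$duration_ms[trace$conductance == 1L]
  if (method == "spectral") {
    p <- .loglik_prep(G)
    return(cpp_loglik_dwells(p$piC, p$dC, p$Uc, p$lamC, p$Qco,
                             p$dO, p$Uo, p$lamO, p$Qoc, tc, to))
  }
  ## reference path: explicit matrix exponentials with renormalization
  p <- .loglik_prep(G)
  v <- p$piC
  acc <- 0
  renorm <- function(v) {
    s <- sum(abs(v))
    acc <<- acc + log(s)
    v / s
  }
  n <- length(tc)
  for (i in seq_len(n)) {
    v <- renorm(as.numeric(v %*% as.matrix(Matrix::expm(G$QCC * tc[i]))))
    v <- renorm(as.numeric(v %*% G$QCO))
    v <- as.numeric(v %*% as.matrix(Matrix::expm(G$QOO * to[i])))
    if (i < n) {
      v <- renorm(v)
      v <- renorm(as.numeric(v %*% G$QOC))
    }
  }
  acc + log(sum(v))
}

#' Total log-likelihood of a gating data set
#'
#' Sums \code{\link{trace_loglik}} over an ensemble of records.  Records
#' may come from different ligand conditions; the generator is rebuilt per
#' condition (and cached across records sharing one).
#'
#' @param traces Nonempty list of \code{"ip3r_trace"} objects.
#' @param occ,flux Parameter vectors.
#' @return Total log-likelihood, with attribute \code{n_exp} (number of
#'   records).
#' @export
dataset_loglik <- function(traces, occ, flux) {
  if (length(traces) == 0L) stop("empty data set")
  key <- vapply(traces, function(tr)
    paste(attr(tr, "ca"), attr(tr, "ip3")), character(1))
  total <- 0
  for (k in unique(key)) {
    ix <- which(key == k)
    tr1 <- traces[[ix[1]]]
    G <- build_generator(occ, flux, attr(tr1, "ca"), attr(tr1, "ip3"))
    p <- .loglik_prep(G)
    for (i in ix) {
      tr <- traces[[i]]
      validate_trace(tr)
      tc <- tr$duration_ms[tr$conductance == 0L]
      to <- tr$duration_ms[tr$conductance == 1L]
      total <- total + cpp_loglik_dwells(p$piC, p$dC, p$Uc, p$lamC, p$Qco,
                                         p$dO, p$Uo, p$lamO, p$Qoc, tc, to)
    }
  }
  attr(total, "n_exp") <- length(traces)
  total
}
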