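#' The twelve gating states of the IP3R channel model
#'
#' The model describes IP3R gating as a continuous-time Markov chain on
#' twelve aggregated states.  Each state name encodes its ligand
#' stoichiometry and gating mode: \code{XmnM} is a closed (\code{X = C}) or
#' open (\code{X = O}) state with \code{m} Ca2+ ions and \code{n} IP3
#' molecules bound, gating in mode \code{M} (L = low activity,
#' I = intermediate, H = high activity/bursting).
#'
#' States are kept in a canonical order with the three open states first
#' (\code{O14I, O24I, O24H}) followed by the nine closed states, so that the
#' generator matrix partitions cleanly into open/open, open/closed,
#' closed/open and closed/closed blocks.
#'
#' @return A data frame with one row per state and columns \code{state},
#'   \code{conductance} (\code{"open"} or \code{"closed"}), \code{mode}
#'   (\code{"L"}, \code{"I"} or \code{"H"}), \code{ca_bound} and
#'   \code{ip3_bound} (ligand stoichiometry used as exponents of the
#'   Ca2+ and IP3 concentrations in the state occupancies).
#' @examples
#' ip3r_states()
#' @export
ip3r_states <- function() {
  state <- c("O14I", "O24I", "O24H",
             "C00L", "C20L", "C30L", "C32L", "C34L", "C04L",
             "C04I", "C24I", "C24H")
  data.frame(
    state       = state,
    conductance = ifelse(substr(state, 1, 1) == "O", "open", "closed"),
    mode        = substr(state, 4, 4),
    ca_bound    = as.integer(substr(state, 2, 2)),
    ip3_bound   = as.integer(substr(state, 3, 3)),
    stringsAsFactors = FALSE
  )
}

## Internal constants derived once from the canonical state table.
.states   <- ip3r_states()
.OPEN     <- which(.states$conductance == "open")    # 1:3
.CLOSED   <- which(.states$conductance == "closed")  # 4:12
.MODE_SET <- split(seq_len(12L), .states$mode)       # indices by mode (H, I, L)

#' State indices of a gating mode
#'
#' @param mode One of \code{"L"}, \code{"I"}, \code{"H"}.
#' @return Integer indices (canonical order) of the states in that mode.
#' @export
mode_states <- function(mode) {
  mode <- match.arg(mode, c("L", "I", "H"))
  .MODE_SET[[mode]]
}

#' Validate a ligand condition
#'
#' A ligand condition is the pair of steady cytoplasmic concentrations the
#' channel is exposed to: free Ca2+ (\code{ca}) and IP3 (\code{ip3}), both
#' in micromolar.
#'
#' @param ca Free Ca2+ concentration (uM), a single nonnegative number.
#' @param ip3 IP3 concentration (uM), a single nonnegative number.
#' @return A named list with elements \code{ca} and \code{ip3}.
#' @examples
#' ligand_condition(ca = 1, ip3 = 0.1)
#' @export
ligand_condition <- function(ca, ip3) {
  if (!is.numeric(ca) || length(ca) != 1L || !is.finite(ca) || ca < 0)
    stop("'ca' must be a single finite nonnegative concentration (uM)")
  if (!is.numeric(ip3) || length(ip3) != 1L || !is.finite(ip3) || ip3 < 0)
    stop("'ip3' must be a single finite nonnegative concentration (uM)")
  list(ca = as.numeric(ca), ip3 = as.numeric(ip3))
}
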