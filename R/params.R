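#' Occupancy parameters of the twelve-state model
#'
#' Each state's equilibrium (unnormalized) occupancy is
#' \eqn{K \, \mathcal{C}^m \mathcal{I}^n}, where \eqn{K} is the state's
#' occupancy parameter (the product of equilibrium association constants
#' along any path from the unliganded reference state \code{C00L}, for which
#' \eqn{K = 1}), and \eqn{(m, n)} is the state's ligand stoichiometry.
#' Units of each \eqn{K} are \eqn{\mu M^{-(m+n)}}.
#'
#' Two parameter sets are provided: channels gating in the presence of
#' wild-type presenilin-1 (\code{"WT"}) and of the familial Alzheimer's
#' disease mutant (\code{"M146L"}).  The mutant differs from wild type in
#' exactly four states: \code{KC32L}, \code{KO14I}, \code{KO24H} and
#' \code{KO24I}.
#'
#' @param variant \code{"WT"} or \code{"M146L"}.
#' @return A named numeric vector of the twelve occupancy parameters with
#'   attribute \code{variant}.
#' @examples
#' occupancy_params("M146L")["KO24H"] / occupancy_params("WT")["KO24H"]
#' @export
occupancy_params <- function(variant = c("WT", "M146L")) {
  variant <- match.arg(variant)
  k <- c(
    KC00L = 1,
    KC20L = 7.061,
    KC30L = 1.778,
    KC32L = 1.504e7,
    KC04L = 1.746e8,
    KC04I = 4.365e7,
    KC24H = 3.082e8,
    KC24I = 3.0823e8,
    KC34L = 1.0319e8,
    KO14I = 6.605e7,
    KO24H = 8.702e8,
    KO24I = 5.856e7
  )
  if (variant == "M146L") {
    k[c("KC32L", "KO14I", "KO24H", "KO24I")] <-
      c(2.749e5, 8.478e7, 3.992e9, 1.006e8)
  }
  structure(k, variant = variant)
}

#' Flux parameters of the twelve-state model
#'
#' Each reversible transition pair is parameterized by a symmetric
#' equilibrium probability flux; the forward and backward transition rates
#' are the pair flux divided by the occupancy of the source state.  The
#' eighteen flux parameters \eqn{j_{ijmn}} (units
#' \eqn{\mu M^{-k}\,ms^{-1}}) connect a state with \eqn{i} Ca2+ and
#' \eqn{j} IP3 bound to one with \eqn{m} Ca2+ and \eqn{n} IP3 bound;
#' superscripts (\code{IL}, \code{II}, \code{HH}) distinguish parallel
#' pathways between equally liganded states in different modes.
#'
#' The M146L variant differs from wild type in exactly two parameters,
#' \code{j0414II} (the \code{C04I <-> O14I} pathway) and \code{j2424HH}
#' (the \code{C24H <-> O24H} pathway), both larger in the mutant.
#'
#' @param variant \code{"WT"} or \code{"M146L"}.
#' @return A named numeric vector of the 18 flux parameters with attribute
#'   \code{variant}.
#' @export
flux_params <- function(variant = c("WT", "M146L")) {
  variant <- match.arg(variant)
  j <- c(
    j0414   = 1.017e6,
    j1424   = 2.840e7,
    j2434   = 4.961e5,
    j0414IL = 9.502e8,
    j1424IL = 6.4e5,
    j2434IL = 2.431e3,
    j2030   = 2.449e-3,
    j0414II = 5.156e5,
    j2424II = 3.0577e7,
    j2424   = 3.301e5,
    j0404   = 5.459e4,
    j2424HH = 5.478e7,
    j3132   = 2.891e-2,
    j3334   = 2.120e3,
    j0001   = 1.138e-2,
    j0304   = 4.756e10,
    j2021   = 8.904e-4,
    j2324   = 8.523e6
  )
  if (variant == "M146L") {
    j[c("j0414II", "j2424HH")] <- c(2.587e7, 1.753e8)
  }
  structure(j, variant = variant)
}

#' Read or write a model parameter set as a plain-text config file
#'
#' Parameter sets are serialized as YAML with fields \code{variant},
#' \code{occupancy} and \code{flux}.  The two built-in parameter sets ship
#' with the package under \code{inst/extdata}.
#'
#' @param path File path.
#' @param occupancy,flux Named numeric vectors as returned by
#'   \code{\link{occupancy_params}} and \code{\link{flux_params}}.
#' @param variant Variant tag stored alongside the values.
#' @return \code{read_params} returns a list with elements \code{variant},
#'   \code{occupancy}, \code{flux}; \code{write_params} returns \code{path}
#'   invisibly.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  occ <- unlist(x$occupancy)
  flx <- unlist(x$flux)
  want_k <- names(occupancy_params("WT"))
  want_j <- names(flux_params("WT"))
  if (!all(want_k %in% names(occ)))
    stop("parameter file is missing occupancy parameters: ",
         paste(setdiff(want_k, names(occ)), collapse = ", "))
  if (!all(want_j %in% names(flx)))
    stop("parameter file is missing flux parameters: ",
         paste(setdiff(want_j, names(flx)), collapse = ", "))
  list(variant = x$variant %||% "custom",
       occupancy = structure(occ[want_k], variant = x$variant %||% "custom"),
       flux = structure(flx[want_j], variant = x$variant %||% "custom"))
}

#' @rdname read_params
#' @export
write_params <- function(path, occupancy, flux,
                         variant = attr(occupancy, "variant") %||% "custom") {
  yaml::write_yaml(
    list(variant = variant,
         occupancy = as.list(occupancy),
         flux = as.list(flux)),
    path, precision = 12L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
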