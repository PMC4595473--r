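#' Geometry of an IP3R channel cluster
#'
#' Channels sit on a planar rectangular array with fixed inter-channel
#' spacing (default: ten channels as a 2 x 5 array, 120 nm apart).  Each
#' channel's own radial reaction-diffusion field is evaluated at the
#' inter-channel distances for the superposition of local Ca2+; a
#' channel's contribution at its own location is evaluated at the source
#' shell radius \code{self_r_um}.
#'
#' @param n_channels Number of channels.
#' @param spacing_um Inter-channel spacing (um); default 0.12.
#' @param n_rows Rows of the array (columns follow from
#'   \code{n_channels}).
#' @param self_r_um Radius at which a channel's own field is sampled for
#'   its local Ca2+ (um); default the source shell radius 2.5 nm.
#' @return List of class \code{"ip3r_cluster_geometry"} with channel
#'   \code{positions} (um), pairwise \code{distances} (with
#'   \code{self_r_um} on the diagonal) and distances to the cluster
#'   centroid \code{r_center}.
#' @export
cluster_geometry <- function(n_channels = 10L, spacing_um = 0.12,
                             n_rows = 2L, self_r_um = 0.0025) {
  stopifnot(n_channels >= 1L, spacing_um > 0, self_r_um > 0)
  n_cols <- ceiling(n_channels / n_rows)
  pos <- cbind(
    x = rep(seq_len(n_cols) - 1, each = n_rows)[seq_len(n_channels)],
    y = rep(seq_len(n_rows) - 1, times = n_cols)[seq_len(n_channels)]
  ) * spacing_um
  d <- as.matrix(stats::dist(pos))
  diag(d) <- self_r_um
  ctr <- colMeans(pos)
  rc <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  rc <- pmax(rc, self_r_um)
  structure(list(positions = pos, distances = d, r_center = rc,
                 spacing_um = spacing_um, self_r_um = self_r_um),
            class = "ip3r_cluster_geometry")
}

#' Buffer, diffusion and source parameters for cluster simulations
#'
#' Parameters of the cytosolic free-Ca2+ / free-dye reaction-diffusion
#' fields and of the channel point source.  The defaults are standard
#' Ca2+-microdomain modeling values for a fast mobile indicator dye; they
#' are package defaults, configurable per run.
#'
#' \code{buffer_params} defaults: \code{D_c} = 220 um^2/s (free Ca2+),
#' \code{D_d} = 32 um^2/s (dye), \code{B_d} = 40 uM total dye,
#' \code{k_d_f} = 150 uM^-1 s^-1, \code{k_d_r} = 300 s^-1, resting Ca2+
#' \code{c_rest} = 0.07 uM.
#'
#' \code{source_params}: single-channel current \code{I_pA} = 0.05 pA,
#' delivered as a Ca2+ source within the shell of radius
#' \code{delta_r_um} = 2.5 nm over the hemispherical volume of radius
#' \code{r_pore_um} (default equal to \code{delta_r_um}).
#'
#' @param B_d,k_d_f,k_d_r,D_c,D_d,c_rest See description (uM, uM^-1 s^-1,
#'   s^-1, um^2/s, um^2/s, uM).
#' @return Named list of parameters.
#' @export
buffer_params <- function(B_d = 40, k_d_f = 150, k_d_r = 300,
                          D_c = 220, D_d = 32, c_rest = 0.07) {
  stopifnot(B_d >= 0, k_d_f > 0, k_d_r > 0, D_c > 0, D_d > 0, c_rest > 0)
  list(B_d = B_d, k_d_f = k_d_f, k_d_r = k_d_r,
       D_c = D_c, D_d = D_d, c_rest = c_rest)
}

#' @rdname buffer_params
#' @param I_pA Single-channel Ca2+ current (pA).
#' @param delta_r_um Source shell radius (um).
#' @param r_pore_um Pore radius defining the hemispherical source volume
#'   (um).
#' @export
source_params <- function(I_pA = 0.05, delta_r_um = 0.0025,
                          r_pore_um = delta_r_um) {
  stopifnot(I_pA > 0, delta_r_um > 0, r_pore_um > 0)
  list(I_pA = I_pA, delta_r_um = delta_r_um, r_pore_um = r_pore_um)
}

#' Radial grid for the per-channel reaction-diffusion fields
#'
#' Finite-volume cells on \code{[0, radius_um]} with the innermost cell
#' spanning the source shell and cell widths growing geometrically
#' outward, concentrating resolution in the microdomain where gradients
#' are steep.
#'
#' @param radius_um Domain radius (um); default 5.
#' @param dr_min_um Width of the innermost cell (um); default the source
#'   shell radius 2.5 nm.
#' @param n_cells Number of cells; default 160.
#' @return List with cell-center \code{nodes} and cell \code{edges} (um).
#' @export
radial_grid <- function(radius_um = 5, dr_min_um = 0.0025,
                        n_cells = 160L) {
  stopifnot(radius_um > dr_min_um, n_cells >= 10L)
  f <- function(g) dr_min_um * (g^n_cells - 1) / (g - 1) - radius_um
  g <- stats::uniroot(f, c(1 + 1e-9, 2), tol = 1e-12)$root
  w <- dr_min_um * g^(seq_len(n_cells) - 1)
  edges <- c(0, cumsum(w))
  edges[n_cells + 1] <- radius_um
  nodes <- (edges[-1] + edges[-(n_cells + 1)]) / 2
  list(nodes = nodes, edges = edges)
}

## Faraday constant (C / mol)
.FARADAY <- 96485.33212

## Source strength in uM/s over the source shell volume: the molar rate
## I/(2F) spread over the hemisphere of radius r_pore.
.source_rate_uM_s <- function(src) {
  mol_s <- src$I_pA * 1e-12 / (2 * .FARADAY)        # mol/s
  vol_L <- 2 * pi / 3 * src$r_pore_um^3 * 1e-15     # hemisphere, um^3 -> L
  mol_s / vol_L * 1e6                               # uM/s
}

#' Advance a single channel's radial field under a source schedule
#'
#' Deterministic driver for one reaction-diffusion field: the source is
#' switched on and off according to a piecewise-constant schedule and the
#' field is advanced with the same numerics as the cluster simulation
#' (backward-Euler diffusion, semi-implicit reaction).  Used for
#' steady-state profiles, fixed-point checks and convergence studies.
#'
#' @param schedule Data frame with columns \code{t_end_s} and \code{on}
#'   (logical): consecutive segments of source state.
#' @param buffers \code{\link{buffer_params}}.
#' @param source \code{\link{source_params}}.
#' @param grid \code{\link{radial_grid}}.
#' @param dt_s Time step (s); default 2e-5.
#' @param record_dt_s Sampling interval for the inner-cell concentration
#'   time series (s); 0 disables recording.
#' @return List with \code{r_um}, final profiles \code{c} and \code{b}
#'   (free Ca2+ and free dye, uM), the equilibrated resting free dye
#'   \code{b_rest}, and time series \code{t_s}, \code{c_inner}.
#' @export
run_field_schedule <- function(schedule, buffers = buffer_params(),
                               source = source_params(),
                               grid = radial_grid(), dt_s = 2e-5,
                               record_dt_s = 0) {
  stopifnot(is.data.frame(schedule), all(c("t_end_s", "on") %in%
                                           names(schedule)))
  n_src <- max(1L, sum(grid$nodes <= source$delta_r_um))
  cpp_single_field(grid$nodes, grid$edges,
                   buffers$D_c, buffers$D_d, buffers$B_d,
                   buffers$k_d_f, buffers$k_d_r, buffers$c_rest,
                   .source_rate_uM_s(source), n_src, dt_s,
                   schedule$t_end_s, schedule$on, record_dt_s)
}

#' Simulate Ca2+ release from a ten-channel IP3R cluster
#'
#' Hybrid stochastic-deterministic simulation: each channel gates
#' according to the twelve-state model driven by its local Ca2+ (the
#' superposition of all channels' radial fields plus the resting level),
#' while every open channel feeds a Ca2+ point source into its own
#' radial reaction-diffusion field.  Channel states advance by exact
#' exponential-clock jumps with rates frozen over one field step.
#'
#' @param occ,flux Gating parameter vectors.
#' @param ip3 IP3 concentration (uM), constant over the run.
#' @param duration_s Simulated time (s).
#' @param geometry \code{\link{cluster_geometry}}.
#' @param buffers \code{\link{buffer_params}}.
#' @param source \code{\link{source_params}}.
#' @param grid \code{\link{radial_grid}}.
#' @param dt_s Field/gating time step (s); default 2e-5.
#' @param record_dt_s Output sampling interval (s); default 2e-4.
#' @param seed Optional integer seed.
#' @return List of class \code{"ip3r_cluster_run"}: \code{t_s},
#'   \code{n_open}, \code{open} (samples x channels 0/1 matrix),
#'   \code{ca_center_uM}, \code{dye_bound_center_uM}, plus the run
#'   configuration.
#' @export
run_cluster <- function(occ, flux, ip3, duration_s,
                        geometry = cluster_geometry(),
                        buffers = buffer_params(),
                        source = source_params(),
                        grid = radial_grid(),
                        dt_s = 2e-5, record_dt_s = 2e-4, seed = NULL) {
  stopifnot(duration_s > 0, ip3 >= 0)
  if (!is.null(seed)) set.seed(seed)
  K <- unname(occ[paste0("K", .states$state)])
  j <- unname(flux[names(flux_params("WT"))])
  nch <- nrow(geometry$distances)
  z <- state_occupancies(occ, buffers$c_rest, ip3)
  p0 <- z / sum(z)
  init <- sample.int(12L, nch, replace = TRUE, prob = p0)
  n_src <- max(1L, sum(grid$nodes <= source$delta_r_um))
  res <- cpp_run_cluster(K, j, ip3, geometry$distances, geometry$r_center,
                         grid$nodes, grid$edges,
                         buffers$D_c, buffers$D_d, buffers$B_d,
                         buffers$k_d_f, buffers$k_d_r, buffers$c_rest,
                         .source_rate_uM_s(source), n_src,
                         duration_s, dt_s, record_dt_s, init)
  structure(c(res,
              list(ip3 = ip3, variant = attr(occ, "variant"),
                   duration_s = duration_s, dt_s = dt_s,
                   record_dt_s = record_dt_s,
                   geometry = geometry, buffers = buffers,
                   source = source)),
            class = "ip3r_cluster_run")
}

#' @export
print.ip3r_cluster_run <- function(x, ...) {
  cat(sprintf("IP3R cluster run (%s): %g s at IP3 = %g uM, %d channels\n",
              x$variant %||% "custom", x$duration_s, x$ip3,
              ncol(x$open)))
  cat(sprintf("  mean open channels %.3f; peak %d; peak Ca at center %.3g uM\n",
              mean(x$n_open), max(x$n_open), max(x$ca_center_uM)))
  invisible(x)
}
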