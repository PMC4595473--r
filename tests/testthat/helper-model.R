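## Shared fixtures: parameter sets and generators at the reference ligand
## conditions used throughout the suite.
OCC_WT <- occupancy_params("WT")
OCC_MUT <- occupancy_params("M146L")
FLX_WT <- flux_params("WT")
FLX_MUT <- flux_params("M146L")
STATES <- ip3r_states()

G_WT_REF <- build_generator(OCC_WT, FLX_WT, ca = 1, ip3 = 0.1)
G_MUT_REF <- build_generator(OCC_MUT, FLX_MUT, ca = 1, ip3 = 0.1)

## small ligand grid used by invariance loops
LIG_GRID <- expand.grid(ca = c(0.01, 0.1, 1, 10),
                        ip3 = c(0.001, 0.01, 0.1, 1, 10))

## builds an idealized trace from explicit dwells (for hand-constructed
## segmentation and event cases)
make_trace <- function(conductance, duration_ms, ca = 1, ip3 = 0.1,
                       variant = "WT", record_id = 1L) {
  structure(data.frame(conductance = as.integer(conductance),
                       duration_ms = as.numeric(duration_ms)),
            ca = ca, ip3 = ip3, variant = variant, record_id = record_id,
            class = c("ip3r_trace", "data.frame"))
}

## reference dwell-sequence likelihood built directly from Eq-structure
## matrix products (Matrix::expm), independent of the package's spectral
## propagation path
ref_loglik <- function(tc, to, piC, QCC, QCO, QOO, QOC) {
  v <- piC
  n <- length(tc)
  acc <- 0
  for (i in seq_len(n)) {
    v <- v %*% as.matrix(Matrix::expm(QCC * tc[i])) %*% QCO %*%
      as.matrix(Matrix::expm(QOO * to[i]))
    if (i < n) v <- v %*% QOC
    s <- sum(abs(v))        # exact rescaling against underflow
    acc <- acc + log(s)
    v <- v / s
  }
  acc + log(sum(v))
}
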