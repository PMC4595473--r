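test_that("entry distributions are probabilities on the entered aggregate", {
  p <- dwell_partition(G_WT_REF)
  ed <- entry_distribution(p)
  expect_equal(sum(ed$X), 1, tolerance = 1e-12)
  expect_equal(sum(ed$Y), 1, tolerance = 1e-12)
  expect_true(all(ed$X >= 0) && all(ed$Y >= 0))
  ## single-state aggregates are entered with certainty
  h <- dwell_partition(G_WT_REF, mode = "H")
  expect_equal(unname(entry_distribution(h)$X), 1)
  expect_equal(unname(entry_distribution(h)$Y), 1)
})

test_that("mode-restricted partitions only see within-mode transitions", {
  im <- dwell_partition(G_MUT_REF, mode = "I")
  ## X = open I states, Y = closed I states
  expect_setequal(im$X, c("O14I", "O24I"))
  expect_setequal(im$Y, c("C04I", "C24I"))
  ## rows of the mode sub-generator balance within the mode:
  ## Q_XX u_X + Q_XY u_Y = 0 and the O24I row excludes the out-of-mode
  ## O24I -> O24H rate
  expect_equal(unname(rowSums(im$QXX) + rowSums(im$QXY)), c(0, 0),
               tolerance = 1e-14)
  expect_equal(im$QXX["O24I", "O24I"], -im$QXY["O24I", "C24I"])
  ## off-diagonal open-open block is empty (no O14I <-> O24I transition)
  expect_equal(im$QXX["O14I", "O24I"], 0)
})

test_that("single-state aggregates give exact exponential dwell laws", {
  h <- dwell_partition(G_WT_REF, mode = "H")
  r <- G_WT_REF$Q["O24H", "C24H"]  # only within-mode exit of O24H
  tt <- c(0.1, 1, 5, 20)
  expect_equal(dwell_pdf(h, tt, "X"), r * exp(-r * tt), tolerance = 1e-9)
  expect_equal(dwell_mean(h, "X"), 1 / r, tolerance = 1e-12)
  expect_equal(dwell_cdf(h, tt, "X"), 1 - exp(-r * tt), tolerance = 1e-9)
})

test_that("dwell pdfs are nonnegative, normalized, with means matching closed form", {
  parts <- list(dwell_partition(G_WT_REF),
                dwell_partition(G_MUT_REF),
                dwell_partition(G_WT_REF, mode = "I"),
                dwell_partition(G_MUT_REF, mode = "H"))
  for (p in parts) for (side in c("X", "Y")) {
    tt <- 10^seq(-3, 5, length.out = 50)
    expect_true(all(dwell_pdf(p, tt, side) >= 0))
    nrm <- integrate(function(t) dwell_pdf(p, t, side), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(nrm, 1, tolerance = 1e-8)
    m_quad <- integrate(function(t) t * dwell_pdf(p, t, side), 0, Inf,
                        rel.tol = 1e-10)$value
    expect_equal(dwell_mean(p, side), m_quad, tolerance = 1e-6)
  }
})

test_that("full-partition dwell means equal the equilibrium mean times", {
  for (G in list(G_WT_REF, G_MUT_REF)) {
    p <- dwell_partition(G)
    taus <- mean_times(G)
    expect_equal(dwell_mean(p, "X"), taus[["tau_o"]], tolerance = 1e-6)
    expect_equal(dwell_mean(p, "Y"), taus[["tau_c"]], tolerance = 1e-6)
  }
})

test_that("spectral propagation matches direct matrix exponentials", {
  p <- dwell_partition(G_WT_REF)
  tt <- c(0.01, 0.5, 3, 40, 500)
  direct <- vapply(tt, function(ti) {
    as.numeric(p$piY %*% as.matrix(Matrix::expm(p$QYY * ti)) %*%
                 p$QYX %*% rep(1, 3))
  }, numeric(1))
  expect_equal(dwell_pdf(p, tt, "Y"), direct, tolerance = 1e-8)
})

test_that("the mutant shifts closed dwells to shorter times", {
  ## H-mode and overall closed dwell medians shorten under the mutation
  for (mk in list(NULL, "H")) {
    pw <- dwell_partition(G_WT_REF, mode = mk[[1]])
    pm <- dwell_partition(G_MUT_REF, mode = mk[[1]])
    expect_lt(dwell_median(pm, "Y"), dwell_median(pw, "Y"))
  }
})

test_that("dwell pdf grids export cleanly", {
  p <- dwell_partition(G_WT_REF)
  g <- dwell_pdf_grid(p, "X", t_min = 0.1, t_max = 100, n = 50)
  expect_named(g, c("t_ms", "density"))
  expect_equal(nrow(g), 50L)
  expect_true(all(diff(g$t_ms) > 0))
})

test_that("simulated dwell histograms follow the theoretical laws", {
  ## Monte-Carlo oracle: long stationary record at the reference
  ## condition; dwells thinned to decorrelate successive sojourns before
  ## a KS test against the closed-form distribution function.
  set.seed(420)
  tr <- to_idealized(simulate_trajectory(G_WT_REF, 2e6))
  p <- dwell_partition(G_WT_REF)
  od <- tr$duration_ms[tr$conductance == 1L]
  cd <- tr$duration_ms[tr$conductance == 0L]
  expect_gt(length(od), 2e4)
  thin <- function(x) x[seq(1, length(x), by = 40)]
  ks_o <- suppressWarnings(
    stats::ks.test(thin(od), function(q) dwell_cdf(p, q, "X")))
  ks_c <- suppressWarnings(
    stats::ks.test(thin(cd), function(q) dwell_cdf(p, q, "Y")))
  expect_gt(ks_o$p.value, 0.01)
  expect_gt(ks_c$p.value, 0.01)
  ## empirical entry states match the entry distribution (3 SE)
  expect_equal(mean(od), dwell_mean(p, "X"),
               tolerance = 3 * stats::sd(od) / sqrt(length(od)) /
                 dwell_mean(p, "X"))
})
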