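test_that("rsr composes step rates harmonically and tolerates edge cases", {
  expect_equal(rsr(2, 2), 1)
  expect_equal(rsr(1, 2, 3), 1 / (1 + 1 / 2 + 1 / 3))
  expect_equal(rsr(0, 5), 0)      # blocked pathway
  expect_equal(rsr(Inf, 5), 5)    # instantaneous step drops out
})

test_that("generator rows sum to zero with nonnegative off-diagonals on a ligand grid", {
  for (i in seq_len(nrow(LIG_GRID))) {
    for (occ in list(OCC_WT, OCC_MUT)) {
      flx <- if (identical(attr(occ, "variant"), "WT")) FLX_WT else FLX_MUT
      G <- build_generator(occ, flx, LIG_GRID$ca[i], LIG_GRID$ip3[i])
      Q <- G$Q
      expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
      ## only the 15 reversible pairs are populated
      expect_equal(sum(off > 0) <= 30, TRUE)
    }
  }
})

test_that("stationary distribution equals the normalized occupancy vector", {
  ## the central consistency check between the occupancy table, the rate
  ## table and the flux table
  for (i in seq_len(nrow(LIG_GRID))) {
    for (v in c("WT", "M146L")) {
      occ <- occupancy_params(v); flx <- flux_params(v)
      G <- build_generator(occ, flx, LIG_GRID$ca[i], LIG_GRID$ip3[i])
      pi <- stationary_distribution(G)
      z <- G$Z / sum(G$Z)
      expect_lt(max(abs(pi - z) / z), 1e-9)
    }
  }
})

test_that("constructed rates reproduce the printed composite-rate formulas", {
  ## The printed rate table divides three backward rates by a nearby
  ## occupancy constant instead of the destination state's own
  ## (KC24H for C04I<-C24I and C00L<-C20L, KC04I*I^3 for C20L<-C24H);
  ## the constructed rates agree with the printed forms to the printed
  ## precision (~1e-4) and are exactly detailed-balanced.
  for (cc in c(0.05, 1, 5)) for (ii in c(0.01, 0.1, 1)) {
    G <- build_generator(OCC_WT, FLX_WT, cc, ii)
    Q <- G$Q
    K <- OCC_WT; j <- FLX_WT
    printed <- rbind(
      c("C04I", "C24H", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / K[["KC04I"]]),
      c("C24H", "C04I", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / (K[["KC24H"]] * cc^2)),
      c("C24H", "O24H", j[["j2424HH"]] / K[["KC24H"]]),
      c("O24H", "C24H", j[["j2424HH"]] / K[["KO24H"]]),
      c("O24H", "C34L", j[["j2434"]] * cc / K[["KO24H"]]),
      c("C34L", "O24H", j[["j2434"]] / K[["KC34L"]]),
      c("C04I", "O14I", j[["j0414II"]] * cc / K[["KC04I"]]),
      c("O14I", "C04I", j[["j0414II"]] / K[["KO14I"]]),
      c("C24I", "O24I", j[["j2424II"]] / K[["KC24I"]]),
      c("O24I", "C24I", j[["j2424II"]] / K[["KO24I"]]),
      c("O24I", "O24H", j[["j2424"]] / K[["KO24I"]]),
      c("C04I", "C04L", j[["j0404"]] / K[["KC04I"]]),
      c("C32L", "C34L", j[["j3334"]] * ii^2 / K[["KC32L"]]),
      c("C30L", "C32L", j[["j3132"]] * ii^2 / K[["KC30L"]]),
      c("C20L", "C30L", j[["j2030"]] * cc / K[["KC20L"]]),
      c("C00L", "C04I", rsr(j[["j0001"]] * ii, j[["j0304"]] * ii^4)),
      c("C04I", "C00L", rsr(j[["j0001"]], j[["j0304"]] * ii^3) / (K[["KC04I"]] * ii^3)),
      c("C20L", "C24H", rsr(j[["j2021"]] * ii, j[["j2324"]] * ii^4)),
      c("C24H", "C20L", rsr(j[["j2021"]], j[["j2324"]] * ii^3) / (K[["KC04I"]] * ii^3)),
      c("C04I", "C24I", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / K[["KC04I"]]),
      c("C24I", "C04I", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / (K[["KC24H"]] * cc^2)),
      c("C00L", "C20L", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / K[["KC04I"]]),
      c("C20L", "C00L", rsr(j[["j0414"]] * cc, j[["j1424"]] * cc^2) / (K[["KC24H"]] * cc^2))
    )
    for (r in seq_len(nrow(printed))) {
      got <- Q[printed[r, 1], printed[r, 2]]
      want <- as.numeric(printed[r, 3])
      expect_lt(abs(got - want) / want, 2e-4)
    }
  }
})

test_that("specific printed rate values are reproduced", {
  ## C24H -> O24H at any ligand condition
  expect_equal(G_WT_REF$Q["C24H", "O24H"], 5.478e7 / 3.082e8,
               tolerance = 1e-12)
  G0 <- build_generator(OCC_WT, FLX_WT, 5, 5)
  expect_equal(G0$Q["C24H", "O24H"], 5.478e7 / 3.082e8, tolerance = 1e-12)
})

test_that("detailed balance holds pairwise between occupancies and rates", {
  z <- G_WT_REF$Z; Q <- G_WT_REF$Q
  for (a in seq_len(12)) for (b in seq_len(12)) {
    if (a != b && Q[a, b] > 0) {
      expect_lt(abs(z[a] * Q[a, b] - z[b] * Q[b, a]) / (z[a] * Q[a, b]),
                1e-10)
    }
  }
})

test_that("zero ligand zeroes binding pathways but keeps unbinding finite", {
  G0 <- build_generator(OCC_WT, FLX_WT, 0, 0)
  expect_true(all(is.finite(G0$Q)))
  ## no binding out of the unliganded reference state
  expect_equal(unname(G0$Q["C00L", "C04I"]), 0)
  expect_equal(unname(G0$Q["C00L", "C20L"]), 0)
  ## ligand-independent transitions persist
  expect_gt(G0$Q["C24H", "O24H"], 0)
})

test_that("C++ and R generator builders agree exactly", {
  K <- unname(OCC_MUT[paste0("K", STATES$state)])
  j <- unname(FLX_MUT)
  for (i in c(1, 7, 12, 20)) {
    cc <- LIG_GRID$ca[i]; ii <- LIG_GRID$ip3[i]
    QR <- build_generator(OCC_MUT, FLX_MUT, cc, ii)$Q
    QC <- ip3rgating:::cpp_build_Q(K, j, cc, ii)
    expect_lt(max(abs(QR - unname(QC))), 1e-13 * max(abs(QR)))
  }
})

test_that("GTH stationary solver matches a dense null-space solve on a benign chain", {
  ## independent algebraic cross-check of the GTH routine itself
  set.seed(42)
  A <- matrix(runif(25, 0.1, 2), 5, 5); diag(A) <- 0
  diag(A) <- -rowSums(A)
  pi_gth <- stationary_distribution(A)
  ns <- svd(t(A))$v[, 5]
  ns <- abs(ns) / sum(abs(ns))
  expect_equal(unname(pi_gth), ns, tolerance = 1e-10)
  expect_lt(max(abs(pi_gth %*% A)), 1e-14)
})
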