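test_that("trajectories are reproducible and structurally valid", {
  t1 <- simulate_trajectory(G_WT_REF, 5000, seed = 123)
  t2 <- simulate_trajectory(G_WT_REF, 5000, seed = 123)
  expect_identical(t1, t2)
  t3 <- simulate_trajectory(G_WT_REF, 5000, seed = 124)
  expect_false(identical(t1, t3))
  expect_true(all(t1$sojourn_ms > 0))
  expect_equal(sum(t1$sojourn_ms), 5000, tolerance = 1e-9)
  ## successive states are connected in the generator
  idx <- match(t1$state, STATES$state)
  for (i in seq_len(nrow(t1) - 1)) {
    expect_gt(G_WT_REF$Q[idx[i], idx[i + 1]], 0)
  }
})

test_that("empirical state frequencies match the stationary distribution", {
  set.seed(77)
  tr <- simulate_trajectory(build_generator(OCC_WT, FLX_WT, 1, 10), 2e6)
  tf <- tapply(tr$sojourn_ms, tr$state, sum)
  z <- state_occupancies(OCC_WT, 1, 10)
  zn <- z / sum(z)
  emp <- tf[names(zn)] / sum(tf)
  emp[is.na(emp)] <- 0
  ## all states with meaningful stationary weight are visited at the
  ## right frequencies (loose multiple of the Monte-Carlo error)
  big <- zn > 1e-3
  expect_lt(max(abs(emp[big] - zn[big]) / zn[big]), 0.2)
})

test_that("saturating-IP3 open probabilities match the equilibrium law", {
  ## empirical Po at Ca = 1 uM, IP3 = 10 uM for both variants; the
  ## mutant's saturating Po approaches the observed 0.86 while the
  ## wild-type parameter set saturates near 0.52
  set.seed(78)
  G <- build_generator(OCC_WT, FLX_WT, 1, 10)
  tr <- to_idealized(simulate_trajectory(G, 5e6))
  po <- sum(tr$duration_ms[tr$conductance == 1L]) / sum(tr$duration_ms)
  expect_equal(po, open_probability(OCC_WT, 1, 10), tolerance = 0.03)
  Gm <- build_generator(OCC_MUT, FLX_MUT, 1, 10)
  trm <- to_idealized(simulate_trajectory(Gm, 2e6))
  pom <- sum(trm$duration_ms[trm$conductance == 1L]) / sum(trm$duration_ms)
  expect_equal(pom, open_probability(OCC_MUT, 1, 10), tolerance = 0.03)
  expect_equal(pom, 0.86, tolerance = 0.06)
})

test_that("mean simulated dwells match the equilibrium mean times", {
  set.seed(79)
  G <- build_generator(OCC_MUT, FLX_MUT, 1, 0.1)
  tr <- to_idealized(simulate_trajectory(G, 1.5e6))
  taus <- mean_times(G)
  od <- tr$duration_ms[tr$conductance == 1L]
  cd <- tr$duration_ms[tr$conductance == 0L]
  expect_gt(length(od), 1e4)
  ## successive dwells are correlated (modal persistence), so the
  ## standard errors come from batch means over 25 record segments
  batch_se <- function(x, nb = 25L) {
    b <- split(x, cut(seq_along(x), nb, labels = FALSE))
    stats::sd(vapply(b, mean, numeric(1))) / sqrt(nb)
  }
  expect_lt(abs(mean(od) - taus[["tau_o"]]), 3 * batch_se(od))
  expect_lt(abs(mean(cd) - taus[["tau_c"]]), 3 * batch_se(cd))
})

test_that("H-mode sojourns match the modal lifetime", {
  set.seed(80)
  G <- build_generator(OCC_MUT, FLX_MUT, 1, 0.1)
  tr <- simulate_trajectory(G, 1e6)
  md <- STATES$mode[match(tr$state, STATES$state)]
  grp <- cumsum(c(1L, (md[-1] == "H") != (md[-length(md)] == "H")))
  soj <- tapply(tr$sojourn_ms, grp, sum)
  inH <- tapply(md == "H", grp, function(x) x[1])
  hs <- soj[inH]
  ## drop the censored first/last sojourn
  hs <- hs[-c(1, length(hs))]
  se <- stats::sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - modal_lifetime(G, "H")), 3 * se)
})

test_that("idealization merges sojourns and trims record edges", {
  traj <- structure(
    data.frame(state = c("O24H", "C24H", "C04I", "O14I", "O24I", "C24I"),
               sojourn_ms = c(2, 1, 3, 4, 2, 5)),
    ca = 1, ip3 = 0.1, variant = "WT",
    class = c("ip3r_trajectory", "data.frame"))
  tr <- to_idealized(traj)
  ## leading open and trailing closed dwells trimmed; consecutive
  ## same-conductance sojourns merged (C24H + C04I -> 4 ms closed,
  ## O14I + O24I -> 6 ms open)
  expect_equal(tr$conductance, c(0L, 1L))
  expect_equal(tr$duration_ms, c(4, 6))
  ## dwell count equals the number of conductance alternations kept
  expect_equal(nrow(tr), 2L)
  ## a trajectory with no opening survives as a silent record
  silent <- structure(
    data.frame(state = c("C00L", "C04I"), sojourn_ms = c(100, 50)),
    ca = 1, ip3 = 0.1, variant = "WT",
    class = c("ip3r_trajectory", "data.frame"))
  s <- to_idealized(silent)
  expect_equal(s$conductance, 0L)
  expect_equal(s$duration_ms, 150)
  expect_false(has_openings(s))
})

test_that("trace ensembles round-trip through the CSV interchange format", {
  trs <- simulate_traces(OCC_WT, FLX_WT, 1, 0.1, n_records = 3,
                         record_ms = 5000, seed = 55)
  tmp <- tempfile(fileext = ".csv")
  write_traces(trs, tmp)
  back <- read_traces(tmp)
  expect_equal(length(back), length(trs))
  for (i in seq_along(trs)) {
    expect_equal(back[[i]]$duration_ms, trs[[i]]$duration_ms)
    expect_equal(back[[i]]$conductance, trs[[i]]$conductance)
    expect_equal(attr(back[[i]], "ca"), 1)
    expect_equal(attr(back[[i]], "ip3"), 0.1)
  }
})
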