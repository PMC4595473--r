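test_that("cluster geometry has symmetric positive distances", {
  g <- cluster_geometry()
  expect_equal(nrow(g$positions), 10L)
  d <- g$distances
  expect_equal(d, t(d))
  off <- d[upper.tri(d)]
  expect_true(all(off >= 0.12 - 1e-12))
  expect_equal(min(off), 0.12, tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0.0025, 10))
})

test_that("the resting field with equilibrated dye is a fixed point", {
  fs <- run_field_schedule(data.frame(t_end_s = 0.02, on = FALSE),
                           dt_s = 2e-5)
  expect_lt(max(abs(fs$c - buffer_params()$c_rest)), 1e-12)
  expect_lt(max(abs(fs$b - fs$b_rest)), 1e-11)
})

test_that("the buffer-free steady state matches the hemispherical point-source law", {
  buf <- buffer_params(B_d = 0)
  fs <- run_field_schedule(data.frame(t_end_s = 0.5, on = TRUE),
                           buffers = buf, dt_s = 2e-5)
  r <- fs$r_um
  q_um <- source_params()$I_pA * 1e-12 / (2 * 96485.33212) * 1e21  # umol/s
  pred <- buf$c_rest + q_um / (2 * pi * buf$D_c) * (1 / r - 1 / max(r))
  sel <- r > 0.01 & r < 1
  expect_lt(max(abs(fs$c[sel] - pred[sel]) / (pred[sel] - buf$c_rest)),
            0.05)
})

test_that("dye stays within its total concentration everywhere", {
  fs <- run_field_schedule(data.frame(t_end_s = c(0.1, 0.15),
                                      on = c(TRUE, FALSE)), dt_s = 2e-5)
  bp <- buffer_params()
  expect_true(all(fs$b >= 0))
  expect_true(all(fs$b <= bp$B_d + 1e-9))
  expect_true(all(fs$c >= 0))
})

test_that("calcium mass balance holds while the front is inside the domain", {
  ## with no buffer, total Ca gained in the domain equals source input
  ## while nothing has reached the absorbing boundary
  buf <- buffer_params(B_d = 0)
  grid <- radial_grid()
  vol <- 2 * pi / 3 * diff(grid$edges^3)  # hemisphere shell volumes, um^3
  t_on <- 0.002
  fs <- run_field_schedule(data.frame(t_end_s = t_on, on = TRUE),
                           buffers = buf, grid = grid, dt_s = 1e-5)
  gained <- sum((fs$c - buf$c_rest) * vol)          # uM um^3
  ## delivered charge as Ca: I/(2F) mol/s * t; 1 uM um^3 = 1e-21 mol
  src_uMum3 <- source_params()$I_pA * 1e-12 / (2 * 96485.33212) *
    t_on / 1e-21
  expect_equal(gained, src_uMum3, tolerance = 0.01)
})

test_that("field solutions converge under time-step and grid refinement", {
  buf <- buffer_params()
  sch <- data.frame(t_end_s = c(0.004, 0.008), on = c(TRUE, FALSE))
  base <- run_field_schedule(sch, buffers = buf, dt_s = 2e-5)
  half <- run_field_schedule(sch, buffers = buf, dt_s = 1e-5)
  ## temporal self-convergence at a representative radius (~120 nm)
  at <- function(fs, r0) stats::approx(fs$r_um, fs$c, r0)$y
  expect_lt(abs(at(base, 0.12) - at(half, 0.12)) /
              abs(at(half, 0.12) - buf$c_rest + 1e-12), 0.05)
  ## spatial refinement: doubled cell count changes the profile < 10%
  fine <- run_field_schedule(sch, buffers = buf,
                             grid = radial_grid(n_cells = 320L),
                             dt_s = 2e-5)
  ref <- run_field_schedule(sch, buffers = buf, dt_s = 2e-5)
  for (r0 in c(0.06, 0.12, 0.5)) {
    expect_lt(abs(at(ref, r0) - at(fine, r0)) /
                (abs(at(fine, r0) - buf$c_rest) + 1e-9), 0.10)
  }
})

test_that("cluster runs are reproducible and inert without IP3", {
  run0 <- run_cluster(OCC_WT, FLX_WT, ip3 = 0, duration_s = 2, seed = 90)
  expect_equal(max(run0$n_open), 0L)
  expect_equal(nrow(detect_events(run0)), 0L)
  expect_lt(max(abs(run0$ca_center_uM - buffer_params()$c_rest)), 1e-9)
  r1 <- run_cluster(OCC_MUT, FLX_MUT, ip3 = 0.1, duration_s = 2, seed = 91)
  r2 <- run_cluster(OCC_MUT, FLX_MUT, ip3 = 0.1, duration_s = 2, seed = 91)
  expect_identical(r1$n_open, r2$n_open)
  expect_identical(r1$ca_center_uM, r2$ca_center_uM)
})

test_that("clamped-coupling cluster gating reduces to independent channels", {
  ## with a vanishing channel current the fields stay at rest, so each
  ## channel gates at (c_rest, ip3): long-run mean open-channel count is
  ## 10 * Po
  run <- run_cluster(OCC_MUT, FLX_MUT, ip3 = 0.1, duration_s = 40,
                     source = source_params(I_pA = 1e-12), seed = 92)
  po <- open_probability(OCC_MUT, buffer_params()$c_rest, 0.1)
  expect_equal(mean(run$n_open), 10 * po, tolerance = 0.15)
})

test_that("open channels raise calcium at their neighbours and the center", {
  run <- run_cluster(OCC_MUT, FLX_MUT, ip3 = 0.1, duration_s = 2,
                     seed = 93)
  ## when anything is open the center sees more than rest
  openish <- run$n_open > 0
  expect_gt(max(run$ca_center_uM), 1)
  expect_gt(stats::cor(run$n_open, run$ca_center_uM), 0.3)
  expect_true(all(run$dye_bound_center_uM >= 0))
})
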