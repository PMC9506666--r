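test_that("an unstimulated run stays at the fixed point", {
  p <- stc_params(N = 1)
  # spine never stimulated within the simulated span
  sch <- make_schedule(n_E = 1, s_E1_min = 1e5)
  tr <- stc_integrate(p, sch, t_start = 0, t_end = 180 * 60)
  y0 <- steady_state_baseline(p)
  expect_lt(max(abs(sweep(tr$states, 2, y0))), 1e-6)
})

test_that("e-LTP raises the tag but not dendritic PRPs; volume relaxes", {
  tr <- eltp_trajectory()
  expect_gt(max(tr$states[, "T_p1"]), 0.9)       # tag set
  expect_lt(max(tr$states[, "P_d"]), 5e-3)       # no PRP synthesis
  expect_lt(max(tr$states[, "U_d"]), 0.01)
  w <- tr$states[, "W1"]
  expect_gt(max(w), 0.3)                         # transient expansion
  expect_lt(w[length(w)], 0.11)                  # decays back
  expect_lt(max(tr$states[, "Z1"]) - 0.10, 1e-4) # no consolidation
})

test_that("l-LTP triggers PRP synthesis and consolidates Z toward W", {
  tr <- lltp_trajectory()
  expect_gt(max(tr$states[, "U_d"]), 0.9)
  expect_gt(max(tr$states[, "P_d"]), 0.5)        # synthesis burst
  n <- nrow(tr$states)
  expect_gt(tr$states[n, "Z1"], 0.2)             # consolidated
  expect_lt(abs(tr$states[n, "W1"] - tr$states[n, "Z1"]), 1e-3)
})

test_that("trajectories preserve state bounds and W >= Z", {
  for (tr in list(eltp_trajectory(), lltp_trajectory())) {
    expect_true(check_trajectory(tr, tol = 1e-6))
    ix <- stcsim:::state_index(tr$params$N)
    expect_true(all(tr$states[, ix$W] - tr$states[, ix$Z] >= -1e-8))
  }
})

test_that("adaptive compiled path agrees with the fixed-step RK4 oracle", {
  # 10-min single-spine e-LTP comparison on a shared sample grid
  p <- stc_params(N = 1)
  sch <- make_schedule(n_E = 1, s_E1_min = 0)
  t_end <- 600
  # atol well below 1e-5 x the smallest variable scale (U_d stays ~1e-5
  # under e-LTP), so the comparison probes truncation error, not atol
  tr_a <- stc_integrate(p, sch, sample_dt = 30, t_start = -60,
                        t_end = t_end, atol = 1e-14)
  tr_o <- stc_integrate_rk4(p, sch, sample_dt = 30, t_start = -60,
                            t_end = t_end)
  shared <- intersect(tr_a$times, tr_o$times)
  ia <- match(shared, tr_a$times)
  io <- match(shared, tr_o$times)
  scale <- apply(abs(tr_o$states[io, ]), 2, max)
  rel <- abs(tr_a$states[ia, ] - tr_o$states[io, ]) /
    rep(pmax(scale, 1e-12), each = length(shared))
  expect_lt(max(rel), 1e-5)
})

test_that("solver tolerance refinement leaves W180 unchanged to 1e-4", {
  p <- stc_params(N = 2)
  sch <- make_schedule(n_E = 1, s_E1_min = -30, lltp_at_min = 0)
  w1 <- readout_W180(stc_integrate(p, sch), "E1")
  w2 <- readout_W180(stc_integrate(p, sch, rtol = 5e-9, atol = 5e-11),
                     "E1")
  expect_lt(abs(w1 - w2), 1e-4)
})

test_that("time translation shifts the trajectory exactly", {
  p <- stc_params(N = 1)
  shift_min <- 45
  tr0 <- stc_integrate(p, make_schedule(n_E = 1, s_E1_min = 0),
                       t_start = -300, t_end = 1800)
  tr1 <- stc_integrate(p, make_schedule(n_E = 1, s_E1_min = shift_min),
                       t_start = -300 + shift_min * 60,
                       t_end = 1800 + shift_min * 60)
  expect_equal(tr1$times, tr0$times + shift_min * 60)
  expect_equal(tr1$states, tr0$states, tolerance = 1e-10)
})

test_that("permuting spine roles permutes per-spine outputs identically", {
  # same physical setup, L1 listed first vs E-spines first is not
  # expressible via make_schedule; instead check E-spine exchange symmetry:
  # synchronized E-spines must produce identical trajectories (within
  # solver tolerance) and identical readouts
  p <- stc_params(N = 4)
  sch <- make_schedule(n_E = 3, s_E1_min = -10, ds_E_min = 0,
                       lltp_at_min = 0, synchronized = TRUE)
  tr <- stc_integrate(p, sch)
  expect_equal(tr$states[, "W2"], tr$states[, "W3"], tolerance = 1e-10)
  expect_equal(tr$states[, "W2"], tr$states[, "W4"], tolerance = 1e-10)
  expect_equal(tr$states[, "P_s2"], tr$states[, "P_s4"], tolerance = 1e-10)
  expect_equal(readout_W180(tr, "E1"), readout_W180(tr, "E3"),
               tolerance = 1e-10)
})

test_that("readout interpolates at onset + 180 min and validates labels", {
  tr <- eltp_trajectory()
  expect_error(readout_W180(tr, "L7"), "unknown spine label")
  w <- tr$states[, "W1"]
  expect_equal(readout_W180(tr, "E1"),
               stats::approx(tr$times, w, xout = 180 * 60)$y)
  short <- stc_integrate(stc_params(N = 1),
                         make_schedule(n_E = 1, s_E1_min = 0),
                         t_end = 600)
  expect_error(readout_W180(short, "E1"), "ends before")
})

test_that("tidy export has one row per sample and variable", {
  tr <- eltp_trajectory()
  df <- as.data.frame(tr)
  expect_identical(names(df),
                   c("time_s", "variable", "spine_label", "value"))
  expect_equal(nrow(df), length(tr$times) * ncol(tr$states))
  expect_true(all(is.na(df$spine_label[df$variable == "P_d"])))
  expect_true(all(df$spine_label[df$variable == "W"] == "E1"))
})
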