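test_that("e-LTP train is 30 x 5 ms pulses at 0.5 Hz", {
  tr <- make_eltp_protocol(0)
  expect_equal(nrow(tr), 30L)
  expect_equal(tr[, "start_s"], 2.0 * (0:29))
  expect_equal(tr[, "end_s"] - tr[, "start_s"], rep(0.005, 30))
  # total span first onset to last offset
  expect_equal(unname(tr[30, "end_s"] - tr[1, "start_s"]),
               29 * 2.0 + 0.005)
  # pure time translation
  tr2 <- make_eltp_protocol(-60)
  expect_equal(tr2, tr - 3600)
})

test_that("l-LTP protocol adds a drug window covering the train", {
  lp <- make_lltp_protocol(0)
  expect_equal(lp$pulses, make_eltp_protocol(0))
  expect_equal(lp$drug_window, c(0, 58.005))
  lp2 <- make_lltp_protocol(0, drug_duration_s = 900)
  expect_equal(lp2$drug_window, c(0, 900))
})

test_that("asynchronous onsets recede from t = 0 so E1 is closest", {
  sch <- make_schedule(n_E = 3, s_E1_min = -10, ds_E_min = 5,
                       lltp_at_min = 0)
  on <- schedule_onsets(sch) / 60
  expect_equal(unname(on[c("E1", "E2", "E3")]), c(-10, -15, -20))
  expect_equal(unname(on["L1"]), 0)
  expect_true(all(diff(abs(on[c("E1", "E2", "E3")])) > 0))
  # right window marches forward in time
  schr <- make_schedule(n_E = 3, s_E1_min = 10, ds_E_min = 5)
  expect_equal(unname(schedule_onsets(schr) / 60), c(10, 15, 20))
})

test_that("synchronized schedules share one onset and labels are unique", {
  sch <- make_schedule(n_E = 5, s_E1_min = 30, ds_E_min = 0,
                       synchronized = TRUE)
  on <- schedule_onsets(sch)
  expect_equal(unname(on), rep(1800, 5))
  expect_false(any(duplicated(schedule_labels(sch))))
  # building twice yields identical pulse data
  expect_identical(sch, make_schedule(n_E = 5, s_E1_min = 30, ds_E_min = 0,
                                      synchronized = TRUE))
})

test_that("schedule validation enforces the spine budget", {
  expect_error(make_schedule(n_E = 20, lltp_at_min = 0), "budget")
  expect_error(make_schedule(n_E = 2, s_E1_min = 0, ds_E_min = -1))
  expect_error(make_schedule(n_E = 0), "at least one spine")
})

test_that("per-spine pulses never overlap and Y is binary", {
  sch <- make_schedule(n_E = 2, s_E1_min = -10, ds_E_min = 1,
                       lltp_at_min = 0)
  for (sp in sch$spines) {
    expect_true(all(sp$pulses[-1, "start_s"] >=
                      sp$pulses[-nrow(sp$pulses), "end_s"]))
  }
  for (t in c(-600, 0, 0.002, 0.01, 2.004, 30)) {
    inp <- stcsim:::schedule_inputs_at(sch, t, 100)
    expect_true(all(inp$Y %in% c(0, 1)))
  }
  # drug factor only inside L1's window
  expect_equal(stcsim:::schedule_inputs_at(sch, 30, 100)$alpha_mult, 100)
  expect_equal(stcsim:::schedule_inputs_at(sch, 60, 100)$alpha_mult, 1)
})

test_that("unit drug gain degenerates l-LTP into e-LTP", {
  p <- stc_params(N = 1, lltp_gain = 1)
  tr_l <- stc_integrate(p, make_schedule(n_E = 0, lltp_at_min = 0),
                        t_end = 1200)
  tr_e <- stc_integrate(stc_params(N = 1),
                        make_schedule(n_E = 1, s_E1_min = 0), t_end = 1200)
  expect_equal(tr_l$states, tr_e$states, tolerance = 1e-12)
})

test_that("schedules serialize to JSON with protocol metadata", {
  sch <- make_schedule(n_E = 1, s_E1_min = -30, lltp_at_min = 0)
  doc <- jsonlite::fromJSON(schedule_to_json(sch), simplifyVector = FALSE)
  expect_equal(doc$n, 2L)
  expect_equal(vapply(doc$spines, `[[`, character(1), "label"),
               c("L1", "E1"))
  expect_equal(doc$spines[[2]]$onset_min, -30)
  expect_equal(doc$spines[[2]]$n_pulses, 30L)
})
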