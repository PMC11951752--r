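# Discrete-event engine: weekly slot release, FIFO discipline, conservation,
# windowed statistics, and equivalence with a naive week-by-week simulator.

test_that("empty pathway produces all-zero counters and an empty window", {
  cfg <- scenario_config(backlog = 0, horizon_weeks = 52,
                         report_windows = list(c(0, 52)))
  res <- run_replication(make_patients(numeric(0)), cfg)
  expect_true(all(res$totals == 0))
  expect_equal(res$windows$mean_wait_weeks, 0)
  expect_equal(res$windows$n_served, 0)
})

test_that("a 228-patient backlog at 12 slots/week clears at week 19", {
  cohort <- assemble_cohort(generate_backlog(228, rng_seed = 1),
                            make_patients(numeric(0)))
  cfg <- scenario_config(horizon_weeks = 52, report_windows = list(c(0, 52)))
  res <- run_replication(cohort, cfg)
  p <- res$patients
  expect_equal(max(p$edt_week), 19)           # ceil(228/12) weekly releases
  expect_equal(max(p$wait_weeks), 19)
  expect_equal(sum(p$edt_week == 19), 228 - 18 * 12)
  expect_true(all(table(p$edt_week) <= 12))   # never above capacity
  expect_equal(res$totals[["end_queue_length"]], 0)
})

test_that("weekly_service_step serves FIFO up to the slot count", {
  q <- make_patients(c(0, 0, 1, 2, 3))
  step <- weekly_service_step(q, 12, 3)
  expect_equal(nrow(step$served), 5)
  expect_equal(nrow(step$queue), 0)

  q <- make_patients(rep(0, 30))
  step <- weekly_service_step(q, 12, 1)
  expect_equal(step$served$id, 1:12)          # earliest ids first
  expect_equal(nrow(step$queue), 18)
  expect_true(all(step$served$edt_week == 1))
  expect_true(all(step$served$wait_weeks == 1))

  empty <- weekly_service_step(make_patients(numeric(0)), 12, 1)
  expect_equal(nrow(empty$served), 0)

  # patients arriving after `now` are not eligible
  q <- make_patients(c(0.5, 4.5))
  step <- weekly_service_step(q, 12, 1)
  expect_equal(nrow(step$served), 1)
})

test_that("engine schedule equals the naive weekly loop on random cases", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(30:150, 1)
    cap <- sample(2:6, 1)
    horizon <- 40
    pats <- make_patients(sort(runif(n, 0, horizon)))
    cfg <- scenario_config(backlog = 0, capacity_per_week = cap,
                           horizon_weeks = horizon,
                           report_windows = list(c(0, horizon)))
    res <- run_replication(pats, cfg)
    expect_equal(res$patients$edt_week,
                 naive_serve_weeks(pats, cap, horizon))
  }
})

test_that("patients are conserved and FIFO order respected", {
  cohort <- assemble_cohort(generate_backlog(50, rng_seed = 2),
                            generate_referrals(audit_params(), 60,
                                               rng_seed = 2))
  cfg <- scenario_config(screening_enabled = TRUE, backlog = 50,
                         horizon_weeks = 60, report_windows = list(c(0, 60)))
  res <- run_replication(cohort, cfg)
  tt <- res$totals
  # referred + backlog = screened out + in queue + served
  expect_equal(tt[["n_referred"]] + 50,
               tt[["n_screened_out"]] + tt[["end_queue_length"]] +
                 tt[["n_edt_performed"]])
  expect_equal(tt[["n_edt_required"]],
               tt[["n_edt_performed"]] + tt[["end_queue_length"]])
  # conservation of screened patients into confusion classes
  expect_equal(tt[["n_screened"]],
               tt[["TP"]] + tt[["FP"]] + tt[["TN"]] + tt[["FN"]])
  expect_equal(tt[["n_screened_out"]], tt[["TN"]] + tt[["FN"]])

  p <- res$patients
  served <- p[!is.na(p$edt_week), ]
  served <- served[order(served$arrival_week, served$id), ]
  expect_true(all(diff(served$edt_week) >= 0))      # FIFO among entrants
  expect_true(all(served$wait_weeks >= 0))
  expect_true(all(table(served$edt_week) <= cfg$capacity_per_week))
  # group D and backlog patients are never screened
  expect_true(all(is.na(p$screen_flagged[p$group == "D"])))
  expect_true(all(is.na(p$screen_flagged[p$source == "backlog"])))
})

test_that("arrival exactly at a slot release is eligible at that release", {
  pats <- make_patients(c(1, 2))
  res <- run_replication(pats, scenario_config(backlog = 0,
                                               horizon_weeks = 10,
                                               report_windows = list(c(0, 10))))
  expect_equal(res$patients$edt_week, c(1, 2))
  expect_equal(res$patients$wait_weeks, c(0, 0))
})

test_that("backlog accrued-wait credit is added to recorded waits", {
  cohort <- assemble_cohort(generate_backlog(12, rng_seed = 1),
                            make_patients(numeric(0)))
  cfg <- scenario_config(backlog = 12, horizon_weeks = 10,
                         report_windows = list(c(0, 10)),
                         backlog_accrued_weeks = 13.6)
  res <- run_replication(cohort, cfg)
  expect_equal(res$patients$wait_weeks, rep(1 + 13.6, 12))
})

test_that("unsorted input is rejected", {
  pats <- make_patients(c(3, 1))
  pats$arrival_week <- c(3, 1) # force out of order
  expect_error(run_replication(pats, scenario_config()), "sorted")
})

test_that("measure_window uses the serving-time convention", {
  p <- make_patients(3)
  p$edt_week <- 10
  p$wait_weeks <- 7
  expect_equal(measure_window(p, c(0, 26)),
               list(mean_wait_weeks = 7, n_served = 1L, empty = FALSE))
  # window boundaries: (start, end]
  expect_equal(measure_window(p, c(10, 20))$n_served, 0)
  expect_equal(measure_window(p, c(9, 10))$n_served, 1)
  empty <- measure_window(p, c(20, 30))
  expect_true(empty$empty)
  expect_equal(empty$mean_wait_weeks, 0)
})
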