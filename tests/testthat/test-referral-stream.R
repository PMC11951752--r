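# Synthetic referral-cohort generator: audit-derived defaults, Poisson
# stream properties, backlog construction, CSV round-trips.

test_that("default group parameters reproduce the 13-week audit arithmetic", {
  gp <- default_group_params()
  expect_equal(gp$group, c("A", "B", "C", "D"))
  expect_equal(gp$weekly_rate, c(77, 14, 40, 64) / 13)
  expect_equal(sum(gp$weekly_rate), 15)            # 195 per quarter
  expect_equal(52 * sum(gp$weekly_rate), 780)      # expected yearly total
  expect_equal(gp$p_abnormal, c(23 / 77, 4 / 14, 5 / 40, NA))
  expect_equal(gp$p_abnormal[gp$group == "C"], 0.125) # 87% normal rounded
  expect_false(gp$screenable[gp$group == "D"])
  expect_error(group_params(c(-1, 1, 1, 1), c(.1, .1, .1)), "non-negative")
  expect_error(group_params(c(1, 1, 1, 1), c(.1, .1, 1.2)), "probabilities")
})

test_that("referral stream is Poisson at the scaled audit rates", {
  gp <- audit_params()
  n_seeds <- 300
  counts <- vapply(seq_len(n_seeds), function(s) {
    nrow(generate_referrals(gp, horizon_weeks = 26, rng_seed = s))
  }, numeric(1))
  # mean count: 15/wk x 26 wk = 390; MC tolerance 4 standard errors
  se <- sqrt(390 / n_seeds)
  expect_lt(abs(mean(counts) - 390), 4 * se)

  # dispersion: per-week counts over many seeds have variance ~ mean
  week_counts <- vapply(seq_len(500), function(s) {
    nrow(generate_referrals(gp, horizon_weeks = 1, rng_seed = 1000 + s))
  }, numeric(1))
  disp <- (length(week_counts) - 1) * var(week_counts) / mean(week_counts)
  expect_gt(disp, qchisq(0.005, length(week_counts) - 1))
  expect_lt(disp, qchisq(0.995, length(week_counts) - 1))
})

test_that("group mix and abnormality draws match the audit proportions", {
  gp <- audit_params()
  pooled <- do.call(rbind, lapply(1:40, function(s) {
    generate_referrals(gp, horizon_weeks = 52, rng_seed = s)
  }))
  obs <- table(factor(pooled$group, levels = c("A", "B", "C", "D")))
  gof <- chisq.test(obs, p = c(77, 14, 40, 64) / 195)
  expect_gt(gof$p.value, 0.001)

  # abnormality fraction per group near p_abnormal
  for (g in c("A", "B", "C")) {
    sub <- pooled[pooled$group == g, ]
    p <- gp$p_abnormal[gp$group == g]
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$true_abnormal) - p), 4 * se)
  }
  expect_true(all(is.na(pooled$true_abnormal[pooled$group == "D"])))

  # abnormality independent of arrival time
  abc <- pooled[pooled$group != "D", ]
  ct <- cor.test(abc$arrival_week, as.numeric(abc$true_abnormal))
  expect_gt(ct$p.value, 0.001)
})

test_that("demand scaling and degenerate horizons behave", {
  gp <- audit_params()
  counts <- vapply(1:150, function(s) {
    nrow(generate_referrals(gp, 26, demand_scale = 1.25, rng_seed = s))
  }, numeric(1))
  se <- sqrt(390 * 1.25 / 150)
  expect_lt(abs(mean(counts) - 390 * 1.25), 4 * se)

  expect_lte(nrow(generate_referrals(gp, 1e-9, rng_seed = 1)), 1)
  expect_error(generate_referrals(gp, 0), "positive")
  expect_error(generate_referrals(gp, -5), "positive")
  expect_error(generate_referrals(gp, 10, demand_scale = 0), "positive")
})

test_that("referral records are sorted, sequentially numbered, unstamped", {
  pats <- generate_referrals(audit_params(), 52, rng_seed = 3)
  expect_false(is.unsorted(pats$arrival_week))
  expect_equal(pats$id, seq_len(nrow(pats)))
  expect_true(all(pats$source == "referral"))
  expect_true(all(is.na(pats$edt_week)))
  expect_true(all(is.na(pats$screen_flagged)))
})

test_that("backlog generation places n patients on the list at week 0", {
  b <- generate_backlog(228, audit_params(), rng_seed = 5)
  expect_equal(nrow(b), 228)
  expect_true(all(b$arrival_week == 0))
  expect_true(all(b$source == "backlog"))
  expect_true(all(is.na(b$edt_week)))
  expect_true(all(is.na(b$true_abnormal[b$group == "D"])))
  expect_true(all(!is.na(b$true_abnormal[b$group != "D"])))
  expect_equal(nrow(generate_backlog(0)), 0)
  expect_error(generate_backlog(-1), "non-negative")
})

test_that("identical seeds give byte-identical CSV output", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_patients(generate_referrals(audit_params(), 26, rng_seed = 11), f1)
  write_patients(generate_referrals(audit_params(), 26, rng_seed = 11), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("patient CSV round-trips field for field", {
  f <- tempfile(fileext = ".csv")

  write_patients(generate_referrals(audit_params(), 1e-9, rng_seed = 1), f)
  expect_equal(length(readLines(f)), 1L) # header only

  b <- generate_backlog(228, rng_seed = 2)
  write_patients(b, f)
  expect_equal(length(readLines(f)), 229L)

  pats <- assemble_cohort(generate_backlog(20, rng_seed = 1),
                          generate_referrals(audit_params(), 30, rng_seed = 1))
  res <- run_replication(pats, scenario_config(screening_enabled = TRUE,
                                               horizon_weeks = 30,
                                               report_windows = list(c(0, 30)),
                                               backlog = 20))
  write_patients(res$patients, f)
  back <- read_patients(f)
  expect_equal(back, res$patients)
  f2 <- tempfile(fileext = ".csv")
  write_patients(back, f2) # re-serialisation is bit-stable
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed patient rows are reported with line numbers", {
  f <- tempfile(fileext = ".csv")
  write_patients(generate_backlog(3, rng_seed = 1), f)
  lines <- readLines(f)
  lines[3] <- sub("^2,backlog", "2,junk", lines[3])
  writeLines(lines, f)
  expect_error(read_patients(f), "line\\(s\\) 3")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_patients(f), "header")
})
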