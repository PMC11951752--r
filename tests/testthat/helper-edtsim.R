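# Shared helpers: hand-built cohorts, a naive week-by-week reference
# simulator, and a numeric-quadrature oracle for the fluid waits.

# Minimal patient frame from arrival times (referrals unless stated).
make_patients <- function(arrival_week, group = "D",
                          source = "referral", true_abnormal = NA) {
  n <- length(arrival_week)
  ord <- order(arrival_week)
  data.frame(
    id = seq_len(n),
    source = rep_len(source, n)[ord],
    arrival_week = arrival_week[ord],
    group = rep_len(group, n)[ord],
    true_abnormal = rep_len(true_abnormal, n)[ord],
    screen_flagged = rep(NA, n),
    edt_week = rep(NA_real_, n),
    wait_weeks = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

# Reference service times by literally iterating weekly_service_step over
# integer weeks; independent of the engine's vectorised schedule.
naive_serve_weeks <- function(patients, capacity, horizon_weeks,
                              accrued = 0) {
  queue <- patients
  served_all <- patients[0, ]
  for (wk in seq_len(floor(horizon_weeks))) {
    step <- weekly_service_step(queue, capacity, wk, accrued)
    served_all <- rbind(served_all, step$served)
    queue <- step$queue
  }
  out <- rep(NA_real_, nrow(patients))
  out[match(served_all$id, patients$id)] <- served_all$edt_week
  out
}

# Riemann-sum version of the fluid windowed wait (independent of the
# closed-form piecewise integration in the package).
quadrature_fluid_wait <- function(lambda, capacity, backlog, window,
                                  accrued = 0, dt = 0.001) {
  tb <- backlog / capacity
  ts <- if (lambda < capacity) backlog / (capacity - lambda) else Inf
  t <- seq(window[1] + dt / 2, window[2] - dt / 2, by = dt)
  wait <- ifelse(t <= tb, t + accrued,
                 ifelse(t < ts,
                        t * (1 - capacity / lambda) + backlog / lambda, 0))
  weight <- ifelse(t < ts, capacity, lambda)
  if (sum(weight) == 0) return(0)
  sum(wait * weight) / sum(weight)
}

audit_params <- function() default_group_params()
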