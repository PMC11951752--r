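# Deterministic fluid approximation of the EDT queue: closed-form waiting
# time trajectories used as an analytic oracle for every simulated scenario.

#' Effective arrival rate into the laboratory EDT queue
#'
#' With screening off, every referral joins the queue, so the effective rate
#' is the total referral rate. With screening on, a screened group
#' contributes only its flagged fraction
#' \eqn{\lambda_g (p_g Se + (1 - p_g)(1 - Sp))}; unscreened groups (always
#' including D) contribute their full rate. Everything scales with
#' `demand_scale`.
#'
#' @param config A [scenario_config()] object.
#' @param group_params A `group_params` data frame.
#' @return Effective arrivals per week into the EDT queue.
#' @examples
#' effective_rate(scenario_config(), default_group_params()) # 15/week
#' @export
effective_rate <- function(config, group_params = default_group_params()) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(group_params, "group_params"))
  lam <- group_params$weekly_rate
  if (!config$screening_enabled) {
    return(config$demand_scale * sum(lam))
  }
  scr <- config$screening
  screened <- group_params$group %in% scr$screened_groups
  p <- group_params$p_abnormal
  pass <- p * scr$sensitivity + (1 - p) * (1 - scr$specificity)
  config$demand_scale *
    (sum(lam[!screened]) + sum(lam[screened] * pass[screened]))
}

#' Fluid-queue state for a scenario
#'
#' Summarises the deterministic-flow view of a scenario: effective arrival
#' rate, weekly capacity, initial backlog, and the clearance time
#' \eqn{t^* = B / (c - \lambda)} (infinite when \eqn{\lambda \ge c}).
#'
#' @inheritParams effective_rate
#' @return List with `lambda_eff`, `capacity`, `backlog`,
#'   `backlog_cleared_week` (`B/c`), `clearance_week` (`t*`, possibly `Inf`)
#'   and `accrued_weeks`.
#' @export
fluid_state <- function(config, group_params = default_group_params()) {
  lam <- effective_rate(config, group_params)
  c_  <- config$capacity_per_week
  b   <- config$backlog
  list(
    lambda_eff = lam,
    capacity = c_,
    backlog = b,
    backlog_cleared_week = b / c_,
    clearance_week = if (lam < c_) b / (c_ - lam) else Inf,
    accrued_weeks = config$backlog_accrued_weeks
  )
}

#' Fluid-approximation mean wait over a window
#'
#' In the fluid model the queue drains at rate `c` while work remains. A
#' patient served at time `t <= B/c` is a backlog patient and has waited `t`
#' (plus any accrued credit); a patient served at `t > B/c` arrived at
#' \eqn{(ct - B)/\lambda}, so waits \eqn{t(1 - c/\lambda) + B/\lambda}. When
#' \eqn{\lambda < c} the wait reaches zero at the clearance time
#' \eqn{t^* = B/(c - \lambda)} and stays zero. The windowed mean integrates
#' the wait trajectory weighted by the service rate (`c` while draining,
#' \eqn{\lambda} after clearance), in exact piecewise-linear closed form.
#'
#' @param state A [fluid_state()] list.
#' @param window `c(start, end)` in weeks.
#' @return List with `mean_wait_weeks` and `served` (fluid mass served in
#'   the window).
#' @export
fluid_window_wait <- function(state, window) {
  stopifnot(length(window) == 2L, window[1] < window[2], window[1] >= 0)
  lam <- state$lambda_eff
  c_  <- state$capacity
  b   <- state$backlog
  tb  <- state$backlog_cleared_week
  ts  <- state$clearance_week

  # wait(t) on each regime, linear in t: wait = slope * t + intercept
  pieces <- list()
  if (b > 0) {
    pieces[[length(pieces) + 1L]] <-
      list(from = 0, to = tb, slope = 1, intercept = state$accrued_weeks,
           weight = c_)
  }
  if (lam > 0) {
    pieces[[length(pieces) + 1L]] <-
      list(from = tb, to = ts, slope = 1 - c_ / lam, intercept = b / lam,
           weight = c_)
  }
  if (is.finite(ts)) {
    pieces[[length(pieces) + 1L]] <-
      list(from = ts, to = Inf, slope = 0, intercept = 0, weight = lam)
  }

  total_wait <- 0
  total_mass <- 0
  for (p in pieces) {
    lo <- max(window[1], p$from)
    hi <- min(window[2], p$to)
    if (hi <= lo) next
    seg_wait <- p$slope * (hi^2 - lo^2) / 2 + p$intercept * (hi - lo)
    total_wait <- total_wait + p$weight * seg_wait
    total_mass <- total_mass + p$weight * (hi - lo)
  }
  list(
    mean_wait_weeks = if (total_mass > 0) total_wait / total_mass else 0,
    served = total_mass
  )
}

#' Fluid-oracle summary for a scenario
#'
#' Convenience wrapper: the fluid state plus the mean wait for each of the
#' scenario's report windows.
#'
#' @inheritParams effective_rate
#' @return List with `state` and a data frame `windows`.
#' @export
fluid_oracle <- function(config, group_params = default_group_params()) {
  st <- fluid_state(config, group_params)
  windows <- do.call(rbind, lapply(config$report_windows, function(w) {
    fw <- fluid_window_wait(st, w)
    data.frame(start = w[1], end = w[2],
               mean_wait_weeks = fw$mean_wait_weeks, served = fw$served)
  }))
  list(state = st, windows = windows)
}
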