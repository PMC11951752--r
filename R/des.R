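# Discrete-event engine: FIFO waiting list for laboratory EDT with weekly
# appointment-slot release, screening at the point of referral, and windowed
# waiting-time statistics per replication.

#' Scenario configuration
#'
#' One fully specified simulation scenario: whether and how screening is
#' applied, laboratory capacity, initial backlog, demand scaling, horizon and
#' reporting windows.
#'
#' @param screening_enabled Apply the hand-held ERG screen to arriving
#'   patients in the screened groups? Backlog patients always bypass
#'   screening.
#' @param screening A [screening_params()] object.
#' @param capacity_per_week Laboratory EDT appointment slots released each
#'   week (positive integer; 12 in the audited service).
#' @param backlog Number of patients on the waiting list at time zero
#'   (228 in the audited service).
#' @param demand_scale Multiplier on all referral rates.
#' @param horizon_weeks Simulated horizon (weeks); slots are released at
#'   integer weeks 1, 2, ..., `floor(horizon_weeks)`.
#' @param report_windows List of `c(start, end)` windows (weeks); a patient
#'   is counted in a window when its service week lies in `(start, end]`.
#' @param rng_seed Seed for the screening random-number stream (arrivals are
#'   seeded when generated, so the two streams are independent and common
#'   random numbers across screening cells are possible).
#' @param backlog_accrued_weeks Waiting-time credit added to backlog
#'   patients' recorded waits for time already spent on the list before the
#'   simulation starts (default 0).
#' @param label Optional scenario label used in reports.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(screening_enabled = FALSE,
                            screening = screening_params(),
                            capacity_per_week = 12L,
                            backlog = 228L,
                            demand_scale = 1,
                            horizon_weeks = 260,
                            report_windows = list(c(0, 260)),
                            rng_seed = 1L,
                            backlog_accrued_weeks = 0,
                            label = NULL) {
  stopifnot(inherits(screening, "screening_params"))
  if (!is.numeric(capacity_per_week) || capacity_per_week < 1 ||
      capacity_per_week != round(capacity_per_week)) {
    stop("'capacity_per_week' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(backlog) || backlog < 0 || backlog != round(backlog)) {
    stop("'backlog' must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(demand_scale) || demand_scale <= 0) {
    stop("'demand_scale' must be positive", call. = FALSE)
  }
  if (!is.numeric(horizon_weeks) || horizon_weeks <= 0) {
    stop("'horizon_weeks' must be positive", call. = FALSE)
  }
  if (!is.numeric(backlog_accrued_weeks) || backlog_accrued_weeks < 0) {
    stop("'backlog_accrued_weeks' must be non-negative", call. = FALSE)
  }
  for (w in report_windows) {
    if (length(w) != 2L || w[1] < 0 || w[2] > horizon_weeks || w[1] >= w[2]) {
      stop("each report window must be c(start, end) with ",
           "0 <= start < end <= horizon_weeks", call. = FALSE)
    }
  }
  structure(
    list(screening_enabled = isTRUE(screening_enabled),
         screening = screening,
         capacity_per_week = as.integer(capacity_per_week),
         backlog = as.integer(backlog),
         demand_scale = demand_scale,
         horizon_weeks = horizon_weeks,
         report_windows = report_windows,
         rng_seed = rng_seed,
         backlog_accrued_weeks = backlog_accrued_weeks,
         label = label),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("EDT pathway scenario",
      if (!is.null(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  screening: %s", if (x$screening_enabled) "on" else "off"))
  if (x$screening_enabled) {
    cat(sprintf(" (Se %.2f, Sp %.2f, groups %s)",
                x$screening$sensitivity, x$screening$specificity,
                paste(x$screening$screened_groups, collapse = "")))
  }
  cat(sprintf("\n  capacity %d/week, backlog %d, demand x%.2f, horizon %g wk\n",
              x$capacity_per_week, x$backlog, x$demand_scale,
              x$horizon_weeks))
  invisible(x)
}

#' Serve one weekly slot release
#'
#' The single-step service primitive: at integer week `now`, up to `slots`
#' of the longest-waiting eligible patients (arrival at or before `now`) are
#' removed from the queue in arrival order (ties broken by id) and stamped
#' with their service week and wait.
#'
#' @param queue Patient data frame of patients currently waiting.
#' @param slots Positive number of appointment slots this week.
#' @param now Integer week of the slot release.
#' @param accrued_weeks Wait credit added for backlog patients.
#' @return List with `served` (stamped records) and `queue` (the remainder).
#' @export
weekly_service_step <- function(queue, slots, now, accrued_weeks = 0) {
  ord <- order(queue$arrival_week, queue$id)
  queue <- queue[ord, , drop = FALSE]
  eligible <- which(queue$arrival_week <= now)
  take <- eligible[seq_len(min(slots, length(eligible)))]
  served <- queue[take, , drop = FALSE]
  if (nrow(served)) {
    served$edt_week <- now
    served$wait_weeks <- now - served$arrival_week +
      ifelse(served$source == "backlog", accrued_weeks, 0)
  }
  remaining <- if (length(take)) queue[-take, , drop = FALSE] else queue
  list(served = served, queue = remaining)
}

# Serve week for every queue entrant, vectorised. Entrants must be in FIFO
# (arrival, id) order. With weekly batches of size c at integer weeks and
# eligibility week e_k = max(1, ceiling(arrival)), the serve week obeys
# s_k = max(e_k, s_{k-c} + 1); the recursion decouples across residue
# classes mod c, where it is a running maximum. Entrants not served by
# floor(horizon_weeks) get NA.
service_schedule <- function(arrival_week, capacity, horizon_weeks) {
  n <- length(arrival_week)
  if (n == 0L) return(numeric(0))
  elig <- pmax(1, ceiling(arrival_week))
  serve <- numeric(n)
  for (r in seq_len(min(capacity, n))) {
    idx <- seq.int(r, n, by = capacity)
    j <- seq_along(idx)
    serve[idx] <- j + cummax(elig[idx] - j)
  }
  serve[serve > floor(horizon_weeks)] <- NA_real_
  serve
}

#' Run one replication of the pathway
#'
#' Applies the screening step (when enabled) to arriving patients in the
#' screened groups, sends flagged, unscreened, group D and backlog patients
#' into the FIFO laboratory EDT queue, serves the queue at weekly slot
#' releases, and collects windowed waiting-time statistics and pathway
#' counters.
#'
#' @param patients Patient data frame sorted by `arrival_week` (backlog
#'   first), e.g. from [assemble_cohort()].
#' @param config A [scenario_config()] object; `config$rng_seed` seeds the
#'   screening draws only.
#' @return An object of class `replication_result`: a list with `windows`
#'   (data frame of `start`, `end`, `mean_wait_weeks`, `n_served`),
#'   `totals` (named numeric vector of pathway counters) and `patients`
#'   (the stamped patient records).
#' @export
run_replication <- function(patients, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.unsorted(patients$arrival_week)) {
    stop("'patients' must be sorted by arrival_week", call. = FALSE)
  }
  n <- nrow(patients)
  is_referral <- patients$source == "referral"

  screened <- rep(FALSE, n)
  if (config$screening_enabled) {
    screened <- is_referral &
      patients$group %in% config$screening$screened_groups
  }
  confusion <- rep(NA_character_, n)
  patients$screen_flagged <- rep(NA, n)
  if (any(screened)) {
    u <- with_seed(config$rng_seed, stats::runif(sum(screened)))
    res <- screen_patient(patients$true_abnormal[screened],
                          config$screening, u)
    patients$screen_flagged[screened] <- res$flagged
    confusion[screened] <- res$confusion_class
  }

  enters_queue <- !screened | (patients$screen_flagged %in% TRUE)
  entrants <- which(enters_queue)
  serve_week <- service_schedule(patients$arrival_week[entrants],
                                 config$capacity_per_week,
                                 config$horizon_weeks)
  patients$edt_week[entrants] <- serve_week
  patients$wait_weeks[entrants] <- serve_week -
    patients$arrival_week[entrants] +
    ifelse(patients$source[entrants] == "backlog",
           config$backlog_accrued_weeks, 0)

  windows <- do.call(rbind, lapply(config$report_windows, function(w) {
    m <- measure_window(patients, w)
    data.frame(start = w[1], end = w[2],
               mean_wait_weeks = m$mean_wait_weeks, n_served = m$n_served)
  }))

  totals <- c(
    n_referred      = sum(is_referral),
    n_screened      = sum(screened),
    n_screened_out  = sum(screened & !(patients$screen_flagged %in% TRUE)),
    n_edt_required  = length(entrants),
    n_edt_performed = sum(!is.na(serve_week)),
    FN = sum(confusion %in% "FN"), FP = sum(confusion %in% "FP"),
    TP = sum(confusion %in% "TP"), TN = sum(confusion %in% "TN"),
    end_queue_length = sum(is.na(serve_week))
  )

  structure(list(windows = windows, totals = totals, patients = patients),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat("Pathway replication:",
      x$totals[["n_referred"]], "referred,",
      x$totals[["n_edt_performed"]], "of",
      x$totals[["n_edt_required"]], "lab EDTs performed\n")
  print(x$windows, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Windowed waiting-time statistic
#'
#' Mean recorded wait of the patients whose laboratory EDT service week
#' falls inside `(start, end]` (the serving-time convention: a window owns
#' the waits of the patients it serves).
#'
#' @param records Patient data frame with `edt_week`/`wait_weeks` stamped.
#' @param window `c(start, end)` in weeks.
#' @return List with `mean_wait_weeks` (0 when empty), `n_served`, and
#'   logical `empty`.
#' @export
measure_window <- function(records, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  inside <- !is.na(records$edt_week) &
    records$edt_week > window[1] & records$edt_week <= window[2]
  n <- sum(inside)
  list(
    mean_wait_weeks = if (n) mean(records$wait_weeks[inside]) else 0,
    n_served = n,
    empty = n == 0L
  )
}
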