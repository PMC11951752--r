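# Five-experiment scenario driver: configuration grids, the two-phase
# (5-year, then 6-year with 5-year warm-up) replication protocol, seed
# scheduling, and across-replication summaries.

#' Deterministic seed schedule
#'
#' Derives the seed for one random-number stream of one replication of one
#' scenario cell from the base seed, by iterating
#' `x <- (x * 69069 + k) mod (2^31 - 1)` over `k` in
#' `(base, cell, rep, stream)`. The multiplier keeps every intermediate
#' product exactly representable in doubles, so the schedule is stable
#' across platforms, and each cell/replication/stream is independently
#' reproducible.
#'
#' @param base_seed,cell,rep,stream Non-negative integers.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(base_seed, cell = 0L, rep = 0L, stream = 0L) {
  m <- 2147483647 # 2^31 - 1
  x <- as.numeric(base_seed) %% m
  for (k in c(cell, rep, stream)) {
    x <- (x * 69069 + as.numeric(k)) %% m
  }
  as.integer(x) + 1L
}

# stream ids within a replication: arrivals/backlog/screening, per phase
.stream <- function(phase, what) {
  10L * phase + switch(what, arrivals = 1L, backlog = 2L, screening = 3L)
}

#' Two-phase replication protocol for one scenario cell
#'
#' Each scenario is evaluated by two sets of runs: phase 1 simulates 5 years
#' (260 weeks) from time zero with the current backlog and reports the mean
#' wait of patients served in years 1-5; phase 2 simulates 6 years
#' (312 weeks) from the same starting conditions and reports only year 6
#' (weeks 260-312), i.e. a 5-year warm-up, to see whether the waiting time
#' has stabilised. Phase 2 regenerates its own arrival streams for the full
#' horizon; it is an independent run, not a continuation of phase 1.
#'
#' @param config A [scenario_config()]; its `horizon_weeks` gives the
#'   phase-1 horizon (phase 2 adds 52 weeks).
#' @param n_reps Number of replications per phase (2000 for headline runs).
#' @param base_seed Base seed for the [derive_seed()] schedule.
#' @param cell_index Integer identifying this cell in the seed schedule.
#' @param group_params Referral-group parameters.
#' @param crn Use common random numbers: share arrival/backlog streams
#'   across cells (cell index 0 for those streams) so that paired scenario
#'   differences have reduced variance. Screening keeps its own stream.
#' @param keep_replications Also return the per-replication table.
#' @return A one-row data frame of class `scenario_summary` with
#'   across-replication means, standard errors and 95 percent confidence
#'   limits of the years-1-5 and year-6 mean waits, and means of the 5-year
#'   pathway counts. With `keep_replications = TRUE`, the per-replication
#'   rows are attached as attribute `"replications"`.
#' @export
two_phase_run <- function(config, n_reps = 2000L, base_seed = 1L,
                          cell_index = 1L,
                          group_params = default_group_params(),
                          crn = FALSE,
                          keep_replications = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1)
  t1 <- config$horizon_weeks
  t2 <- t1 + 52
  arr_cell <- if (crn) 0L else cell_index

  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    row <- list(replication = i)
    for (phase in 1:2) {
      horizon <- if (phase == 1L) t1 else t2
      window  <- if (phase == 1L) c(0, t1) else c(t1, t2)
      cohort <- assemble_cohort(
        generate_backlog(config$backlog, group_params,
                         derive_seed(base_seed, arr_cell, i,
                                     .stream(phase, "backlog"))),
        generate_referrals(group_params, horizon, config$demand_scale,
                           derive_seed(base_seed, arr_cell, i,
                                       .stream(phase, "arrivals")))
      )
      cfg <- config
      cfg$horizon_weeks <- horizon
      cfg$report_windows <- list(window)
      cfg$rng_seed <- derive_seed(base_seed, cell_index, i,
                                  .stream(phase, "screening"))
      res <- run_replication(cohort, cfg)
      if (phase == 1L) {
        row$wait_y15 <- res$windows$mean_wait_weeks[1]
        row <- c(row, as.list(res$totals))
      } else {
        row$wait_y6 <- res$windows$mean_wait_weeks[1]
        row$n_served_y6 <- res$windows$n_served[1]
      }
    }
    reps[[i]] <- as.data.frame(row)
  }
  reps <- do.call(rbind, reps)

  msd <- function(x) {
    se <- if (n_reps > 1) stats::sd(x) / sqrt(n_reps) else NA_real_
    c(mean = mean(x), se = se,
      lo = mean(x) - stats::qnorm(0.975) * se,
      hi = mean(x) + stats::qnorm(0.975) * se)
  }
  w15 <- msd(reps$wait_y15)
  w6  <- msd(reps$wait_y6)
  out <- data.frame(
    label = if (is.null(config$label)) NA_character_ else config$label,
    n_replications = n_reps,
    wait_y15_mean = w15[["mean"]], wait_y15_se = w15[["se"]],
    wait_y15_lo = w15[["lo"]], wait_y15_hi = w15[["hi"]],
    wait_y6_mean = w6[["mean"]], wait_y6_se = w6[["se"]],
    wait_y6_lo = w6[["lo"]], wait_y6_hi = w6[["hi"]],
    referred_mean = mean(reps$n_referred),
    screened_mean = mean(reps$n_screened),
    screened_out_mean = mean(reps$n_screened_out),
    edt_required_mean = mean(reps$n_edt_required),
    edt_performed_mean = mean(reps$n_edt_performed),
    fn_mean = mean(reps$FN), fp_mean = mean(reps$FP),
    tp_mean = mean(reps$TP), tn_mean = mean(reps$TN),
    end_queue_mean = mean(reps$end_queue_length),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scenario_summary", "data.frame")
  if (keep_replications) attr(out, "replications") <- reps
  out
}

#' Build one of the five experiment grids
#'
#' * Experiment 1: status quo vs screening at Se = Sp = 0.95.
#' * Experiment 2: sensitivity/specificity grid — symmetric
#'   Se = Sp in \{0.25, 0.50, 0.80, 0.95\} plus the asymmetric
#'   (0.90, 0.95) and (0.95, 0.90) cells.
#' * Experiment 3: weekly lab capacity 10, 12, 14 with screening on.
#' * Experiment 4: demand scale 1.00-1.25 in steps of 0.05 with screening
#'   on.
#' * Experiment 5: screening restricted to a single group A, B or C.
#'
#' Non-varied fields sit at the service defaults (capacity 12/week, backlog
#' 228, Se = Sp = 0.95, scale 1).
#'
#' @param experiment_id Integer 1-5.
#' @param n_replications Default replication count recorded on the grid.
#' @return An object of class `experiment_grid`: list with `experiment_id`,
#'   named list `cells` of [scenario_config()]s, and `n_replications`.
#' @export
build_experiment <- function(experiment_id, n_replications = 2000L) {
  if (!experiment_id %in% 1:5) {
    stop("'experiment_id' must be one of 1, 2, 3, 4, 5", call. = FALSE)
  }
  cell <- function(label, ...) scenario_config(..., label = label)
  scr <- function(se = 0.95, sp = 0.95, groups = c("A", "B", "C")) {
    screening_params(se, sp, groups)
  }
  cells <- switch(as.character(experiment_id),
    "1" = list(
      status_quo = cell("status_quo", screening_enabled = FALSE),
      screening  = cell("screening", screening_enabled = TRUE)
    ),
    "2" = {
      pts <- list(c(0.95, 0.95), c(0.90, 0.95), c(0.95, 0.90),
                  c(0.80, 0.80), c(0.50, 0.50), c(0.25, 0.25))
      out <- lapply(pts, function(p) {
        cell(sprintf("se%02d_sp%02d", round(100 * p[1]), round(100 * p[2])),
             screening_enabled = TRUE, screening = scr(p[1], p[2]))
      })
      names(out) <- vapply(out, function(cfg) cfg$label, character(1))
      out
    },
    "3" = {
      out <- lapply(c(10L, 12L, 14L), function(cap) {
        cell(sprintf("capacity_%d", cap), screening_enabled = TRUE,
             capacity_per_week = cap)
      })
      names(out) <- vapply(out, function(cfg) cfg$label, character(1))
      out
    },
    "4" = {
      out <- lapply(seq(1, 1.25, by = 0.05), function(s) {
        cell(sprintf("demand_%03d", round(100 * s)),
             screening_enabled = TRUE, demand_scale = s)
      })
      names(out) <- vapply(out, function(cfg) cfg$label, character(1))
      out
    },
    "5" = {
      out <- lapply(c("A", "B", "C"), function(g) {
        cell(paste0("screen_", g, "_only"), screening_enabled = TRUE,
             screening = scr(groups = g))
      })
      names(out) <- vapply(out, function(cfg) cfg$label, character(1))
      out
    }
  )
  structure(list(experiment_id = experiment_id, cells = cells,
                 n_replications = as.integer(n_replications)),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("Experiment %d: %d cells x %d replications\n",
              x$experiment_id, length(x$cells), x$n_replications))
  cat("  cells:", paste(names(x$cells), collapse = ", "), "\n")
  invisible(x)
}

#' Run experiment grids and write summary tables
#'
#' Runs every cell of every grid through [two_phase_run()], writes
#' `summary_<id>.csv` (one row per cell, full precision),
#' `replications_<id>.csv` (one row per replication), a rendered
#' `table_<id>.txt`, a run manifest and a log file under `out_dir`.
#' Deterministic given `base_seed`.
#'
#' @param grids A single `experiment_grid` or list of them.
#' @param base_seed Base seed for the seed schedule.
#' @param n_reps Replications per cell; defaults to each grid's
#'   `n_replications`.
#' @param out_dir Output directory (created if needed); `NULL` writes no
#'   files.
#' @param group_params Referral-group parameters.
#' @return Named list of summary data frames, one per experiment,
#'   invisibly when files are written.
#' @export
run_all <- function(grids, base_seed = 1L, n_reps = NULL, out_dir = NULL,
                    group_params = default_group_params()) {
  if (inherits(grids, "experiment_grid")) grids <- list(grids)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  results <- list()
  outputs <- character(0)
  for (grid in grids) {
    id <- grid$experiment_id
    reps <- if (is.null(n_reps)) grid$n_replications else n_reps
    say("experiment %d: %d cells, %d replications, base seed %d",
        id, length(grid$cells), reps, base_seed)
    rows <- list()
    rep_rows <- list()
    for (j in seq_along(grid$cells)) {
      cfg <- grid$cells[[j]]
      t0 <- proc.time()[["elapsed"]]
      s <- tryCatch(
        two_phase_run(cfg, reps, base_seed,
                      cell_index = 100L * id + j,
                      group_params = group_params,
                      keep_replications = TRUE),
        error = function(e) {
          say("  cell %s FAILED: %s", cfg$label, conditionMessage(e))
          NULL
        }
      )
      if (is.null(s)) next
      say("  cell %s: wait y1-5 = %.1f wk, y6 = %.1f wk (%.1fs)",
          cfg$label, s$wait_y15_mean, s$wait_y6_mean,
          proc.time()[["elapsed"]] - t0)
      rows[[length(rows) + 1L]] <- s
      rr <- attr(s, "replications")
      rr <- cbind(cell = cfg$label, rr)
      rep_rows[[length(rep_rows) + 1L]] <- rr
    }
    summary_df <- do.call(rbind, lapply(rows, function(r) {
      attr(r, "replications") <- NULL
      r
    }))
    results[[paste0("experiment_", id)]] <- summary_df
    if (!is.null(out_dir)) {
      fs <- file.path(out_dir, sprintf("summary_%d.csv", id))
      fr <- file.path(out_dir, sprintf("replications_%d.csv", id))
      ft <- file.path(out_dir, sprintf("table_%d.txt", id))
      utils::write.csv(summary_df, fs, row.names = FALSE)
      utils::write.csv(do.call(rbind, rep_rows), fr, row.names = FALSE)
      writeLines(render_table3(summary_df), ft)
      outputs <- c(outputs, fs, fr, ft)
    }
  }
  if (!is.null(out_dir)) {
    manifest <- run_manifest(grids, base_seed, n_reps, outputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(results))
  }
  results
}
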