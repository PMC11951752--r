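# Configuration loading/validation, run manifests, and rendering of the
# results table (waits, lab-test demand, screening error counts and
# percentages of all referred patients).

CONFIG_KEYS <- c("screening_enabled", "sensitivity", "specificity",
                 "screened_groups", "capacity_per_week", "backlog",
                 "demand_scale", "horizon_weeks", "rng_seed",
                 "backlog_accrued_weeks", "label")

#' Load a scenario configuration from YAML or JSON
#'
#' Reads a flat key-value file, validates it, and fills unspecified fields
#' with the service defaults (no screening, Se = Sp = 0.95, capacity
#' 12/week, backlog 228, demand scale 1, 260-week horizon). An empty file
#' yields the all-defaults status-quo configuration. Unknown keys and
#' out-of-range values are rejected with the offending field named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  config_from_list(vals)
}

#' Build a scenario configuration from a named list
#'
#' The programmatic core of [load_config()]; also used to reload the config
#' echoed into a run manifest.
#'
#' @param vals Named list of configuration fields.
#' @return A [scenario_config()] object.
#' @export
config_from_list <- function(vals) {
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  unknown <- setdiff(names(vals), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get_or <- function(key, default) {
    if (is.null(vals[[key]])) default else vals[[key]]
  }
  for (key in c("sensitivity", "specificity")) {
    v <- vals[[key]]
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1)) {
      stop("config field '", key, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  scenario_config(
    screening_enabled = get_or("screening_enabled", FALSE),
    screening = screening_params(
      sensitivity = get_or("sensitivity", 0.95),
      specificity = get_or("specificity", 0.95),
      screened_groups = get_or("screened_groups", c("A", "B", "C"))
    ),
    capacity_per_week = get_or("capacity_per_week", 12L),
    backlog = get_or("backlog", 228L),
    demand_scale = get_or("demand_scale", 1),
    horizon_weeks = get_or("horizon_weeks", 260),
    report_windows = list(c(0, get_or("horizon_weeks", 260))),
    rng_seed = get_or("rng_seed", 1L),
    backlog_accrued_weeks = get_or("backlog_accrued_weeks", 0),
    label = get_or("label", NULL)
  )
}

#' Echo a scenario configuration as a named list
#'
#' Inverse of [config_from_list()], used for manifests;
#' `config_from_list(config_to_list(x))` reproduces `x`.
#'
#' @param config A [scenario_config()] object.
#' @return Named list of configuration fields.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(
    screening_enabled = config$screening_enabled,
    sensitivity = config$screening$sensitivity,
    specificity = config$screening$specificity,
    screened_groups = config$screening$screened_groups,
    capacity_per_week = config$capacity_per_week,
    backlog = config$backlog,
    demand_scale = config$demand_scale,
    horizon_weeks = config$horizon_weeks,
    rng_seed = config$rng_seed,
    backlog_accrued_weeks = config$backlog_accrued_weeks
  )
  if (!is.null(config$label)) out$label <- config$label
  out
}

#' Assemble a run manifest
#'
#' Records everything needed to reproduce a [run_all()] invocation: package
#' version, base seed, timestamp, the full configuration of every cell, and
#' the output files written.
#'
#' @param grids List of `experiment_grid`s.
#' @param base_seed Base seed used.
#' @param n_reps Replication override (`NULL` for grid defaults).
#' @param outputs Character vector of files written.
#' @return Named list (serialise with `jsonlite::write_json`).
#' @export
run_manifest <- function(grids, base_seed, n_reps = NULL,
                         outputs = character(0)) {
  list(
    package = "edtsim",
    version = as.character(utils::packageVersion("edtsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = base_seed,
    n_reps = n_reps,
    experiments = lapply(grids, function(g) {
      list(experiment_id = g$experiment_id,
           n_replications = g$n_replications,
           cells = lapply(g$cells, config_to_list))
    }),
    outputs = as.list(outputs)
  )
}

#' Render scenario summaries as a results table
#'
#' Formats one line per scenario with the years-1-5 and year-6 mean waits
#' (rounded to integer weeks), the 5-year laboratory EDT demand, the number
#' screened, and false-negative/false-positive counts with percentages.
#' Percentages use the total number of patients referred for laboratory
#' electrophysiology over the horizon — including group D, who cannot be
#' screened but form part of the laboratory burden — as denominator.
#' Screening-error cells are blank (not zero) for scenarios without a
#' screening step. CSVs written elsewhere keep full precision; rounding
#' happens only here.
#'
#' @param summaries A `scenario_summary` data frame (one or more rows).
#' @return Character vector of table lines.
#' @export
render_table3 <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  fmt_count <- function(x) formatC(round(x), format = "d", big.mark = "")
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    screened <- s$screened_mean > 0
    pct <- function(x) sprintf("%.1f%%", 100 * x / s$referred_mean)
    label <- if (is.na(s$label)) "(unnamed)" else as.character(s$label)
    c(scenario = label,
      wait_y1_5 = fmt_count(s$wait_y15_mean),
      wait_y6 = fmt_count(s$wait_y6_mean),
      edt_5y = fmt_count(s$edt_required_mean),
      screened = if (screened) fmt_count(s$screened_mean) else "",
      fn = if (screened) {
        sprintf("%s (%s)", fmt_count(s$fn_mean), pct(s$fn_mean))
      } else "",
      fp = if (screened) {
        sprintf("%s (%s)", fmt_count(s$fp_mean), pct(s$fp_mean))
      } else "")
  })
  header <- c(scenario = "scenario", wait_y1_5 = "wait y1-5 (wk)",
              wait_y6 = "wait y6 (wk)", edt_5y = "lab EDTs (5y)",
              screened = "screened", fn = "false neg", fp = "false pos")
  tab <- rbind(header, do.call(rbind, rows))
  widths <- apply(nchar(tab), 2, max)
  apply(tab, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
}
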