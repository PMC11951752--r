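# Synthetic referral-cohort generator: Poisson arrival streams per group,
# latent gold-standard ERG status, initial waiting-list backlog, CSV I/O.

PATIENT_COLUMNS <- c("id", "source", "arrival_week", "group",
                     "true_abnormal", "screen_flagged",
                     "edt_week", "wait_weeks")

new_patient_frame <- function(n) {
  data.frame(
    id             = integer(n),
    source         = character(n),
    arrival_week   = numeric(n),
    group          = character(n),
    true_abnormal  = rep(NA, n),
    screen_flagged = rep(NA, n),
    edt_week       = rep(NA_real_, n),
    wait_weeks     = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

#' Generate a stochastic referral stream
#'
#' Draws independent homogeneous Poisson arrival streams per referral group
#' over `[0, horizon_weeks)`, at each group's weekly rate multiplied by
#' `demand_scale`. Each group A-C patient receives a latent true ERG status
#' drawn Bernoulli with that group's abnormality probability; group D patients
#' (VEP referrals) carry no ERG status. Records are returned sorted by arrival
#' time with sequential ids.
#'
#' @param params A `group_params` data frame, see [default_group_params()].
#' @param horizon_weeks Positive length of the generation window, in weeks.
#' @param demand_scale Positive multiplier applied to every group's rate
#'   (1 reproduces the audited demand; 1.25 models a 25 percent increase).
#' @param rng_seed Integer seed; the stream is reproducible given the seed.
#' @return A patient data frame with columns `id`, `source`, `arrival_week`,
#'   `group`, `true_abnormal`, `screen_flagged`, `edt_week`, `wait_weeks`
#'   (the last three `NA` until the patient passes through the pathway).
#' @examples
#' pats <- generate_referrals(default_group_params(), 52, rng_seed = 1)
#' table(pats$group)
#' @export
generate_referrals <- function(params = default_group_params(),
                               horizon_weeks,
                               demand_scale = 1,
                               rng_seed = 1L) {
  stopifnot(inherits(params, "group_params"))
  if (!is.numeric(horizon_weeks) || length(horizon_weeks) != 1L ||
      !is.finite(horizon_weeks) || horizon_weeks <= 0) {
    stop("'horizon_weeks' must be a single positive number of weeks",
         call. = FALSE)
  }
  if (!is.numeric(demand_scale) || length(demand_scale) != 1L ||
      !is.finite(demand_scale) || demand_scale <= 0) {
    stop("'demand_scale' must be a single positive number", call. = FALSE)
  }
  with_seed(rng_seed, {
    per_group <- lapply(seq_len(nrow(params)), function(i) {
      rate <- params$weekly_rate[i] * demand_scale
      n <- stats::rpois(1L, rate * horizon_weeks)
      arr <- stats::runif(n, 0, horizon_weeks)
      abn <- if (params$screenable[i]) {
        stats::runif(n) < params$p_abnormal[i]
      } else {
        rep(NA, n)
      }
      list(group = rep(params$group[i], n), arrival = arr, abnormal = abn)
    })
    arrival  <- unlist(lapply(per_group, `[[`, "arrival"))
    group    <- unlist(lapply(per_group, `[[`, "group"))
    abnormal <- unlist(lapply(per_group, `[[`, "abnormal"))
    ord <- order(arrival)
    out <- new_patient_frame(length(arrival))
    out$id            <- seq_along(arrival)
    out$source        <- rep("referral", length(arrival))
    out$arrival_week  <- arrival[ord]
    out$group         <- group[ord]
    out$true_abnormal <- abnormal[ord]
    out
  })
}

#' Generate the initial waiting-list backlog
#'
#' Creates `n` patients already waiting for a laboratory EDT at time zero.
#' Backlog patients enter the EDT queue directly (they are never screened);
#' their group labels, drawn from the referral mix, and latent ERG statuses
#' are bookkeeping only.
#'
#' @param n Non-negative number of backlog patients (228 in the audited
#'   service).
#' @inheritParams generate_referrals
#' @return A patient data frame with `source = "backlog"` and
#'   `arrival_week = 0`.
#' @export
generate_backlog <- function(n = 228L,
                             params = default_group_params(),
                             rng_seed = 1L) {
  stopifnot(inherits(params, "group_params"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      n != round(n)) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(rng_seed, {
    grp <- sample(params$group, n, replace = TRUE,
                  prob = params$weekly_rate)
    p <- params$p_abnormal[match(grp, params$group)]
    abn <- ifelse(is.na(p), NA, stats::runif(n) < p)
    out <- new_patient_frame(n)
    out$id            <- seq_len(n)
    out$source        <- rep("backlog", n)
    out$group         <- grp
    out$true_abnormal <- abn
    out
  })
}

#' Combine backlog and referral records into one cohort
#'
#' Re-numbers ids so the combined cohort has unique ids, backlog first, and
#' is sorted by arrival time (backlog patients all arrive at week 0, ahead of
#' every referral).
#'
#' @param backlog,referrals Patient data frames.
#' @return A single patient data frame sorted by `arrival_week` then id.
#' @export
assemble_cohort <- function(backlog, referrals) {
  referrals$id <- referrals$id + if (nrow(backlog)) max(backlog$id) else 0L
  out <- rbind(backlog, referrals)
  out <- out[order(out$arrival_week, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write patient records as CSV
#'
#' A fixed-header CSV (`id, source, arrival_week, group, true_abnormal,
#' screen_flagged, edt_week, wait_weeks`), one row per patient. Numeric
#' fields are written at full precision so that
#' `read_patients(write_patients(x, f))` reproduces `x` field for field.
#'
#' @param records A patient data frame.
#' @param path File path.
#' @return `write_patients` returns `path` invisibly; `read_patients` returns
#'   a patient data frame.
#' @export
write_patients <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(PATIENT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("patient records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- records[PATIENT_COLUMNS]
  for (col in c("arrival_week", "edt_week", "wait_weeks")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(raw), PATIENT_COLUMNS)) {
    stop("'", path, "' does not have the expected patient CSV header",
         call. = FALSE)
  }
  out <- new_patient_frame(nrow(raw))
  bad <- which(is.na(suppressWarnings(as.integer(raw$id))) |
                 !raw$group %in% c("A", "B", "C", "D") |
                 !raw$source %in% c("backlog", "referral"))
  if (length(bad)) {
    stop("malformed patient rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  out$id           <- as.integer(raw$id)
  out$source       <- raw$source
  out$arrival_week <- as.numeric(raw$arrival_week)
  out$group        <- raw$group
  out$true_abnormal  <- as_logical_or_na(raw$true_abnormal)
  out$screen_flagged <- as_logical_or_na(raw$screen_flagged)
  out$edt_week     <- suppressWarnings(as.numeric(raw$edt_week))
  out$wait_weeks   <- suppressWarnings(as.numeric(raw$wait_weeks))
  out
}

as_logical_or_na <- function(x) {
  ifelse(x == "", NA, x == "TRUE")
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'rng_seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
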