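# Hand-held ERG screening step: Bernoulli test outcome given latent truth,
# confusion-class accounting, and closed-form expected error counts.

#' Screening-test parameters
#'
#' The hand-held ERG screen is modelled as a binary test applied at the point
#' of referral: a truly abnormal patient is flagged (sent on to the laboratory
#' EDT queue) with probability `sensitivity`; a truly normal patient is
#' cleared (screened out of the pathway) with probability `specificity`.
#' Group D (VEP) referrals are never screenable.
#'
#' @param sensitivity,specificity Probabilities in \[0, 1\]; default 0.95 for
#'   both, the working threshold adopted for the device.
#' @param screened_groups Subset of `c("A", "B", "C")`: the referral groups
#'   the screen is applied to.
#' @return An object of class `screening_params`.
#' @export
screening_params <- function(sensitivity = 0.95, specificity = 0.95,
                             screened_groups = c("A", "B", "C")) {
  for (p in c(sensitivity, specificity)) {
    if (!is.numeric(p) || length(sensitivity) != 1L ||
        length(specificity) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("sensitivity and specificity must be single probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  screened_groups <- unique(as.character(screened_groups))
  if (length(screened_groups) && !all(screened_groups %in% c("A", "B", "C"))) {
    stop("'screened_groups' must be a subset of A, B, C ",
         "(group D cannot be screened with a hand-held ERG)", call. = FALSE)
  }
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         screened_groups = screened_groups),
    class = "screening_params"
  )
}

#' @export
print.screening_params <- function(x, ...) {
  cat(sprintf("ERG screen: Se = %.2f, Sp = %.2f, groups {%s}\n",
              x$sensitivity, x$specificity,
              paste(x$screened_groups, collapse = ", ")))
  invisible(x)
}

#' Apply the screening test to one or more patients
#'
#' Vectorised over patients. A truly abnormal patient is flagged when its
#' uniform draw is below `sensitivity`; a truly normal patient is flagged
#' when its draw is at or above `specificity` (i.e. cleared with probability
#' `specificity`). Flagged patients proceed to the laboratory EDT queue;
#' unflagged patients leave the pathway.
#'
#' @param true_abnormal Logical vector of latent gold-standard ERG statuses.
#' @param params A [screening_params()] object.
#' @param rand_draw Uniform(0, 1) draws, one per patient (supplied rather
#'   than drawn internally so screening can use its own random-number stream
#'   and support common random numbers across sensitivity/specificity cells).
#' @return A data frame with logical `flagged` and `confusion_class` in
#'   `{"TP", "FP", "TN", "FN"}`.
#' @examples
#' screen_patient(c(TRUE, FALSE), screening_params(1, 1), c(0.5, 0.5))
#' @export
screen_patient <- function(true_abnormal, params, rand_draw) {
  stopifnot(inherits(params, "screening_params"))
  if (length(rand_draw) != length(true_abnormal)) {
    stop("'rand_draw' must supply one uniform draw per patient", call. = FALSE)
  }
  if (any(rand_draw < 0 | rand_draw >= 1)) {
    stop("'rand_draw' values must lie in [0, 1)", call. = FALSE)
  }
  if (any(is.na(true_abnormal))) {
    stop("screened patients must carry a true ERG status", call. = FALSE)
  }
  flagged <- ifelse(true_abnormal,
                    rand_draw < params$sensitivity,
                    rand_draw >= params$specificity)
  confusion <- ifelse(true_abnormal,
                      ifelse(flagged, "TP", "FN"),
                      ifelse(flagged, "FP", "TN"))
  data.frame(flagged = flagged, confusion_class = confusion,
             stringsAsFactors = FALSE)
}

#' Closed-form expected screening counts
#'
#' Deterministic expectations for a horizon of `T` weeks with group rates
#' \eqn{\lambda_g} and abnormality probabilities \eqn{p_g}:
#' \deqn{screened = T \sum_g \lambda_g, \quad
#'       FN = T \sum_g \lambda_g p_g (1 - Se), \quad
#'       FP = T \sum_g \lambda_g (1 - p_g)(1 - Sp),}
#' with sums over the screened groups, and
#' \eqn{flagged = T \sum_g \lambda_g (p_g Se + (1 - p_g)(1 - Sp))}.
#' These serve as the analytic oracle for the simulated counts.
#'
#' @param params A [screening_params()] object.
#' @param group_params A `group_params` data frame.
#' @param horizon_weeks Horizon `T` in weeks.
#' @param demand_scale Multiplier on all rates.
#' @return Named list: `screened`, `flagged`, `screened_out`, `FN`, `FP`.
#' @examples
#' expected_screen_counts(screening_params(), default_group_params(), 260)
#' @export
expected_screen_counts <- function(params, group_params, horizon_weeks,
                                   demand_scale = 1) {
  stopifnot(inherits(params, "screening_params"),
            inherits(group_params, "group_params"))
  g <- group_params[group_params$group %in% params$screened_groups, ]
  lam <- g$weekly_rate * demand_scale
  p   <- g$p_abnormal
  se  <- params$sensitivity
  sp  <- params$specificity
  screened <- horizon_weeks * sum(lam)
  fn       <- horizon_weeks * sum(lam * p * (1 - se))
  fp       <- horizon_weeks * sum(lam * (1 - p) * (1 - sp))
  flagged  <- horizon_weeks * sum(lam * (p * se + (1 - p) * (1 - sp)))
  list(screened = screened, flagged = flagged,
       screened_out = screened - flagged, FN = fn, FP = fp)
}
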