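#' Referral-group parameters for the EDT pathway
#'
#' The pathway model distinguishes four referral groups. Groups A-C are
#' referred primarily for an electroretinogram (ERG) and can in principle be
#' screened at the point of referral with a hand-held device; group D patients
#' are referred primarily for visual evoked potentials (VEP) and cannot be
#' screened, but still consume laboratory EDT appointment slots.
#'
#' `default_group_params()` returns the rates and abnormality probabilities
#' reconstructed from a 3-month retrospective referral audit (a 13-week
#' quarter): 77, 14, 40 and 64 referrals in groups A-D respectively, of which
#' 23, 4 and 5 of the A-C patients had an abnormal gold-standard ERG. Group D
#' patients carry no ERG-status variable in the model.
#'
#' @param weekly_rate Numeric vector of 4 non-negative arrival rates
#'   (patients/week) for groups A, B, C, D.
#' @param p_abnormal Numeric vector of 3 probabilities in \[0, 1\] that the
#'   gold-standard ERG is abnormal, for groups A, B, C.
#' @return A data frame of class `group_params` with columns `group`,
#'   `weekly_rate`, `p_abnormal` (`NA` for group D) and `screenable`.
#' @examples
#' gp <- default_group_params()
#' sum(gp$weekly_rate)      # 15 patients/week
#' 52 * sum(gp$weekly_rate) # 780 expected referrals/year
#' @export
default_group_params <- function() {
  group_params(
    weekly_rate = c(77, 14, 40, 64) / 13,
    p_abnormal  = c(23 / 77, 4 / 14, 5 / 40)
  )
}

#' @rdname default_group_params
#' @export
group_params <- function(weekly_rate, p_abnormal) {
  if (length(weekly_rate) != 4L || any(!is.finite(weekly_rate)) ||
      any(weekly_rate < 0)) {
    stop("'weekly_rate' must be 4 non-negative finite rates (groups A-D)",
         call. = FALSE)
  }
  if (length(p_abnormal) != 3L || any(!is.finite(p_abnormal)) ||
      any(p_abnormal < 0) || any(p_abnormal > 1)) {
    stop("'p_abnormal' must be 3 probabilities in [0, 1] (groups A-C)",
         call. = FALSE)
  }
  out <- data.frame(
    group       = c("A", "B", "C", "D"),
    weekly_rate = as.numeric(weekly_rate),
    p_abnormal  = c(as.numeric(p_abnormal), NA_real_),
    screenable  = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_params", "data.frame")
  out
}

#' @export
print.group_params <- function(x, ...) {
  cat("Referral-group parameters (",
      format(sum(x$weekly_rate), digits = 4), " patients/week total)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
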