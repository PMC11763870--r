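#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] exposing the curve as a plain
#' table. At tied times events precede censorings, the survfit convention.
#'
#' @param records data.frame with columns `time` (months, positive) and
#'   `event` (1 = death, 0 = censored).
#' @return A `km_curve` list: `times` (ordered, one entry per distinct
#'   observed time), `survival`, `at_risk`, `n_events`, `n`.
#' @export
#' @examples
#' km_estimate(data.frame(time = 1:3, event = 1))$survival  # 2/3 1/3 0
km_estimate <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, censored = TRUE)
  if (any(diff(s$surv) > 1e-12)) stop("internal error: non-monotone KM")
  structure(list(times = s$time, survival = s$surv, at_risk = s$n.risk,
                 n_events = s$n.event, n = nrow(records)),
            class = "km_curve")
}

#' Survival probability at given times from a KM curve
#'
#' Step-function evaluation: `S(t)` is 1 before the first observed time.
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- which(curve$times <= ti)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Backed by [survival::survdiff()] (1 degree of freedom). With zero events
#' overall the statistic is undefined and both entries are `NA`.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns.
#' @return List: `chi_square`, `p_value`, `n` (per-group sizes),
#'   `events` (per-group observed events).
#' @export
log_rank <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1, nrow(group_b) >= 1)
  dat <- rbind(
    data.frame(time = group_a$time, event = group_a$event, g = "A"),
    data.frame(time = group_b$time, event = group_b$event, g = "B")
  )
  if (sum(dat$event) == 0) {
    return(list(chi_square = NA_real_, p_value = NA_real_,
                n = c(A = nrow(group_a), B = nrow(group_b)),
                events = c(A = 0, B = 0)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  list(chi_square = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = c(A = nrow(group_a), B = nrow(group_b)),
       events = c(A = unname(sd$obs[1]), B = unname(sd$obs[2])))
}

#' Compare survival between two molecular strata
#'
#' Stratifies the cohort with [stratify()], joins the survival table, and
#' returns both KM curves plus the log-rank test. Patients missing from the
#' survival table are dropped from the comparison and reported, so the
#' molecular group counts and the survival-analysis counts can legitimately
#' differ.
#'
#' @param profiles List of `patient_profile`.
#' @param survival_table data.frame with `patient_id`, `time`, `event`.
#' @param scheme Stratification scheme, see [stratify()].
#' @return A `strata_comparison` list: `strata`, per-group `km` curves and
#'   sizes, `test` (log-rank or `NULL` when a group is empty),
#'   `underpowered` flag (any group of size 1), `missing_survival` ids.
#' @export
compare_strata <- function(profiles, survival_table,
                           scheme = c("BAP1", "CHR1", "CHR3", "CHR8")) {
  scheme <- match.arg(scheme)
  st <- stratify(profiles, scheme)
  take <- function(ids) {
    survival_table[survival_table$patient_id %in% ids, , drop = FALSE]
  }
  surv_a <- take(st$group_a)
  surv_b <- take(st$group_b)
  missing <- setdiff(c(st$group_a, st$group_b), survival_table$patient_id)
  res <- list(
    strata = st,
    n = stats::setNames(c(nrow(surv_a), nrow(surv_b)),
                        c(st$label_a, st$label_b)),
    km_a = if (nrow(surv_a)) km_estimate(surv_a),
    km_b = if (nrow(surv_b)) km_estimate(surv_b),
    test = NULL, underpowered = FALSE, missing_survival = missing
  )
  if (nrow(surv_a) && nrow(surv_b)) {
    res$test <- log_rank(surv_a, surv_b)
    res$underpowered <- min(nrow(surv_a), nrow(surv_b)) < 2
  }
  structure(res, class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: n = %d vs %d\n", x$strata$label_a, x$strata$label_b,
              x$n[1], x$n[2]))
  if (!is.null(x$test)) {
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g%s\n",
                x$test$chi_square, x$test$p_value,
                if (x$underpowered) " [under-powered]" else ""))
  } else {
    cat("log-rank not computed (empty group)\n")
  }
  invisible(x)
}
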