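# Time-dependent prognostic performance: Harrell's C, IPCW cumulative/dynamic
# AUC, Graf IPCW Brier score, and the multi-model comparison report.

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Fits the censoring survival function G(t) by reversing the event
#' indicator. Returns an evaluator with right-continuous value `G(t)` and
#' left limit `G(t-)` (events at tied times are processed before
#' censorings, so G's risk sets retain the subjects whose event occurs at
#' the censoring time).
#'
#' @param times Follow-up times.
#' @param status 1 event / 0 censored.
#' @return List of functions `G(t)` and `G_minus(t)`.
#' @export
censoring_km <- function(times, status) {
  fit <- survival::survfit(survival::Surv(times, 1 - status) ~ 1)
  tt <- fit$time[fit$n.event > 0]
  ss <- fit$surv[fit$n.event > 0]
  G <- if (length(tt)) stats::stepfun(tt, c(1, ss)) else function(t) rep(1, length(t))
  G_minus <- function(t) {
    if (!length(tt)) return(rep(1, length(t)))
    vapply(t, function(u) {
      before <- ss[tt < u]
      if (length(before)) before[length(before)] else 1
    }, numeric(1))
  }
  list(G = function(t) G(t), G_minus = G_minus)
}

#' Harrell's concordance index
#'
#' Fraction of censoring-usable pairs (the earlier time is an observed
#' event, strictly earlier than the other subject's time) in which the
#' higher risk score belongs to the earlier event; risk ties score 0.5.
#'
#' @param times Follow-up times.
#' @param status 1 event / 0 censored.
#' @param risk Risk scores (higher = worse prognosis).
#' @return Concordance in \[0,1\].
#' @export
harrell_c <- function(times, status, risk) {
  stopifnot(length(times) == length(status), length(times) == length(risk))
  ev <- which(status == 1)
  num <- 0; den <- 0
  for (i in ev) {
    usable <- times > times[i]
    den <- den + sum(usable)
    num <- num + sum(risk[i] > risk[usable]) + 0.5 * sum(risk[i] == risk[usable])
  }
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  num / den
}

#' IPCW Brier score at a horizon
#'
#' Graf-style inverse-probability-of-censoring-weighted mean squared error
#' between the event indicator at the horizon and the predicted event
#' probability. Subjects with an observed event at or before the horizon are
#' weighted by `1/G(T-)`; subjects still at risk past the horizon by
#' `1/G(horizon)`; subjects censored before the horizon contribute 0.
#'
#' @param times,status Follow-up times and event indicators.
#' @param pred Predicted event probabilities by the horizon, in \[0,1\].
#' @param horizon Evaluation time (> 0).
#' @return The Brier score BS(horizon).
#' @export
ipcw_brier <- function(times, status, pred, horizon) {
  stopifnot(horizon > 0, all(pred >= 0 & pred <= 1))
  cw <- censoring_km(times, status)
  event_by_t <- times <= horizon & status == 1
  at_risk <- times > horizon
  w <- numeric(length(times))
  if (any(event_by_t)) {
    g <- cw$G_minus(times[event_by_t])
    if (any(g <= 0))
      stop("censoring survival is 0 before the horizon; use a smaller horizon",
           call. = FALSE)
    w[event_by_t] <- 1 / g
  }
  if (any(at_risk)) {
    gt <- cw$G(horizon)
    if (gt <= 0)
      stop("censoring survival is 0 at the horizon; use a smaller horizon",
           call. = FALSE)
    w[at_risk] <- 1 / gt
  }
  mean(w * (as.numeric(event_by_t) - pred)^2)
}

#' IPCW cumulative/dynamic AUC at a horizon
#'
#' Probability that a case (event by the horizon) carries a higher risk
#' score than a control (event-free past the horizon), with IPCW weights
#' `1/G(T-)` for cases and `1/G(horizon)` for controls; risk ties count 0.5.
#'
#' @param times,status Follow-up times and event indicators.
#' @param risk Risk scores.
#' @param horizon Evaluation time.
#' @return AUC(horizon) in \[0,1\].
#' @export
ipcw_auc <- function(times, status, risk, horizon) {
  cases <- which(times <= horizon & status == 1)
  controls <- which(times > horizon)
  if (!length(cases) || !length(controls))
    stop("need at least one case and one control at the horizon", call. = FALSE)
  cw <- censoring_km(times, status)
  wi <- 1 / cw$G_minus(times[cases])
  wj <- rep(1 / cw$G(horizon), length(controls))
  if (any(!is.finite(wi)) || any(!is.finite(wj)))
    stop("censoring survival is 0 at a needed point; use a smaller horizon",
         call. = FALSE)
  num <- 0
  for (k in seq_along(cases)) {
    conc <- sum(wj * (risk[cases[k]] > risk[controls])) +
      0.5 * sum(wj * (risk[cases[k]] == risk[controls]))
    num <- num + wi[k] * conc
  }
  num / (sum(wi) * sum(wj))
}

#' Per-group Kaplan-Meier event probabilities
#'
#' For a categorical risk model, the predicted event probability by each
#' horizon is `1 - S_g(t)` from the group-specific Kaplan-Meier curve.
#'
#' @param group Factor of group membership.
#' @param times,status Follow-up and event indicator used to fit the curves.
#' @param horizons Numeric vector of horizons.
#' @return Matrix (patients x horizons) of event probabilities.
#' @export
km_group_predictions <- function(group, times, status, horizons) {
  group <- as.factor(group)
  out <- base::matrix(NA_real_, length(group), length(horizons),
                      dimnames = list(NULL, as.character(horizons)))
  for (g in levels(group)) {
    idx <- group == g
    if (!any(idx)) next
    km <- kaplan_meier(times[idx], status[idx])
    S <- stats::stepfun(km$time, c(1, km$surv))
    out[idx, ] <- rep(1 - S(horizons), each = sum(idx))
  }
  out
}

#' Multi-model, multi-horizon performance report
#'
#' Evaluates each model on each endpoint: overall Harrell's C plus IPCW
#' AUC and Brier score at every horizon. `endpoints` is a named list of
#' `list(times, status)`; `models` is a named list of
#' `list(risk = <numeric>, pred = <named list of patient-by-horizon
#' matrices, one per endpoint>)`. The best value per endpoint / horizon /
#' metric is flagged (highest C and AUC, lowest Brier). A metric that cannot
#' be evaluated is reported as `NA` with the reason.
#'
#' @param models Named list of model specifications (see Details).
#' @param endpoints Named list of endpoint data.
#' @param horizons Numeric vector of evaluation times (default 6, 10, 14
#'   years).
#' @return Data frame: model, endpoint, horizon, cindex, auc, brier,
#'   best_auc, best_brier, best_cindex, note.
#' @export
performance_report <- function(models, endpoints, horizons = c(6, 10, 14)) {
  rows <- list()
  for (en in names(endpoints)) {
    ep <- endpoints[[en]]
    for (mn in names(models)) {
      m <- models[[mn]]
      note <- ""
      cidx <- tryCatch(harrell_c(ep$times, ep$status, m$risk),
                       error = function(e) { note <<- conditionMessage(e); NA_real_ })
      for (h in horizons) {
        pred <- m$pred[[en]][, as.character(h)]
        auc <- tryCatch(ipcw_auc(ep$times, ep$status, m$risk, h),
                        error = function(e) NA_real_)
        bs <- tryCatch(ipcw_brier(ep$times, ep$status, pred, h),
                       error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, endpoint = en, horizon = h,
          cindex = cidx, auc = auc, brier = bs, note = note,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$best_cindex <- FALSE; out$best_auc <- FALSE; out$best_brier <- FALSE
  for (en in unique(out$endpoint)) for (h in unique(out$horizon)) {
    sel <- out$endpoint == en & out$horizon == h
    if (any(sel & !is.na(out$auc)))
      out$best_auc[sel][which.max(out$auc[sel])] <- TRUE
    if (any(sel & !is.na(out$brier)))
      out$best_brier[sel][which.min(out$brier[sel])] <- TRUE
    if (any(sel & !is.na(out$cindex)))
      out$best_cindex[sel][which.max(out$cindex[sel])] <- TRUE
  }
  out
}

#' Endpoint data from a clinical table
#'
#' Builds the `(times, status)` pairs used by the performance metrics:
#' overall survival (time to death, censored otherwise) and hematologic
#' transformation (cause-specific: death without transformation censors).
#'
#' @param clinical Validated clinical data frame.
#' @return Named list with `overall_survival` and `transformation`, each
#'   `list(times, status)`.
#' @export
endpoint_data <- function(clinical) {
  died <- clinical$event_death == 1L
  os_time <- ifelse(died, clinical$time_death, clinical$time_censor)
  transformed <- clinical$event_transformation == 1L
  tfs_time <- ifelse(transformed, clinical$time_transformation,
                     ifelse(died, clinical$time_death, clinical$time_censor))
  list(
    overall_survival = list(times = os_time, status = as.integer(died)),
    transformation = list(times = tfs_time, status = as.integer(transformed)))
}
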