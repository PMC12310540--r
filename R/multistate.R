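# Illness-death multistate machinery: long-format construction, Kaplan-Meier,
# transition-specific Cox models, Aalen-Johansen occupation probabilities,
# stepwise covariate selection.

transition_levels <- c("1->2", "1->3", "2->3")

#' Build the long-format multistate dataset
#'
#' Expands each clinical record into transition rows of the illness-death
#' model (states: 1 chronic, 2 hematologic transformation, 3 death). Every
#' patient contributes a `1->2` and a `1->3` row from time 0 to the end of
#' the chronic phase (transformation, death, or censoring — whichever comes
#' first), with cause-specific status; transformed patients additionally
#' contribute a `2->3` row entered (left-truncated) at the transformation
#' time. Intervals are half-open (entry, exit]; the clock is time since
#' diagnosis for all transitions.
#'
#' @param clinical Validated clinical data frame (see [read_cohort()]).
#' @param covariates Columns to carry onto the transition rows (default: all
#'   besides the outcome columns).
#' @return Data frame: patient_id, transition, entry, exit, status, plus
#'   covariate columns.
#' @export
to_multistate <- function(clinical, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(clinical),
                          c("patient_id", "time_transformation",
                            "event_transformation", "transformation_subtype",
                            "time_death", "event_death", "time_censor"))
  transformed <- clinical$event_transformation == 1L
  died <- clinical$event_death == 1L
  chronic_exit <- ifelse(transformed, clinical$time_transformation,
                         ifelse(died, clinical$time_death,
                                clinical$time_censor))
  if (any(chronic_exit <= 0))
    stop("non-positive chronic-phase exit time for patient(s): ",
         paste(utils::head(clinical$patient_id[chronic_exit <= 0], 5),
               collapse = ", "), call. = FALSE)

  chronic <- data.frame(
    patient_id = rep(clinical$patient_id, each = 2),
    transition = rep(c("1->2", "1->3"), nrow(clinical)),
    entry = 0,
    exit = rep(chronic_exit, each = 2),
    status = as.integer(as.vector(rbind(transformed, !transformed & died))),
    stringsAsFactors = FALSE)
  chronic <- cbind(chronic,
                   clinical[rep(seq_len(nrow(clinical)), each = 2),
                            covariates, drop = FALSE])

  exit2 <- ifelse(died, clinical$time_death, clinical$time_censor)
  bad <- transformed & died & exit2 <= chronic_exit
  if (any(bad))
    stop("death not after transformation for patient(s): ",
         paste(utils::head(clinical$patient_id[bad], 5), collapse = ", "),
         call. = FALSE)
  # censored exactly at transformation => no post-transformation follow-up
  post_idx <- which(transformed & exit2 > chronic_exit)
  if (length(post_idx)) {
    post <- data.frame(
      patient_id = clinical$patient_id[post_idx],
      transition = "2->3",
      entry = chronic_exit[post_idx],
      exit = exit2[post_idx],
      status = as.integer(died[post_idx]),
      stringsAsFactors = FALSE)
    post <- cbind(post, clinical[post_idx, covariates, drop = FALSE])
    ms <- rbind(chronic, post)
  } else ms <- chronic
  rownames(ms) <- NULL
  stopifnot(all(ms$entry < ms$exit))
  ms
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; at tied times all events are processed before
#' censorings.
#'
#' @param times Follow-up times (>= 0).
#' @param status 1 event / 0 censored.
#' @return Data frame: time, n_risk, n_event, n_censor, surv.
#' @export
kaplan_meier <- function(times, status) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Fit a transition-specific Cox proportional-hazards model
#'
#' Maximises the Breslow-ties partial likelihood over the rows of one
#' transition, respecting left truncation through the entry times. The
#' baseline cumulative hazard uses the Breslow estimator; confidence
#' intervals are Wald. Efron tie handling is available behind `ties`.
#'
#' @param msdata Multistate dataset from [to_multistate()].
#' @param transition One of `"1->2"`, `"1->3"`, `"2->3"`.
#' @param covariates Character vector of covariate columns; `NULL` fits the
#'   null model (baseline hazard only, i.e. the Nelson-Aalen estimator).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Wald confidence level.
#' @return Object of class `transition_model`: coefficients, standard
#'   errors, hazard ratios with CI, Wald p-values, baseline cumulative
#'   hazard (step function values), log-likelihood, counts.
#' @export
fit_cox_transition <- function(msdata, transition, covariates = NULL,
                               ties = "breslow", conf_level = 0.95) {
  stopifnot(transition %in% transition_levels)
  d <- msdata[msdata$transition == transition, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for transition ", transition, call. = FALSE)
  if (sum(d$status) < 1)
    stop("no events on transition ", transition, call. = FALSE)

  if (length(covariates)) {
    for (v in covariates) {
      x <- d[[v]]
      if (is.null(x)) stop("unknown covariate: ", v, call. = FALSE)
      if (length(unique(x[!is.na(x)])) < 2)
        stop("covariate constant within transition ", transition, ": ", v,
             call. = FALSE)
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(entry, exit, status) ~",
      paste(covariates, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = d, ties = ties,
                      control = survival::coxph.control(iter.max = 50)),
      warning = function(w) {
        # monotone-likelihood warning is converted to an error below
        if (grepl("beta may be infinite", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
      worst <- names(beta)[which.max(abs(beta))]
      stop("monotone partial likelihood (perfect separation) for covariate ",
           worst, " on transition ", transition, call. = FALSE)
    }
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    coef_table <- data.frame(
      term = names(beta), coef = unname(beta), se = unname(se),
      hr = exp(unname(beta)),
      hr_lower = exp(unname(beta) - z * unname(se)),
      hr_upper = exp(unname(beta) + z * unname(se)),
      p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
      row.names = NULL)
    bh <- survival::basehaz(fit, centered = FALSE)
  } else {
    fit <- survival::coxph(survival::Surv(entry, exit, status) ~ 1, data = d,
                           ties = ties)
    coef_table <- data.frame(term = character(0), coef = numeric(0),
                             se = numeric(0), hr = numeric(0),
                             hr_lower = numeric(0), hr_upper = numeric(0),
                             p_value = numeric(0))
    bh <- survival::basehaz(fit, centered = FALSE)
  }
  structure(list(transition = transition, coef = coef_table,
                 baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
                 loglik = as.numeric(utils::tail(fit$loglik, 1)),
                 n = nrow(d), n_event = sum(d$status),
                 ties = ties, fit = fit),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model [", x$transition, "]: ", x$n_event, " events / ",
      x$n, " rows\n", sep = "")
  if (nrow(x$coef)) print(x$coef, digits = 3)
  invisible(x)
}

#' Predicted event probability from a transition Cox model
#'
#' Cause-specific cumulative-incidence style prediction
#' `1 - exp(-Lambda0(t) * exp(lp))` at given horizons for new covariate
#' rows.
#'
#' @param model A `transition_model`.
#' @param newdata Data frame with the model's covariate columns.
#' @param horizons Numeric vector of times.
#' @return Matrix (rows = patients, cols = horizons) of event probabilities.
#' @export
predict_event_prob <- function(model, newdata, horizons) {
  lp <- if (nrow(model$coef)) {
    X <- as.matrix(newdata[, model$coef$term, drop = FALSE])
    as.numeric(X %*% model$coef$coef)
  } else rep(0, nrow(newdata))
  H0 <- stats::stepfun(model$baseline_cumhaz$time,
                       c(0, model$baseline_cumhaz$hazard))
  out <- sapply(horizons, function(t) 1 - exp(-H0(t) * exp(lp)))
  base::matrix(out, nrow = nrow(newdata),
               dimnames = list(NULL, as.character(horizons)))
}

#' Aalen-Johansen state-occupation probabilities
#'
#' Product-integral estimator of the occupation probabilities of the three
#' illness-death states (chronic, transformed, dead) over time, from the
#' long-format transition data.
#'
#' @param msdata Multistate dataset from [to_multistate()].
#' @return Data frame: time, p_chronic, p_transformed, p_dead.
#' @export
aalen_johansen <- function(msdata) {
  # rebuild per-subject intervals with a single endpoint factor
  chronic <- msdata[msdata$transition %in% c("1->2", "1->3"), , drop = FALSE]
  post <- msdata[msdata$transition == "2->3", , drop = FALSE]
  ids <- unique(chronic$patient_id)
  ev12 <- chronic$patient_id[chronic$transition == "1->2" & chronic$status == 1]
  ev13 <- chronic$patient_id[chronic$transition == "1->3" & chronic$status == 1]
  first <- chronic[chronic$transition == "1->2", , drop = FALSE]
  first <- first[match(ids, first$patient_id), , drop = FALSE]
  iv <- data.frame(
    id = ids, t0 = first$entry, t1 = first$exit,
    ev = ifelse(ids %in% ev12, "transformed",
                ifelse(ids %in% ev13, "dead", "censor")),
    istate = "chronic", stringsAsFactors = FALSE)
  if (nrow(post)) {
    iv <- rbind(iv, data.frame(
      id = post$patient_id, t0 = post$entry, t1 = post$exit,
      ev = ifelse(post$status == 1, "dead", "censor"),
      istate = "transformed", stringsAsFactors = FALSE))
  }
  iv$ev <- factor(iv$ev, levels = c("censor", "transformed", "dead"))

  if (all(iv$ev == "censor")) {
    tmax <- max(iv$t1)
    return(data.frame(time = c(0, tmax), p_chronic = c(1, 1),
                      p_transformed = c(0, 0), p_dead = c(0, 0)))
  }
  fit <- survival::survfit(survival::Surv(t0, t1, ev) ~ 1, data = iv,
                           id = iv$id, istate = iv$istate)
  ps <- base::matrix(0, length(fit$time), 3,
                     dimnames = list(NULL, c("chronic", "transformed", "dead")))
  present <- intersect(fit$states, colnames(ps))
  ps[, present] <- fit$pstate[, match(present, fit$states)]
  out <- data.frame(time = fit$time, p_chronic = ps[, "chronic"],
                    p_transformed = ps[, "transformed"],
                    p_dead = ps[, "dead"])
  rbind(data.frame(time = 0, p_chronic = 1, p_transformed = 0, p_dead = 0),
        out)
}

#' Stepwise backward covariate selection for a transition model
#'
#' Iteratively drops the covariate with the largest Wald p-value above
#' `alpha` and refits, until every remaining covariate has p <= alpha (or
#' none remain). Ties are broken by covariate name (lexicographically first
#' dropped).
#'
#' @param msdata Multistate dataset.
#' @param transition Transition label.
#' @param covariates Starting covariate set.
#' @param alpha Wald p-value threshold to stay in the model.
#' @param ties Tie handling for the Cox fits.
#' @return List: `selected` covariates, final `model` (`NULL` if all were
#'   dropped), and `dropped` (data frame of term and p at removal).
#' @export
stepwise_select <- function(msdata, transition, covariates, alpha = 0.05,
                            ties = "breslow") {
  current <- sort(covariates)
  dropped <- data.frame(term = character(0), p_value = numeric(0))
  model <- NULL
  while (length(current)) {
    model <- fit_cox_transition(msdata, transition, current, ties = ties)
    p <- stats::setNames(model$coef$p_value, model$coef$term)
    p[is.na(p)] <- Inf   # non-identifiable term: remove first
    if (all(p <= alpha)) return(list(selected = current, model = model,
                                     dropped = dropped))
    over <- p[p > alpha]
    # largest p first; ties (to 10 decimals) by lexicographic term name
    worst <- names(over)[order(-round(over, 10), names(over))][1]
    dropped <- rbind(dropped,
                     data.frame(term = worst, p_value = unname(over[worst])))
    current <- setdiff(current, worst)
    model <- NULL
  }
  list(selected = character(0), model = model, dropped = dropped)
}
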