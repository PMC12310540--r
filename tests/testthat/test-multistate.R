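# Illness-death machinery: long format, Kaplan-Meier, transition Cox fits,
# Aalen-Johansen, stepwise selection.

base_clinical <- function(n) {
  data.frame(patient_id = sprintf("P%d", seq_len(n)),
             age_dx = 66, sex = "male",
             prior_arterial_thrombosis = 0L, prior_venous_thrombosis = 0L,
             constitutional_symptoms = 0L, pruritus = 0L,
             leukocytes = 10, platelets = 400,
             neutrophil_lymphocyte_ratio = 4,
             driver = "V617F", driver_vaf = 40,
             time_transformation = NA_real_, event_transformation = 0L,
             time_death = NA_real_, event_death = 0L, time_censor = 10,
             stringsAsFactors = FALSE)
}

test_that("transition rows are constructed per the illness-death layout", {
  cl <- base_clinical(3)
  # P1 transformed at 5, died at 7; P2 censored at 10; P3 died at 4
  cl$event_transformation[1] <- 1L; cl$time_transformation[1] <- 5
  cl$event_death[1] <- 1L; cl$time_death[1] <- 7
  cl$event_death[3] <- 1L; cl$time_death[3] <- 4
  ms <- to_multistate(cl)

  p1 <- ms[ms$patient_id == "P1", ]
  expect_equal(p1$transition, c("1->2", "1->3", "2->3"))
  expect_equal(p1$exit, c(5, 5, 7))
  expect_equal(p1$entry, c(0, 0, 5))
  expect_equal(p1$status, c(1L, 0L, 1L))

  p2 <- ms[ms$patient_id == "P2", ]
  expect_equal(p2$exit, c(10, 10))
  expect_equal(p2$status, c(0L, 0L))

  p3 <- ms[ms$patient_id == "P3", ]
  expect_equal(p3$transition, c("1->2", "1->3"))
  expect_equal(p3$status, c(0L, 1L))
})

test_that("death not after transformation is fatal", {
  cl <- base_clinical(1)
  cl$event_transformation <- 1L; cl$time_transformation <- 5
  cl$event_death <- 1L; cl$time_death <- 5
  expect_error(to_multistate(cl), "not after transformation")
})

test_that("Kaplan-Meier matches the hand-computed product-limit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # all censored -> S identically 1
  km2 <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  # mixed 5-subject fixture, manual risk-set arithmetic
  t5 <- c(1, 2, 2, 3, 5); s5 <- c(1, 0, 1, 1, 0)
  km3 <- kaplan_meier(t5, s5)
  hand <- oracle_km(t5, s5)
  expect_equal(km3$surv[km3$n_event > 0], hand$surv)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Cox fits equal the brute-force partial-likelihood maximiser", {
  fixtures <- list(
    list(exit = c(1, 2, 3, 4, 5, 6), status = c(1, 1, 1, 0, 1, 1),
         x = c(1, 1, 0, 1, 0, 0)),
    list(exit = c(2, 2, 3, 5, 7, 8), status = c(1, 1, 0, 1, 1, 0),
         x = c(0, 1, 1, 0, 1, 0)),                     # tied event times
    list(exit = c(1, 3, 4, 6, 7, 9, 10, 12),
         status = c(1, 0, 1, 1, 0, 1, 1, 0),
         x = c(1, 0, 1, 0, 1, 0, 1, 0)))
  for (f in fixtures) {
    ms <- make_msdata(f$exit, f$status, f$x)
    fit <- fit_cox_transition(ms, "1->3", "x")
    brute <- oracle_cox_beta(rep(0, length(f$exit)), f$exit, f$status, f$x)
    expect_equal(fit$coef$coef, brute, tolerance = 1e-4)
  }

  # left truncation changes the risk sets; oracle agrees
  entry <- c(0, 0, 2, 2, 4, 0)
  exit <- c(3, 5, 6, 7, 9, 4)
  status <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  ms <- make_msdata(exit, status, x, entry = entry)
  fit <- fit_cox_transition(ms, "1->3", "x")
  expect_equal(fit$coef$coef, oracle_cox_beta(entry, exit, status, x),
               tolerance = 1e-4)
})

test_that("degenerate Cox inputs raise errors", {
  ms <- make_msdata(1:6, c(1, 1, 0, 1, 0, 1), rep(1, 6))
  expect_error(fit_cox_transition(ms, "1->3", "x"), "constant")
  ms2 <- make_msdata(1:6, rep(0, 6), c(0, 1, 0, 1, 0, 1))
  expect_error(fit_cox_transition(ms2, "1->3", "x"), "no events")
  # perfect separation is reported with the covariate name
  ms3 <- make_msdata(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
                     c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox_transition(ms3, "1->3", "x"), "x")
})

test_that("the Cox estimate recovers a known log hazard ratio", {
  set.seed(31)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, 0.1 * exp(0.7 * x))
  cens <- runif(n, 0, 15)
  exit <- pmin(t_event, cens)
  status <- as.integer(t_event <= cens)
  fit <- fit_cox_transition(make_msdata(exit, status, x), "1->3", "x")
  expect_lt(abs(fit$coef$coef - 0.7), 3 * fit$coef$se)
})

test_that("the null-model baseline is the Nelson-Aalen estimator", {
  exit <- c(1, 2, 2, 4, 6, 7); status <- c(1, 0, 1, 1, 1, 0)
  ms <- make_msdata(exit, status, rep(0, 6))
  fit <- fit_cox_transition(ms, "1->3", covariates = NULL)
  # hand Nelson-Aalen: sum d/n over event times
  ts <- sort(unique(exit[status == 1]))
  na_hand <- cumsum(vapply(ts, function(u)
    sum(exit == u & status == 1) / sum(exit >= u), numeric(1)))
  got <- fit$baseline_cumhaz
  expect_equal(got$hazard[match(ts, got$time)], na_hand, tolerance = 1e-12)
  expect_true(all(diff(got$hazard) >= 0))
})

test_that("Aalen-Johansen reduces to known forms", {
  # no events: chronic occupation identically 1
  cl <- base_clinical(4)
  aj0 <- aalen_johansen(to_multistate(cl))
  expect_true(all(aj0$p_chronic == 1))

  # only chronic->death events: chronic curve equals Kaplan-Meier
  cl <- base_clinical(8)
  cl$event_death <- c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  cl$time_death <- c(1, 2, NA, 4, NA, 6, NA, 8)
  cl$time_censor <- c(9, 9, 3, 9, 5, 9, 7, 9)
  ms <- to_multistate(cl)
  aj <- aalen_johansen(ms)
  os_time <- ifelse(cl$event_death == 1, cl$time_death, cl$time_censor)
  km <- oracle_km(os_time, cl$event_death)
  expect_equal(aj$p_chronic[match(km$time, aj$time)], km$surv,
               tolerance = 1e-12)

  # occupation probabilities always sum to one, death non-decreasing
  co <- simulate_cohort(default_sim_config(n = 250, seed = 14))
  aj2 <- aalen_johansen(to_multistate(co$clinical))
  expect_true(all(abs(rowSums(aj2[, c("p_chronic", "p_transformed",
                                      "p_dead")]) - 1) < 1e-10))
  expect_true(all(diff(aj2$p_dead) >= -1e-12))
})

test_that("constant-hazard occupation matches the closed form", {
  n <- 10000
  covs <- data.frame(dummy = rep(0, n))
  hz <- list(baseline = c(`1->2` = 0.1, `1->3` = 0.1, `2->3` = 0.2),
             shape = c(`1->2` = 1, `1->3` = 1, `2->3` = 1),
             beta = list(`1->2` = NULL, `1->3` = NULL, `2->3` = NULL))
  out <- simulate_event_histories(covs, hz,
                                  list(admin_horizon = 30, rate = 0), seed = 88)
  cl <- cbind(base_clinical(n)[, 1:12], out)
  aj <- aalen_johansen(to_multistate(cl))
  S <- stats::stepfun(aj$time, c(1, aj$p_chronic))
  for (t0 in c(2, 5))
    expect_lt(abs(S(t0) - exp(-0.2 * t0)), 0.02)
})

test_that("stepwise selection drops noise and keeps real effects", {
  dropped_noise <- 0
  for (rep in 1:20) {
    set.seed(400 + rep)
    n <- 500
    x <- rbinom(n, 1, 0.4)
    noise <- rnorm(n)
    t_event <- rexp(n, 0.08 * exp(0.9 * x))
    cens <- runif(n, 0, 18)
    ms <- make_msdata(pmin(t_event, cens), as.integer(t_event <= cens), x)
    ms$noise <- noise
    sel <- stepwise_select(ms, "1->3", c("x", "noise"))
    if (!"noise" %in% sel$selected) dropped_noise <- dropped_noise + 1
    expect_true("x" %in% sel$selected)
  }
  expect_gte(dropped_noise, 17)  # ~95% per replicate under the null
})

test_that("stepwise keeps everything when all effects are real", {
  set.seed(77)
  n <- 800
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  t_event <- rexp(n, 0.08 * exp(0.8 * x1 + 0.5 * x2))
  cens <- runif(n, 0, 18)
  ms <- make_msdata(pmin(t_event, cens), as.integer(t_event <= cens), x1)
  ms$x2 <- x2
  sel <- stepwise_select(ms, "1->3", c("x", "x2"))
  expect_setequal(sel$selected, c("x", "x2"))
  expect_equal(nrow(sel$dropped), 0)
})

test_that("tied removal candidates drop the lexicographically first term", {
  # data symmetric under swapping the two covariates -> identical Wald p
  exit <- c(1, 1, 2, 3, 4, 4)
  status <- c(1, 1, 1, 0, 1, 1)
  a <- c(1, 0, 1, 0, 1, 0)
  b <- c(0, 1, 1, 0, 0, 1)
  ms <- make_msdata(exit, status, a)
  ms$b <- b
  names(ms)[names(ms) == "x"] <- "a"
  fit <- fit_cox_transition(ms, "1->3", c("a", "b"))
  expect_equal(fit$coef$p_value[1], fit$coef$p_value[2], tolerance = 1e-6)
  sel <- stepwise_select(ms, "1->3", c("a", "b"), alpha = 0.001)
  expect_equal(sel$dropped$term[1], "a")
})
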