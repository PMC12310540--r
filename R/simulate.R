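# Synthetic clinical-genomic cohort generator for the PV illness-death
# pipeline: mutation presence from a DAG of Bernoulli conditionals, per-gene
# VAF mixtures, CNV calls, clinical covariates, and event histories from
# cause-specific hazards with censoring.

#' Default simulation configuration
#'
#' The defaults emulate the statistical structure of the source cohort.
#' Values read from the published cohort description are marked `[PUBLISHED]`
#' in the source; the rest are documented modelling choices (`[ASSUMED]`,
#' see the package vignette).
#'
#' @param n Number of patients.
#' @param seed Integer seed (mandatory at simulation time).
#' @return A `sim_config` list with components `genes` (DAG of Bernoulli
#'   conditionals + VAF mixtures), `extra_variant_prob`, `cnv`, `clinical`,
#'   `hazards`, `censoring`.
#' @export
default_sim_config <- function(n = 439, seed = 1L) {
  # gene nodes in topological order; prob is indexed by the binary parent
  # configuration (c(p0, p1) for one parent)
  genes <- list(
    TET2   = list(parents = character(0), prob = 0.26,
                  w_low = 0.5),                       # bimodal VAF
    DNMT3A = list(parents = character(0), prob = 0.16,
                  w_low = 0.85),                      # low-VAF gene
    ASXL1  = list(parents = "TET2", prob = c(0.08, 0.21),
                  w_low = 0.5),                       # bimodal; co-occurs with TET2
    EZH2   = list(parents = "ASXL1", prob = c(0.011, 0.13), w_low = 0.4),
    SRSF2  = list(parents = "ASXL1", prob = c(0.02, 0.16),
                  w_low = 0.15),                      # high-VAF gene
    IDH2   = list(parents = "SRSF2", prob = c(0.016, 0.20), w_low = 0.15),
    IDH1   = list(parents = "SRSF2", prob = c(0.011, 0.11), w_low = 0.2),
    NFE2   = list(parents = character(0), prob = 0.033, w_low = 0.85),
    BCOR   = list(parents = "DNMT3A", prob = c(0.013, 0.08), w_low = 0.6),
    CBL    = list(parents = character(0), prob = 0.026, w_low = 0.5),
    TP53   = list(parents = character(0), prob = 0.026, w_low = 0.7),
    PPM1D  = list(parents = character(0), prob = 0.02, w_low = 0.8),
    SF3B1  = list(parents = character(0), prob = 0.013, w_low = 0.4),
    U2AF1  = list(parents = character(0), prob = 0.007, w_low = 0.4))

  # fraction of a gene's variants that are truncating (nonsense/frameshift)
  truncating_frac <- c(TET2 = 0.7, ASXL1 = 0.85, NFE2 = 0.85, PPM1D = 0.8,
                       BCOR = 0.7, EZH2 = 0.6, DNMT3A = 0.15, CBL = 0.05,
                       SRSF2 = 0.02, IDH1 = 0.02, IDH2 = 0.02, SF3B1 = 0.05,
                       TP53 = 0.25, U2AF1 = 0.05)

  list(
    n = n, seed = seed, genes = genes, truncating_frac = truncating_frac,
    # chance of a second variant in the same gene given one: TET2 is the
    # gene with frequent multiple hits (28/439 patients = 6.4% of cohort)
    extra_variant_prob = c(TET2 = 0.30, .default = 0.05),
    # extra non-retained rows per patient to exercise the filters
    noise = list(vus_rate = 0.3, common_poly_rate = 0.1, low_vaf_rate = 0.1),
    cnv = list(                       # per-region Bernoulli prevalences
      `9p_UPD` = 0.45,                # [PUBLISHED] 181/399
      `9p_gain` = 0.018, `20q_loss` = 0.007, `7_loss` = 0.005,
      `1q_gain` = 0.005, `13q_loss` = 0.002, `8_gain` = 0.002),
    clinical = list(
      age_median = 66, age_sd = 15.5, age_range = c(18, 95),  # [PUBLISHED] 66 (IQR 55-76)
      male_frac = 0.59,                                       # [PUBLISHED]
      leuko_meanlog = log(10.8), leuko_sdlog = 0.35,  # ~48% >= 11 G/L [PUBLISHED]
      plt_meanlog = log(450), plt_sdlog = 0.30,
      nlr_meanlog = log(4.0), nlr_sdlog = 0.50,
      prior_venous = 94 / 439, prior_arterial = 84 / 439,     # [PUBLISHED] counts
      constitutional = 0.25, pruritus = 0.30,                 # [ASSUMED]
      v617f_frac = 0.98, driver_vaf_mean = 37.6, driver_vaf_sd = 22),
    hazards = list(
      baseline = c(`1->2` = 0.0042, `1->3` = 0.014, `2->3` = 0.30),
      shape = c(`1->2` = 1, `1->3` = 1, `2->3` = 1),  # 1 = exponential
      # log hazard ratios; group effects from the final multistate model
      beta = list(
        `1->2` = c(group_high = log(5.42), group_intermediate = log(3.51),
                   age_c = log(1.07)),                        # [PUBLISHED]
        `1->3` = c(group_high = log(1.92), age_c = log(1.09)),# [PUBLISHED]
        `2->3` = c(age_c = log(1.03))),                       # [ASSUMED]
      age_center = 66),
    censoring = list(admin_horizon = 20, rate = 0.05))
}

rbeta_scaled <- function(n, lo, hi, a, b) lo + (hi - lo) * stats::rbeta(n, a, b)

# VAF mixture: low-clone component on [2, 20]%, high-clone around 40%.
sample_vaf <- function(n, w_low) {
  low <- stats::runif(n) < w_low
  vaf <- numeric(n)
  vaf[low] <- rbeta_scaled(sum(low), 2, 20, 1.5, 2.5)
  vaf[!low] <- rbeta_scaled(sum(!low), 20, 95, 2.5, 4.5)
  round(vaf, 1)
}

sample_gene_presence <- function(cfg, n) {
  genes <- names(cfg$genes)
  pres <- base::matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (g in genes) {
    node <- cfg$genes[[g]]
    if (!length(node$parents)) {
      p <- rep(node$prob, n)
    } else {
      pm <- pres[, node$parents, drop = FALSE]
      idx <- as.integer(pm %*% 2^(seq_along(node$parents) - 1)) + 1L
      p <- node$prob[idx]
    }
    pres[, g] <- as.integer(stats::runif(n) < p)
  }
  pres
}

#' Simulate event histories under the illness-death model
#'
#' Draws competing chronic-phase exit times (transformation vs death) by
#' inversion of each cause-specific cumulative hazard (Weibull baseline,
#' shape 1 = exponential, times covariate effects), then — if transformation
#' comes first — a post-transformation death time from the `2->3` hazard on
#' the same diagnosis clock (left-truncated at the transformation time).
#' Administrative plus independent exponential censoring is applied last.
#'
#' @param covariates Data frame with the columns named in the hazard `beta`
#'   vectors (e.g. `group_high`, `group_intermediate`, `age_c`).
#' @param hazards List with `baseline`, `shape`, `beta` per transition (see
#'   [default_sim_config()]).
#' @param censoring List with `admin_horizon` and exponential `rate`.
#' @param seed Optional integer seed.
#' @return Data frame: time_transformation, event_transformation,
#'   time_death, event_death, time_censor.
#' @export
simulate_event_histories <- function(covariates, hazards, censoring,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  lp <- function(tr) {
    b <- hazards$beta[[tr]]
    if (!length(b)) return(rep(0, n))
    X <- as.matrix(covariates[, names(b), drop = FALSE])
    as.numeric(X %*% b)
  }
  draw_time <- function(tr, entry = rep(0, n)) {
    lam <- hazards$baseline[[tr]] * exp(lp(tr))
    s <- hazards$shape[[tr]]
    e <- stats::rexp(n)
    out <- rep(Inf, n)
    pos <- lam > 0
    out[pos] <- (e[pos] / lam[pos] + entry[pos]^s)^(1 / s)
    out
  }
  t12 <- draw_time("1->2")
  t13 <- draw_time("1->3")
  cens <- pmin(censoring$admin_horizon,
               if (censoring$rate > 0) stats::rexp(n, censoring$rate) else Inf)

  chronic_exit <- pmin(t12, t13)
  transformed <- t12 < t13 & t12 < cens
  t23 <- draw_time("2->3", entry = t12)

  death_time <- ifelse(transformed, t23, t13)
  died <- is.finite(death_time) & death_time < cens &
    (transformed | t13 < t12)

  data.frame(
    time_transformation = ifelse(transformed, round(t12, 6), NA_real_),
    event_transformation = as.integer(transformed),
    time_death = ifelse(died, round(death_time, 6), NA_real_),
    event_death = as.integer(died),
    time_censor = round(cens, 6))
}

#' Simulate a full clinical-genomic cohort
#'
#' Generates variant, CNV and clinical tables that round-trip through
#' [read_cohort()] unchanged. Mutation presence is sampled ancestrally from
#' the configured DAG; VAFs from per-gene low/high-clone mixtures; CNVs as
#' per-region Bernoulli draws; clinical covariates from the configured
#' distributions. The patient's genomic group (from the same classification
#' rules as [classify_pv_hmr()]) and centred age drive the transition
#' hazards via [simulate_event_histories()]. Random-number streams are split
#' per component (mutations / CNV / clinical / outcomes) so toggling one
#' block does not shift the others.
#'
#' @param config A `sim_config` (see [default_sim_config()]).
#' @return List with `variants`, `cnv`, `clinical` data frames and the
#'   `group` assignment used for outcome generation.
#' @export
simulate_cohort <- function(config = default_sim_config()) {
  n <- config$n
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  ids <- sprintf("P%04d", seq_len(n))
  sub_seed <- function(k) (config$seed * 7L + k * 1009L) %% .Machine$integer.max

  ## mutations ---------------------------------------------------------------
  set.seed(sub_seed(1L))
  pres <- sample_gene_presence(config, n)
  vrows <- list()
  for (g in colnames(pres)) {
    idx <- which(pres[, g] == 1L)
    if (!length(idx)) next
    extra_p <- unname(config$extra_variant_prob[g])
    if (is.na(extra_p)) extra_p <- unname(config$extra_variant_prob[".default"])
    n_var <- 1L + as.integer(stats::runif(length(idx)) < extra_p)
    pid <- rep(ids[idx], n_var)
    m <- length(pid)
    tf <- unname(config$truncating_frac[g])
    if (is.na(tf)) tf <- 0.5
    trunc <- stats::runif(m) < tf
    effect <- ifelse(trunc,
                     sample(c("nonsense", "frameshift"), m, replace = TRUE),
                     sample(c("missense", "splice", "inframe"), m,
                            replace = TRUE, prob = c(0.8, 0.15, 0.05)))
    vrows[[g]] <- data.frame(
      patient_id = pid, gene = g, effect = effect,
      vaf = sample_vaf(m, config$genes[[g]]$w_low),
      pathogenicity = sample(c("pathogenic", "likely_pathogenic"), m,
                             replace = TRUE, prob = c(0.6, 0.4)),
      pop_maf = 0, is_driver = 0L, stringsAsFactors = FALSE)
  }
  # driver rows: one JAK2 mutation per patient
  driver_vaf <- pmin(98, pmax(1.3, stats::rnorm(
    n, config$clinical$driver_vaf_mean, config$clinical$driver_vaf_sd)))
  is_v617f <- stats::runif(n) < config$clinical$v617f_frac
  vrows$driver <- data.frame(
    patient_id = ids, gene = "JAK2",
    effect = ifelse(is_v617f, "missense", "inframe"),
    vaf = round(driver_vaf, 1), pathogenicity = "pathogenic",
    pop_maf = 0, is_driver = 1L, stringsAsFactors = FALSE)
  # noise rows that the retention rules must remove: rare-polymorphism VUS,
  # common polymorphisms, and sub-threshold VAF calls
  nz <- config$noise
  panel_nd <- setdiff(names(config$genes), "JAK2")
  noise_rows <- function(m, pathogenicity, vaf, pop_maf) {
    if (m <= 0) return(NULL)
    data.frame(
      patient_id = sample(ids, m, replace = TRUE),
      gene = sample(panel_nd, m, replace = TRUE),
      effect = sample(variant_effects, m, replace = TRUE),
      vaf = vaf, pathogenicity = pathogenicity, pop_maf = pop_maf,
      is_driver = 0L, stringsAsFactors = FALSE)
  }
  n_vus <- stats::rpois(1, nz$vus_rate * n)
  vrows$noise_vus <- noise_rows(n_vus, "VUS",
                                round(stats::runif(n_vus, 2, 60), 1),
                                round(stats::runif(n_vus, 0.01, 0.5), 3))
  n_poly <- stats::rpois(1, nz$common_poly_rate * n)
  vrows$noise_poly <- noise_rows(n_poly, "likely_pathogenic",
                                 round(stats::runif(n_poly, 30, 60), 1),
                                 round(stats::runif(n_poly, 1, 30), 2))
  n_low <- stats::rpois(1, nz$low_vaf_rate * n)
  vrows$noise_lowvaf <- noise_rows(n_low, "pathogenic",
                                   round(stats::runif(n_low, 0.5, 1.9), 2), 0)
  variants <- do.call(rbind, vrows)
  rownames(variants) <- NULL

  ## CNV ---------------------------------------------------------------------
  set.seed(sub_seed(2L))
  crows <- list()
  for (lbl in names(config$cnv)) {
    hit <- which(stats::runif(n) < config$cnv[[lbl]])
    if (!length(hit)) next
    parts <- strsplit(lbl, "_")[[1]]
    crows[[lbl]] <- data.frame(patient_id = ids[hit], region = parts[1],
                               kind = parts[2], stringsAsFactors = FALSE)
  }
  cnv <- if (length(crows)) do.call(rbind, crows) else
    data.frame(patient_id = character(0), region = character(0),
               kind = character(0))
  rownames(cnv) <- NULL

  ## clinical covariates -----------------------------------------------------
  set.seed(sub_seed(3L))
  cc <- config$clinical
  age <- pmin(cc$age_range[2], pmax(cc$age_range[1],
                                    stats::rnorm(n, cc$age_median, cc$age_sd)))
  clinical <- data.frame(
    patient_id = ids,
    age_dx = round(age, 1),
    sex = ifelse(stats::runif(n) < cc$male_frac, "male", "female"),
    prior_arterial_thrombosis = as.integer(stats::runif(n) < cc$prior_arterial),
    prior_venous_thrombosis = as.integer(stats::runif(n) < cc$prior_venous),
    constitutional_symptoms = as.integer(stats::runif(n) < cc$constitutional),
    pruritus = as.integer(stats::runif(n) < cc$pruritus),
    leukocytes = round(stats::rlnorm(n, cc$leuko_meanlog, cc$leuko_sdlog), 1),
    platelets = round(stats::rlnorm(n, cc$plt_meanlog, cc$plt_sdlog)),
    neutrophil_lymphocyte_ratio =
      round(stats::rlnorm(n, cc$nlr_meanlog, cc$nlr_sdlog), 2),
    driver = ifelse(is_v617f, "V617F", "exon12"),
    driver_vaf = round(driver_vaf, 1),
    stringsAsFactors = FALSE)

  ## genomic group from the generated genetics -------------------------------
  retained <- prognostic_subset(filter_variants(variants))
  grp <- classify_pv_hmr(retained, cnv, ids)

  ## outcomes ----------------------------------------------------------------
  covs <- data.frame(
    group_high = as.integer(grp$genomic_group == "high"),
    group_intermediate = as.integer(grp$genomic_group == "intermediate"),
    age_c = clinical$age_dx - config$hazards$age_center)
  outcomes <- simulate_event_histories(covs, config$hazards,
                                       config$censoring,
                                       seed = sub_seed(4L))
  # transformation subtype: SMF about twice as frequent as MDS/AML (31 vs 14 published)
  subtype <- rep(NA_character_, n)
  tr <- outcomes$event_transformation == 1L
  subtype[tr] <- sample(c("SMF", "MDS_AML"), sum(tr), replace = TRUE,
                        prob = c(31, 14) / 45)
  clinical <- cbind(clinical,
                    outcomes[, c("time_transformation", "event_transformation")],
                    data.frame(transformation_subtype = subtype),
                    outcomes[, c("time_death", "event_death", "time_censor")])

  list(variants = variants, cnv = cnv, clinical = clinical,
       group = grp$genomic_group)
}

#' Hazard-ratio recovery study for a transition-specific group effect
#'
#' Simulates seeded replicate cohorts from the illness-death generator with
#' a categorical genomic-risk group whose hazard on one transition is
#' multiplied by known effects, fits the transition-specific Cox model to
#' each replicate, and summarises the fitted hazard ratios. This is the
#' package's parameter-recovery engine: with the effect sizes set to the
#' final multistate-model estimates it checks that the fitting machinery
#' returns what the generator put in.
#'
#' @param transition Transition carrying the group effect (`"1->2"` or
#'   `"1->3"`).
#' @param hr Named numeric vector of hazard ratios for the non-reference
#'   group levels, e.g. `c(group_high = 5.42)` or
#'   `c(group_high = 5.42, group_intermediate = 3.51)`.
#' @param group_probs Membership probabilities, named `low` /
#'   `intermediate` / `high` (levels with probability 0 may be omitted).
#' @param n Patients per replicate.
#' @param n_rep Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param baseline Constant baseline hazards per transition.
#' @param censoring List with `admin_horizon` and exponential `rate`.
#' @return List with `mean_hr` (named), `hr` (replicate-by-term matrix) and
#'   the call parameters.
#' @export
simulate_hr_recovery <- function(transition, hr,
                                 group_probs = c(low = 0.85, high = 0.15),
                                 n = 1500, n_rep = 100, seed = 1,
                                 baseline = c(`1->2` = 0.0042,
                                              `1->3` = 0.014,
                                              `2->3` = 0.30),
                                 censoring = list(admin_horizon = 20,
                                                  rate = 0.018)) {
  stopifnot(transition %in% c("1->2", "1->3"))
  terms <- names(hr)
  stopifnot(all(terms %in% c("group_high", "group_intermediate")))
  levels_used <- names(group_probs)[group_probs > 0]
  hmat <- base::matrix(NA_real_, n_rep, length(terms),
                       dimnames = list(NULL, terms))
  hazards <- list(baseline = baseline,
                  shape = c(`1->2` = 1, `1->3` = 1, `2->3` = 1),
                  beta = stats::setNames(
                    list(NULL, NULL, NULL), c("1->2", "1->3", "2->3")))
  hazards$beta[[transition]] <- log(hr)
  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    grp <- sample(levels_used, n, replace = TRUE,
                  prob = group_probs[levels_used])
    covs <- data.frame(group_high = as.integer(grp == "high"),
                       group_intermediate = as.integer(grp == "intermediate"))
    out <- simulate_event_histories(covs, hazards, censoring,
                                    seed = seed * 13L + r)
    cl <- cbind(data.frame(patient_id = sprintf("P%05d", seq_len(n))),
                covs, out)
    ms <- to_multistate(cl, covariates = terms)
    fit <- fit_cox_transition(ms, transition, terms)
    hmat[r, ] <- fit$coef$hr[match(terms, fit$coef$term)]
  }
  list(transition = transition, true_hr = hr,
       mean_hr = colMeans(hmat), hr = hmat,
       n = n, n_rep = n_rep, seed = seed)
}
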