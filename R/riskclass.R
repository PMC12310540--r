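# PV-HMR 3-tier genomic classification and a generic rule-based score engine.

genomic_group_levels <- c("low", "intermediate", "high")

#' Classify patients into the PV-HMR 3-tier genomic groups
#'
#' Sequential classification of each patient from their retained prognostic
#' (pathogenic / likely-pathogenic, filtered) non-driver variants and CNV
#' calls:
#'
#' 1. **high** (PV-HMR) — any mutation in the high-molecular-risk genes
#'    (default SRSF2, IDH1, IDH2, EZH2, NFE2), or two or more additional
#'    (non-driver) mutations, or at least one CNV outside chromosome 9;
#' 2. **intermediate** — otherwise, a TET2 mutation with VAF at or above
#'    `tet2_vaf_threshold` (default 5%);
#' 3. **low** — otherwise.
#'
#' The JAK2 driver never counts toward any rule; 9p abnormalities (9pUPD, 9p
#' trisomy) never count as CNV triggers. The TET2 rule uses the per-patient
#' maximum TET2 VAF. Thresholds are inclusive.
#'
#' @param variants Prognostic variant subset (with `is_driver`).
#' @param cnv Validated CNV calls.
#' @param patients Character vector of patient identifiers to classify.
#' @param hmr_genes High-molecular-risk gene set.
#' @param tet2_vaf_threshold TET2 VAF cutoff (percent) for intermediate risk.
#' @return Data frame: patient_id, genomic_group (factor low < intermediate
#'   < high), n_additional, max_tet2_vaf, has_non9_cnv, trigger_rule.
#' @export
classify_pv_hmr <- function(variants, cnv, patients,
                            hmr_genes = c("SRSF2", "IDH1", "IDH2", "EZH2", "NFE2"),
                            tet2_vaf_threshold = 5.0) {
  patients <- as.character(patients)
  nd <- variants[variants$is_driver != 1L, , drop = FALSE]

  n_additional <- stats::setNames(integer(length(patients)), patients)
  if (nrow(nd)) {
    tab <- table(factor(nd$patient_id, levels = patients))
    n_additional[] <- as.integer(tab)
  }
  has_hmr <- patients %in% nd$patient_id[nd$gene %in% hmr_genes]
  tet2 <- nd[nd$gene == "TET2", , drop = FALSE]
  max_tet2 <- stats::setNames(numeric(length(patients)), patients)
  if (nrow(tet2)) {
    mx <- tapply(tet2$vaf, factor(tet2$patient_id, levels = patients), max)
    max_tet2[!is.na(mx)] <- mx[!is.na(mx)]
  }
  non9 <- unique(cnv$patient_id[cnv$region != "9p"])
  has_non9 <- patients %in% non9

  group <- rep("low", length(patients))
  trigger <- rep("none", length(patients))
  multi <- n_additional >= 2L
  tet2_rule <- max_tet2 >= tet2_vaf_threshold

  high <- has_hmr | multi | has_non9
  group[high] <- "high"
  trigger[high] <- ifelse(has_hmr[high], "hmr_gene",
                          ifelse(multi[high], "multiple_mutations", "non9_cnv"))
  inter <- !high & tet2_rule
  group[inter] <- "intermediate"
  trigger[inter] <- "tet2_vaf"

  data.frame(patient_id = patients,
             genomic_group = factor(group, levels = genomic_group_levels),
             n_additional = as.integer(n_additional),
             max_tet2_vaf = as.numeric(max_tet2),
             has_non9_cnv = has_non9,
             trigger_rule = trigger,
             row.names = NULL, stringsAsFactors = FALSE)
}

score_ops <- list(
  ge = `>=`, gt = `>`, le = `<=`, lt = `<`, eq = `==`,
  `in` = function(x, set) x %in% set)

#' Validate a rule-based score configuration
#'
#' A score configuration holds a `name`, an ordered list of `criteria`
#' (each `field`, `op` in ge/gt/le/lt/eq/in, `value`, `points`), and
#' `categories`: strictly increasing point `cutpoints` with one more `labels`
#' entry than cutpoints. Criteria referencing a field absent from `fields`
#' (when given) fail at load time.
#'
#' @param config List (typically from [read_score_config()]).
#' @param fields Optional character vector of known field names.
#' @return The validated config, invisibly classed `score_config`.
#' @export
validate_score_config <- function(config, fields = NULL) {
  if (is.null(config$name)) stop("score config needs a name", call. = FALSE)
  for (cr in config$criteria) {
    if (is.null(cr$field) || is.null(cr$op) || is.null(cr$value) ||
        is.null(cr$points))
      stop("each criterion needs field/op/value/points", call. = FALSE)
    if (!cr$op %in% names(score_ops))
      stop("unknown predicate operator: ", cr$op, call. = FALSE)
    if (!is.null(fields) && !cr$field %in% fields)
      stop("criterion references unknown field: ", cr$field, call. = FALSE)
  }
  config$categories$cutpoints <- unlist(config$categories$cutpoints)
  config$categories$labels <- unlist(config$categories$labels)
  cuts <- config$categories$cutpoints
  labs <- config$categories$labels
  if (is.null(labs) || length(labs) < 2)
    stop("score config needs at least 2 categories", call. = FALSE)
  if (length(labs) != length(cuts) + 1)
    stop("need one more category label than cutpoints", call. = FALSE)
  if (is.unsorted(cuts, strictly = TRUE))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  class(config) <- "score_config"
  invisible(config)
}

#' Read a score configuration from YAML
#'
#' @param path YAML file path.
#' @param fields Optional known field names for validation.
#' @return A validated `score_config`.
#' @export
read_score_config <- function(path, fields = NULL) {
  validate_score_config(yaml::read_yaml(path), fields = fields)
}

#' Apply a rule-based prognostic score
#'
#' Evaluates each criterion's predicate on the patient table, sums the points
#' of satisfied criteria, and buckets the total by the configured cutpoints
#' (category j when `cutpoints[j-1] <= total < cutpoints[j]`). Patients with
#' a missing value in any referenced field are reported as `"unevaluable"`.
#'
#' @param patients Data frame of patient-level fields (one row per patient).
#' @param config A `score_config` (see [validate_score_config()]).
#' @return Data frame: patient_id, points, category.
#' @export
score_rule_based <- function(patients, config) {
  config <- validate_score_config(unclass(config), fields = names(patients))
  n <- nrow(patients)
  points <- numeric(n)
  unevaluable <- logical(n)
  for (cr in config$criteria) {
    x <- patients[[cr$field]]
    hit <- score_ops[[cr$op]](x, cr$value)
    unevaluable <- unevaluable | is.na(hit)
    points <- points + ifelse(is.na(hit), 0, hit) * cr$points
  }
  cuts <- config$categories$cutpoints
  labs <- config$categories$labels
  category <- labs[findInterval(points, cuts) + 1L]
  category[unevaluable] <- "unevaluable"
  data.frame(patient_id = patients$patient_id, points = points,
             category = category, row.names = NULL, stringsAsFactors = FALSE)
}
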