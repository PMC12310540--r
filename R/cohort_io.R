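# Cohort tables: reading, validation, variant retention rules, mutation matrix.

#' Default myeloid gene panel
#'
#' Genes named in the source cohort's targeted myeloid panel that this package
#' ships as a default. The full custom capture covered 36 genes; the panel is
#' configurable (see [read_pipeline_config()]) and any gene symbol outside the
#' configured panel is dropped with a warning at read time.
#'
#' @return Character vector of gene symbols.
#' @export
default_panel <- function() {
  c("JAK2", "TET2", "DNMT3A", "ASXL1", "SRSF2", "SF3B1", "U2AF1",
    "IDH1", "IDH2", "EZH2", "NFE2", "CBL", "TP53", "PPM1D", "BCOR")
}

variant_effects <- c("missense", "nonsense", "frameshift", "splice", "inframe")
truncating_effects <- c("nonsense", "frameshift")
pathogenicity_levels <- c("pathogenic", "likely_pathogenic", "VUS")
cnv_regions <- c("1q", "5", "7", "8", "9p", "13q", "17p", "20q")
cnv_kinds <- c("UPD", "gain", "loss")

clinical_required_cols <- c(
  "patient_id", "age_dx", "sex",
  "prior_arterial_thrombosis", "prior_venous_thrombosis",
  "constitutional_symptoms", "pruritus",
  "leukocytes", "platelets", "neutrophil_lymphocyte_ratio",
  "driver", "driver_vaf",
  "time_transformation", "event_transformation",
  "time_death", "event_death", "time_censor")

stop_rows <- function(msg, lines) {
  stop(msg, " (line", if (length(lines) > 1) "s", " ",
       paste(utils::head(lines, 10L), collapse = ", "),
       if (length(lines) > 10) ", ...", ")", call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", what, " table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

validate_variants <- function(variants, panel) {
  check_columns(variants, c("patient_id", "gene", "effect", "vaf",
                            "pathogenicity", "pop_maf", "is_driver"),
                "variant")
  variants$patient_id <- as.character(variants$patient_id)
  variants$gene <- as.character(variants$gene)
  variants$vaf <- as.numeric(variants$vaf)
  variants$pop_maf <- as.numeric(variants$pop_maf)
  variants$is_driver <- as.integer(variants$is_driver)
  # data line numbers (header is line 1)
  ln <- seq_len(nrow(variants)) + 1L

  bad <- which(is.na(variants$vaf) | variants$vaf < 0 | variants$vaf > 100)
  if (length(bad)) stop_rows("variant allele frequency out of [0,100]", ln[bad])
  bad <- which(is.na(variants$pop_maf) | variants$pop_maf < 0 | variants$pop_maf > 100)
  if (length(bad)) stop_rows("population MAF out of [0,100]", ln[bad])
  bad <- which(!variants$effect %in% variant_effects)
  if (length(bad)) stop_rows("unknown variant effect class", ln[bad])
  bad <- which(!variants$pathogenicity %in% pathogenicity_levels)
  if (length(bad)) stop_rows("unknown pathogenicity class", ln[bad])

  unknown <- which(!variants$gene %in% panel)
  if (length(unknown)) {
    warning(length(unknown), " variant row(s) in genes outside the configured panel dropped: ",
            paste(unique(variants$gene[unknown]), collapse = ", "), call. = FALSE)
    variants <- variants[-unknown, , drop = FALSE]
  }
  attr(variants, "n_dropped_unknown_gene") <- length(unknown)
  variants
}

validate_cnv <- function(cnv) {
  check_columns(cnv, c("patient_id", "region", "kind"), "CNV")
  cnv$patient_id <- as.character(cnv$patient_id)
  ln <- seq_len(nrow(cnv)) + 1L
  bad <- which(!cnv$region %in% cnv_regions)
  if (length(bad)) stop_rows("unknown CNV region", ln[bad])
  bad <- which(!cnv$kind %in% cnv_kinds)
  if (length(bad)) stop_rows("unknown CNV kind", ln[bad])
  cnv
}

validate_clinical <- function(clinical) {
  check_columns(clinical, clinical_required_cols, "clinical")
  clinical$patient_id <- as.character(clinical$patient_id)
  for (col in c("age_dx", "leukocytes", "platelets", "neutrophil_lymphocyte_ratio",
                "driver_vaf", "time_transformation", "time_death", "time_censor"))
    clinical[[col]] <- as.numeric(clinical[[col]])
  for (col in c("prior_arterial_thrombosis", "prior_venous_thrombosis",
                "constitutional_symptoms", "pruritus",
                "event_transformation", "event_death"))
    clinical[[col]] <- as.integer(clinical[[col]])
  ln <- seq_len(nrow(clinical)) + 1L

  if (anyDuplicated(clinical$patient_id))
    stop_rows("duplicated patient_id in clinical table",
              ln[duplicated(clinical$patient_id)])
  bad <- which(!clinical$sex %in% c("male", "female"))
  if (length(bad)) stop_rows("sex must be male/female", ln[bad])
  bad <- which(!clinical$driver %in% c("V617F", "exon12"))
  if (length(bad)) stop_rows("driver must be V617F/exon12", ln[bad])
  for (col in c("time_transformation", "time_death", "time_censor")) {
    bad <- which(clinical[[col]] < 0)
    if (length(bad)) stop_rows(paste0(col, " negative"), ln[bad])
  }
  bad <- which(is.na(clinical$time_censor))
  if (length(bad)) stop_rows("time_censor is required for every patient", ln[bad])
  bad <- which(clinical$event_transformation == 1L &
                 (is.na(clinical$time_transformation) |
                    clinical$time_transformation >
                      pmin(clinical$time_death, clinical$time_censor, na.rm = TRUE)))
  if (length(bad))
    stop_rows("transformation time missing or after death/censoring", ln[bad])
  bad <- which(clinical$event_death == 1L & is.na(clinical$time_death))
  if (length(bad)) stop_rows("death time missing for death event", ln[bad])
  clinical
}

#' Read and validate a cohort (variant, CNV, clinical tables)
#'
#' Reads the three tab-separated cohort tables, coerces types, enforces the
#' domain invariants (VAF and population MAF in \[0,100\], known effect and
#' pathogenicity classes, CNV regions from the panel's eight target regions,
#' event-time ordering) and checks referential integrity: every patient
#' mentioned in the variant or CNV table must exist in the clinical table.
#' Variants in genes outside `panel` are dropped with a warning; the dropped
#' count is kept in `attr(, "n_dropped_unknown_gene")`.
#'
#' @param variant_path,cnv_path,clinical_path Paths to tab-separated files
#'   with header rows (see the package vignette for column layouts).
#' @param panel Character vector of gene symbols to accept.
#' @return A list with elements `variants`, `cnv`, `clinical` (data frames).
#' @export
read_cohort <- function(variant_path, cnv_path, clinical_path,
                        panel = default_panel()) {
  read_tsv0 <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  variants <- validate_variants(read_tsv0(variant_path), panel)
  cnv <- validate_cnv(read_tsv0(cnv_path))
  clinical <- validate_clinical(read_tsv0(clinical_path))

  orphan <- setdiff(c(variants$patient_id, cnv$patient_id), clinical$patient_id)
  if (length(orphan))
    stop("patient(s) in variant/CNV table absent from clinical table: ",
         paste(utils::head(orphan, 10L), collapse = ", "), call. = FALSE)
  list(variants = variants, cnv = cnv, clinical = clinical)
}

#' Write a cohort to tab-separated files
#'
#' Inverse of [read_cohort()]: writes `variants.tsv`, `cnv.tsv` and
#' `clinical.tsv` under `dir`. Missing times are written as empty fields.
#'
#' @param cohort List with `variants`, `cnv`, `clinical` data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("variants.tsv", "cnv.tsv", "clinical.tsv"))
  for (i in seq_along(paths))
    utils::write.table(cohort[[i]], paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  invisible(paths)
}

#' Apply the variant retention rules
#'
#' Retains variants with allele frequency at or above the detection floor
#' (default 2%), removes common polymorphisms (population MAF >= 1%), and
#' removes variants of unknown significance that are rare polymorphisms
#' (population MAF >= 0.01%). All three thresholds are inclusive and
#' configurable. Input row order is preserved; the operation is idempotent.
#'
#' @param variants Validated variant data frame.
#' @param min_vaf VAF floor in percent.
#' @param common_maf Population-MAF cutoff (percent) above which any variant
#'   is treated as a common polymorphism.
#' @param rare_vus_maf Population-MAF cutoff (percent) above which a VUS is
#'   treated as a rare polymorphism.
#' @return The retained subset of `variants`.
#' @export
filter_variants <- function(variants, min_vaf = 2.0, common_maf = 1.0,
                            rare_vus_maf = 0.01) {
  keep <- variants$vaf >= min_vaf &
    variants$pop_maf < common_maf &
    !(variants$pathogenicity == "VUS" & variants$pop_maf >= rare_vus_maf)
  variants[keep, , drop = FALSE]
}

#' Restrict to the prognostic variant subset
#'
#' Keeps only pathogenic and likely-pathogenic variants for prognostic
#' analysis. Driver (JAK2) variants are retained here — they carry the
#' `is_driver` flag and are excluded later from "additional mutation" counts
#' and matrix categories.
#'
#' @param variants Filtered variant data frame.
#' @return Subset with `pathogenicity` pathogenic or likely_pathogenic.
#' @export
prognostic_subset <- function(variants) {
  variants[variants$pathogenicity %in% c("pathogenic", "likely_pathogenic"), ,
           drop = FALSE]
}

category_of <- function(gene, effect, split_effect_genes) {
  ifelse(gene %in% split_effect_genes,
         paste0(gene, ifelse(effect %in% truncating_effects,
                             "_truncating", "_missense")),
         gene)
}

#' Gene category to gene symbol
#'
#' Maps matrix category labels (e.g. `"TET2_truncating"`) back to gene
#' symbols (`"TET2"`).
#'
#' @param categories Character vector of category labels.
#' @return Character vector of gene symbols.
#' @export
category_gene <- function(categories) {
  sub("_(truncating|missense)$", "", categories)
}

#' Build the patients-by-category mutation matrix
#'
#' Constructs binary presence and maximum-VAF matrices over gene categories
#' from the prognostic variant subset. Genes in `split_effect_genes` are split
#' into truncating (nonsense/frameshift) versus missense/other categories.
#' Driver variants never form categories and never count as additional
#' mutations. The per-patient `n_additional` counts retained non-driver
#' *variants* (two TET2 variants count as 2, not 1). Categories mutated in
#' fewer than `min_patients` patients are dropped from the matrices (but not
#' from `n_additional`).
#'
#' @param variants Prognostic variant subset (see [prognostic_subset()]).
#' @param patients Character vector of all patient identifiers (row order of
#'   the output matrices).
#' @param split_effect_genes Genes split by effect class.
#' @param min_patients Minimum number of mutated patients for a category to
#'   be kept.
#' @return An object of class `mutation_matrix`: list with `patients`,
#'   `categories`, `presence` (0/1 matrix), `max_vaf` (percent matrix) and
#'   `n_additional` (named integer vector).
#' @export
build_mutation_matrix <- function(variants, patients,
                                  split_effect_genes = c("TET2", "DNMT3A"),
                                  min_patients = 0L) {
  patients <- as.character(patients)
  stray <- setdiff(unique(variants$patient_id), patients)
  if (length(stray))
    stop("variant rows for patient(s) absent from the patient list: ",
         paste(utils::head(stray, 10L), collapse = ", "), call. = FALSE)

  nondriver <- variants[variants$is_driver != 1L, , drop = FALSE]
  n_additional <- stats::setNames(integer(length(patients)), patients)
  if (nrow(nondriver)) {
    tab <- table(factor(nondriver$patient_id, levels = patients))
    n_additional[] <- as.integer(tab)
  }

  cats <- sort(unique(category_of(nondriver$gene, nondriver$effect,
                                  split_effect_genes)))
  presence <- matrix(0L, length(patients), length(cats),
                     dimnames = list(patients, cats))
  max_vaf <- matrix(0, length(patients), length(cats),
                    dimnames = list(patients, cats))
  if (nrow(nondriver)) {
    cat_idx <- match(category_of(nondriver$gene, nondriver$effect,
                                 split_effect_genes), cats)
    pat_idx <- match(nondriver$patient_id, patients)
    for (k in seq_len(nrow(nondriver))) {
      i <- pat_idx[k]; j <- cat_idx[k]
      presence[i, j] <- 1L
      max_vaf[i, j] <- max(max_vaf[i, j], nondriver$vaf[k])
    }
  }
  keep <- colSums(presence) >= min_patients
  structure(
    list(patients = patients, categories = cats[keep],
         presence = presence[, keep, drop = FALSE],
         max_vaf = max_vaf[, keep, drop = FALSE],
         n_additional = n_additional),
    class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("mutation_matrix:", length(x$patients), "patients x",
      length(x$categories), "gene categories\n")
  cat("  patients with >=1 additional mutation:",
      sum(x$n_additional >= 1), "\n")
  invisible(x)
}

#' Read the pipeline configuration
#'
#' Loads a YAML configuration holding the gene panel and the variant filter
#' thresholds (`panel.genes`, `filters.min_vaf`, `filters.common_maf`,
#' `filters.rare_vus_maf`). Values missing from the file fall back to the
#' package defaults.
#'
#' @param path Path to a YAML file; `NULL` loads the packaged default.
#' @return List with `panel` (character) and `filters` (named numeric list).
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pipeline_config.yaml", package = "pvhmr")
  cfg <- yaml::read_yaml(path)
  filters <- list(min_vaf = 2.0, common_maf = 1.0, rare_vus_maf = 0.01)
  filters[names(cfg$filters)] <- cfg$filters
  panel <- if (is.null(cfg$panel$genes)) default_panel() else
    as.character(cfg$panel$genes)
  list(panel = panel, filters = filters)
}
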