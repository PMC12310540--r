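#!/usr/bin/env Rscript
# Step 3 — genomic risk classification.
#
# Applies the sequential PV-HMR rules (high-risk genes / >=2 additional
# mutations / non-9p CNV, then TET2 VAF >= 5%) and the two comparator
# scores, and writes the per-patient group table.

library(pvhmr)

co <- read_cohort("scratch/cohort/variants.tsv", "scratch/cohort/cnv.tsv",
                  "scratch/cohort/clinical.tsv")
prog <- prognostic_subset(filter_variants(co$variants))
grp <- classify_pv_hmr(prog, co$cnv, co$clinical$patient_id)
message("PV-HMR groups: ",
        paste(names(table(grp$genomic_group)), table(grp$genomic_group),
              sep = "=", collapse = ", "))

# comparator scores need two derived fields
patients <- co$clinical
patients$srsf2_mutated <- as.integer(
  patients$patient_id %in% prog$patient_id[prog$gene == "SRSF2"])
patients$prior_thrombosis <- as.integer(
  patients$prior_arterial_thrombosis == 1 |
    patients$prior_venous_thrombosis == 1)
iwg <- score_rule_based(patients,
                        read_score_config(system.file("extdata", "iwg_pv.yaml",
                                                      package = "pvhmr")))
mipss <- score_rule_based(patients,
                          read_score_config(system.file("extdata",
                                                        "mipss_pv.yaml",
                                                        package = "pvhmr")))
message("IWG-PV high: ", sum(iwg$category == "high"),
        "; MIPSS-PV high: ", sum(mipss$category == "high"))

grp$iwg_pv <- iwg$category
grp$mipss_pv <- mipss$category
dir.create("results", showWarnings = FALSE)
write.table(grp, "results/groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("written: results/groups.tsv")
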