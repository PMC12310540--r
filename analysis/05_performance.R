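#!/usr/bin/env Rscript
# Step 5 — prognostic performance comparison.
#
# Evaluates the genomic classification (+ age) against the IWG-PV and
# MIPSS-PV comparator scores on both endpoints (overall survival and
# hematologic transformation) with Harrell's C and IPCW AUC / Brier at
# 6, 10 and 14 years.

library(pvhmr)

co <- read_cohort("scratch/cohort/variants.tsv", "scratch/cohort/cnv.tsv",
                  "scratch/cohort/clinical.tsv")
groups <- read.delim("results/groups.tsv")
cl <- co$clinical
eps <- endpoint_data(cl)
horizons <- c(6, 10, 14)

cat_risk <- function(x, levels) match(x, levels)
model_from_groups <- function(g, extra = 0) {
  risk <- as.numeric(g) + extra
  list(risk = risk,
       pred = lapply(eps, function(ep)
         km_group_predictions(g, ep$times, ep$status, horizons)))
}
genomic_group <- factor(groups$genomic_group,
                        levels = c("low", "intermediate", "high"))
models <- list(
  `PV-HMR+age` = model_from_groups(genomic_group, extra = cl$age_dx / 200),
  `IWG-PV` = model_from_groups(factor(groups$iwg_pv,
                                      levels = c("low", "intermediate", "high"))),
  `MIPSS-PV` = model_from_groups(factor(groups$mipss_pv,
                                        levels = c("low", "intermediate", "high"))))

report <- performance_report(models, eps, horizons)
write.table(report, "results/performance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (en in unique(report$endpoint)) {
  message(en, ":")
  for (mn in unique(report$model)) {
    r <- report[report$model == mn & report$endpoint == en, ]
    message(sprintf("  %-11s C %.2f | AUC %s | Brier %s", mn, r$cindex[1],
                    paste(sprintf("%.3f", r$auc), collapse = "/"),
                    paste(sprintf("%.3f", r$brier), collapse = "/")))
  }
}
message("written: results/performance.tsv")
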