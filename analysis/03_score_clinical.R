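#!/usr/bin/env Rscript
# Score the bedside record against the consensus gold standard: hour-level
# identification (mark or antiseizure medication in the hour or the hour
# after), false detections (form mark with no confirmed seizure in that
# hour or the hour before), and inappropriate medication administrations.

suppressPackageStartupMessages(library(cotside))

in_dir <- "results/synthetic_cohort"
ann <- read_annotations(file.path(in_dir, c("annotations_expert1.csv",
                                            "annotations_expert2.csv")))
clin <- read_clinical(file.path(in_dir, "clinical.csv"))
meta <- read_metadata(file.path(in_dir, "metadata.csv"))

cons <- build_consensus(ann, meta)
scored <- score_cohort(clin, cons, meta)

readr::write_csv(scored$hour_scores, "results/hour_scores.csv")
readr::write_csv(scored$neonates, "results/neonate_scores.csv")

nn <- scored$neonates
for (g in unique(nn$group)) {
  d <- nn[nn$group == g, ]
  cc <- neonate_confusion(d)
  cat(sprintf("%s: tp=%d tn=%d fp=%d fn=%d | gold hours=%d identified=%d\n",
              g, cc$tp, cc$tn, cc$fp, cc$fn,
              sum(d$n_gold_hours), sum(d$n_identified)))
}
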