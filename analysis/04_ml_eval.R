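#!/usr/bin/env Rscript
# Machine-learning evaluation: polynomial-kernel SVM classification of sleep
# stages from window-level MI features, SVR prediction of RDI and ESS from
# subject-level stage MI, and the pooled-MI highest-density interval reported
# alongside the 75% accuracy decision threshold.

suppressPackageStartupMessages(library(pacsleep))

cohort <- if (file.exists("scratch/cohort.rds")) {
  readRDS("scratch/cohort.rds")
} else {
  generate_cohort(cohort_spec(seed = 1))
}
smis <- if (file.exists("scratch/stage_mi.rds")) {
  readRDS("scratch/stage_mi.rds")
} else {
  stop("run analysis/02_stage_mi.R first")
}

# window-level features from a balanced subject subset (both groups); the
# classifier pools windows across subjects
set.seed(2)
ids <- c(sample(cohort$subjects$id[cohort$subjects$rdi <= 15], 5),
         sample(cohort$subjects$id[cohort$subjects$rdi > 15], 5))
wf <- do.call(rbind, lapply(ids, function(id) {
  dec <- split_bands(antialias_and_detrend(cohort$recordings[[id]]))
  window_feature_table(dec, cohort$hypnograms[[id]])
}))
# stratified subsample: the grid search scales quadratically with rows and
# 600 windows already give ~2% accuracy resolution
wf <- do.call(rbind, lapply(split(wf, wf$stage), function(g) {
  g[sample(nrow(g), min(nrow(g), 120)), ]
}))
cat("Stage classification on", nrow(wf), "windows from", length(ids),
    "subjects (10 x 75/25 splits, grid-searched polynomial SVM):\n")
cv <- classify_stages(wf, seed = 3)
cat(sprintf("  per-split accuracy: %s\n",
            paste(sprintf("%.1f", cv$accuracy), collapse = " ")))
cat(sprintf("  mean accuracy: %.1f%% (chance 20%%)\n", cv$mean_accuracy))
print(cv$confusion)

features <- subject_feature_table(smis, cohort$subjects)
thr <- accuracy_threshold(unlist(lapply(smis, function(s) s$mi)))
cat(sprintf("\nPooled-MI 95%% HDI: [%.4f, %.4f]; decision threshold %.0f%%\n",
            thr$hdi_lower, thr$hdi_upper, thr$threshold))

pred <- list()
for (target in c("rdi", "ess")) {
  pr <- predict_clinical(features, target, seed = 4)
  pred[[target]] <- pr
  cat(sprintf("SVR %s: per-split skill %s | mean %.1f%%, %d/%d above %.0f%%\n",
              toupper(target),
              paste(sprintf("%.0f", pr$accuracy), collapse = " "),
              pr$mean_accuracy, sum(pr$accuracy > thr$threshold),
              length(pr$accuracy), thr$threshold))
}

jsonlite::write_json(
  list(classification = list(accuracy = cv$accuracy,
                             mean_accuracy = cv$mean_accuracy,
                             confusion = as.data.frame.matrix(cv$confusion)),
       threshold = thr,
       prediction = lapply(pred, function(p)
         list(accuracy = p$accuracy, mean_accuracy = p$mean_accuracy))),
  "results/ml_eval.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/ml_eval.json\n")
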