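#!/usr/bin/env Rscript
# Stage 1 — simulate a longitudinal aging cohort with known ground truth.
#
# Draws subjects with truncated-normal baseline ages (mean 69, range
# 47-102), ~3 visits each at least a year apart, a 24-marker cytokine
# panel in which 9 markers truly drift with age, 4 assay batches, and
# TIV-scaled volumes of 7 highly inter-correlated functional networks
# that decline with age and load negatively on a latent inflammation
# score.  Not every visit carries both a blood draw and an MRI scan;
# that partial overlap is what clock propagation later repairs.

source(file.path("analysis", "00_config.R"))

cfg <- sim_config(n_subjects = n_subjects, seed = stage_seeds[1])
cohort <- generate_cohort(cfg)

set.seed(stage_seeds[2])
n <- nrow(cohort$visits)
visits <- cohort$visits
visits$has_blood <- runif(n) < 0.85
visits$has_mri <- runif(n) < 0.80
keep <- visits$has_blood | visits$has_mri
visits <- visits[keep, ]

write_stage(visits, "visits.csv")
write_stage(data.frame(visit_id = visits$visit_id,
                       cohort$panel[keep, , drop = FALSE]),
            "panel_complete.csv")
write_stage(cohort$volumes[keep, ][visits$has_mri, ], "volumes.csv")
jsonlite::write_json(
  list(support = cohort$truth$support,
       age_slopes = as.list(cohort$truth$age_slopes),
       latent = as.list(setNames(cohort$truth$latent[keep],
                                 visits$visit_id)),
       seed = cfg$seed),
  file.path("results", "truth.json"), auto_unbox = TRUE, digits = 10)

message(sprintf(
  "Simulated %d subjects / %d visits (%d blood, %d MRI, %d both).",
  length(unique(visits$subject_id)), nrow(visits), sum(visits$has_blood),
  sum(visits$has_mri), sum(visits$has_blood & visits$has_mri)))
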