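#!/usr/bin/env Rscript
# Stage 3 — multiple imputation by chained equations with weighted
# predictive mean matching: M completed panels, each on its own
# substream of the master seed, with the balancing weights as
# observation weights in every conditional regression.

source(file.path("analysis", "00_config.R"))

visits <- read_stage("visits.csv")
pp <- read_stage("panel_processed.csv")
panel <- as.matrix(pp[, -1]); rownames(panel) <- pp$visit_id
bvis <- visits[match(pp$visit_id, visits$visit_id), ]
w <- read_stage("weights.csv")$weight

spec <- impute_spec(n_imputations = n_imputations, seed = stage_seeds[5])
ens <- generate_ensemble(panel, bvis$sex, w, spec)

imp_dir <- res_dir("imputations")
dir.create(imp_dir, showWarnings = FALSE)
for (m in seq_along(ens$panels))
  write.csv(data.frame(visit_id = pp$visit_id, ens$panels[[m]]),
            file.path(imp_dir, sprintf("imp_%03d.csv", m)),
            row.names = FALSE)
jsonlite::write_json(ens$provenance, file.path(imp_dir, "manifest.json"),
                     auto_unbox = TRUE)
message(sprintf("Wrote %d completed panels to %s.", length(ens$panels),
                imp_dir))
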