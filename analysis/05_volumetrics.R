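#!/usr/bin/env Rscript
# Stage 5 — TIV-normalize the brain volumes, match MRI visits to clock
# values, and tabulate the descriptive correlation structure among age,
# CyClo, sex and the 7 functional-network volume fractions.

source(file.path("analysis", "00_config.R"))

visits <- read_stage("visits.csv")
volumes <- normalize_to_tiv(read_stage("volumes.csv"))
cyclo_tab <- read_stage("cyclo.csv")

m <- match_visits(visits, cyclo_tab, volumes)
message(sprintf(
  "Matched visits: %d MRI, %d with same-visit clock, %d after +/-3 y propagation.",
  m$n_mri, m$n_before, m$n_after))

frac_cols <- paste0(network_names, "_frac")
cm <- correlation_matrix(m$table[, c("age", "cyclo", "sex", frac_cols)])
print(cm)
net_age <- cm$r[frac_cols, "age"]
message(sprintf("Network-age correlations span [%.2f, %.2f]; mean pairwise network correlation %.2f.",
                min(net_age), max(net_age),
                mean(cm$r[frac_cols, frac_cols][upper.tri(diag(7))])))

write_stage(m$table, "matched.csv")
write_stage(data.frame(variable = rownames(cm$r), round(cm$r, 6)),
            "correlation_matrix.csv")
jsonlite::write_json(
  list(p_values = as.data.frame(round(cm$p, 8)),
       n_mri = m$n_mri, n_before = m$n_before, n_after = m$n_after),
  file.path("results", "correlation_pvalues.json"), auto_unbox = TRUE)
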