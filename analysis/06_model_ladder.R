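#!/usr/bin/env Rscript
# Stage 6 — the four-model random-intercept ladder for total GMV:
#   gmv_frac ~ 1, ~ age, ~ age + sex, ~ age + sex + cyclo,
# each with (1 | subject), compared by AIC/BIC and successive
# likelihood-ratio tests.  The question: does the cytokine clock explain
# gray-matter variance beyond calendar age and sex?

source(file.path("analysis", "00_config.R"))

matched <- read_stage("matched.csv")
lad <- build_model_ladder(matched)
print(lad)

message(sprintf(
  "CyClo beyond age + sex: chi2(%d) = %.2f, p = %.2g.",
  lad$lrt["m4_vs_m3", "df"], lad$lrt["m4_vs_m3", "chisq"],
  lad$lrt["m4_vs_m3", "p"]))

tab <- data.frame(model = rownames(lad$table), round(lad$table, 2),
                  lrt_p_vs_previous = c(NA, signif(lad$lrt[, "p"], 4)))
write_stage(tab, "ladder.csv")
jsonlite::write_json(
  list(table = tab, lrt = as.data.frame(lad$lrt),
       best_aic = lad$best_aic, best_bic = lad$best_bic,
       stars = lad$stars, n = lad$n),
  file.path("results", "ladder.json"), auto_unbox = TRUE, digits = 10)
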