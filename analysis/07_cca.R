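#!/usr/bin/env Rscript
# Stage 7 — canonical correlation analysis between the aging factors
# X = (age, cyclo, sex) and the 7 network volume fractions Y, with
# Bartlett and Rao sequential significance tests and redundancy
# coefficients.

source(file.path("analysis", "00_config.R"))

matched <- read_stage("matched.csv")
frac_cols <- paste0(network_names, "_frac")
rows <- complete.cases(matched[, c("age", "cyclo", "sex", frac_cols)])

cca <- fit_cca(matched[rows, c("age", "cyclo", "sex")],
               matched[rows, frac_cols])
tests <- bartlett_sequential_test(cca$cor, cca$n, cca$p, cca$q)
rao <- rao_f_test(cca$cor, cca$n, cca$p, cca$q)
red <- redundancy(cca)

cca_report(cca, tests)
message(sprintf("Redundancy: X|Y = %.3f, Y|X = %.3f.",
                red$total_x_given_y, red$total_y_given_x))

jsonlite::write_json(
  list(n = cca$n, cor = cca$cor, roots = cca$roots,
       xweights = as.data.frame(round(cca$xweights, 6)),
       yweights = as.data.frame(round(cca$yweights, 6)),
       xloadings = as.data.frame(round(cca$xloadings, 6)),
       yloadings = as.data.frame(round(cca$yloadings, 6)),
       bartlett = tests, rao = rao,
       redundancy = red),
  file.path("results", "cca.json"), auto_unbox = TRUE, digits = 10)
message("Wrote results/cca.json")
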