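# Shared settings for the numbered analysis scripts.  Source()d by each
# stage so the whole workflow is driven by one seed and one scale.
library(cytoclock)

master_seed <- 20221202
n_subjects <- 300      # desk-scale cohort; the study design had 554
n_imputations <- 50    # desk-scale ensemble; the study design ran 500

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(dirname(file.path(d, ".")), showWarnings = FALSE,
             recursive = TRUE)
  d
}

stage_seeds <- cytoclock:::derive_seeds(master_seed, 6L, tag = 1L)

read_stage <- function(f) read.csv(file.path("results", f),
                                   stringsAsFactors = FALSE)
write_stage <- function(d, f) {
  dir.create("results", showWarnings = FALSE)
  write.csv(d, file.path("results", f), row.names = FALSE)
}
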