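# Shared settings for the analysis scripts. Each numbered script can be run
# on its own (in order) from the repository root; intermediate artifacts live
# under results/analysis/.

library(metabGA)

BASE_SEED <- 20190319
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

analysis_config <- function() {
  pipeline_config(seed = BASE_SEED, n_train = 5000, n_external = 1500,
                  m_imputations = 10)
}
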