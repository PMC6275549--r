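# Shared configuration for the analysis scripts: one synthetic cohort
# emulating the 52-week ChIP-seq study conditions, regenerated
# deterministically by every stage (cheap, and keeps stages independently
# runnable).

library(k4redist)

COHORT_SEED <- 1
N_SAMPLES <- 24

demo_genome <- function() genome_model()
demo_params <- function() redistribution_params()   # mistarget_slope 0.1
demo_spikein <- function() spikein_params()

demo_cohort <- function() {
  simulate_cohort(demo_genome(), cohort_design(N_SAMPLES, seed = COHORT_SEED),
                  demo_params(), demo_spikein(), seed = COHORT_SEED)
}

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)

save_figure <- function(plot, name, width = 6, height = 4) {
  # figures are advisory outputs; never inputs to later stages
  tryCatch(
    ggplot2::ggsave(file.path("scratch/figures", name), plot,
                    width = width, height = height, dpi = 120),
    error = function(e) message("figure skipped (", conditionMessage(e), ")"))
}
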