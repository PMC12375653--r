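# Shared configuration for the numbered analysis scripts. Everything
# downstream is a pure function of this configuration: scripts regenerate
# the synthetic scenes deterministically instead of re-reading bulky cubes.

library(needlespec)

an <- new.env()
an$seed <- 1L
an$out <- "results/analysis"
an$config <- pipeline_config(
  n_samples = 120L,
  scene = scene_config(height = 64, width = 64, stroke_count = 40),
  n_feat = 8L,
  train = train_config(iterations = 1000L, batch_size = 2L,
                       patch = 32L, stride = 16L),
  recon_train_images = 24L,
  models = "plsr",
  seed = an$seed
)
dir.create(an$out, recursive = TRUE, showWarnings = FALSE)

# the scenes exactly as the pipeline's simulate stage draws them
an$dataset <- function() {
  scene <- an$config$scene
  scene$seed <- (an$seed + 101L) %% .Machine$integer.max  # simulate-stage seed
  generate_dataset(an$config$n_samples, scene)
}
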