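# shared fixtures: tiny phantoms and cached objects, built in code

tiny_phantom_config <- function(...) {
  cfg <- read_phantom_config(
    system.file("extdata", "phantom_small.yaml", package = "abdomenseg"))
  over <- list(...)
  for (n in names(over)) cfg[[n]] <- over[[n]]
  do.call(phantom_config, cfg[setdiff(names(cfg), character(0))])
}

small_preprocess_config <- function(...) {
  cfg <- read_preprocess_config(
    system.file("extdata", "preprocess_small.yaml", package = "abdomenseg"),
    ...)
  cfg
}

# cache one clean (no bias, no noise) and one default phantom per session
phantom_cache <- new.env()

clean_phantom <- function() {
  if (is.null(phantom_cache$clean))
    phantom_cache$clean <- generate_phantom(
      tiny_phantom_config(bias_amplitude = 0, noise_sigma = 0, seed = 5L))
  phantom_cache$clean
}

default_phantom <- function() {
  if (is.null(phantom_cache$default))
    phantom_cache$default <- generate_phantom(tiny_phantom_config(seed = 6L))
  phantom_cache$default
}

# tiny standardized study + labels for training/inference tests
tiny_training_pair <- function() {
  if (is.null(phantom_cache$pair)) {
    cfg <- small_preprocess_config()
    ph <- default_phantom()
    std <- preprocess_study(ph$study, cfg)
    lab <- preprocess_labelmap(ph$labels, ph$labels_affine, cfg)
    phantom_cache$pair <- list(study = std, labels = lab$volume,
                               affine = lab$affine)
  }
  phantom_cache$pair
}
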