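# Desk-scale parameter-recovery runs shared across accuracy tests.
# Conditions (fixed; see the methods vignette): tiny backbone at 256 px,
# z in [-5, +5] um on a 0.25 um grid, 3-5 particles per scene, 48 scenes
# split 0.7/0.3, 60 epochs with batch 2 and depth loss weight 5, three
# seeds.  Trained lazily once per test session and cached.
recovery_seeds <- c(101L, 202L, 303L)

recovery_conditions <- function(seed) {
  optical <- optical_config(z_min = -5, z_max = 5, z_step = 0.25,
                            noise_sd = 0.02, seed = seed)
  classes <- default_bead_classes()
  list(optical = optical, classes = classes,
       library = build_calibration_library(classes, optical))
}

recovery_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    runs <- lapply(recovery_seeds, function(seed) {
      cond <- recovery_conditions(seed)
      dir <- file.path(tempdir(), sprintf("recovery_ds_%d", seed))
      if (!dir.exists(dir))
        build_dataset(cond$library, n_images = 48, out_dir = dir,
                      size_range = c(256, 256),
                      n_particles_range = c(3, 5),
                      split_fractions = c(train = 0.7, eval = 0.3),
                      seed = seed)
      man <- read_manifest(dir)
      res <- train(man, train_config(epochs = 60, seed = seed,
                                     batch_size = 2,
                                     loss = loss_weights(depth = 5)))
      report <- evaluate_model(res$net, man, "eval")
      list(seed = seed, net = res$net, manifest = man, report = report,
           conditions = cond)
    })
    cache <<- runs
    runs
  }
})
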