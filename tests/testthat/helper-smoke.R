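# Shared end-to-end fixtures, built lazily and memoized across test files.
# Study conditions: 2 Mb uniform genome, 300 planted sites of an 8 bp motif
# (info_strength 0.9), Gaussian peaks. Smoke-scale training uses a slimmed
# encoder/decoder, lr 3e-3, batch 8 and fixed small epoch counts (see the
# methods vignette for the rationale behind these problem sizes).

.smoke <- new.env(parent = emptyenv())

smoke_memo <- function(name, build) {
  if (is.null(.smoke[[name]])) .smoke[[name]] <- build()
  .smoke[[name]]
}

smoke_model_config <- function(task, n_filters = 64L,
                               L = if (task == "binary") 500L else 1000L) {
  model_config(task = task, input_length = L,
               qconv = qconv_config(n_qubits = 4, k_target = 16, n_layers = 3),
               channels = c(as.integer(n_filters), 24L, 32L),
               kernels = c(conv2 = 7L, conv3 = 5L, bottleneck = 5L,
                           decoder = 5L),
               dec_channels = 16L)
}

smoke_train_config <- function(seed) {
  train_config(lr = 3e-3, batch_size = 8, seed = seed, patience = 38)
}

smoke_sim <- function() smoke_memo("sim", function() {
  simulate_dataset(sim_config(seed = 101))
})

smoke_signal_dataset <- function() smoke_memo("ds_signal", function() {
  sim <- smoke_sim()
  build_dataset(sim$genome, sim$peaks, sim$signal, task = "signal",
                seed = 102)
})

smoke_binary_dataset <- function() smoke_memo("ds_binary", function() {
  sim <- smoke_sim()
  build_dataset(sim$genome, sim$peaks, sim$signal, task = "binary",
                pcm = 100 * sim$config$primary_pwm, length = 500, seed = 103)
})

# positive test-split examples of a fit, for motif extraction
smoke_test_positives <- function(fit, ds) {
  fit$split$test[vapply(fit$split$test, function(i) {
    ds$examples[[i]]$is_positive
  }, logical(1))]
}

# the default-width (64-filter) binary model, smoke-trained; shared by the
# motif shape contract and the end-to-end checks
smoke_binary_fit <- function(epochs = 6L) smoke_memo("binary_fit", function() {
  ds <- smoke_binary_dataset()
  set.seed(410)
  m <- build_model(smoke_model_config("binary"))
  train(m, ds, smoke_train_config(510), epochs = epochs, restore_best = FALSE)
})

smoke_binary_pfms <- function() smoke_memo("binary_pfms", function() {
  ds <- smoke_binary_dataset()
  fit <- smoke_binary_fit()
  extract_filter_pfms(fit$model, ds$examples[smoke_test_positives(fit, ds)])
})

# the signal variant, smoke-trained (end-to-end contract)
smoke_signal_fit <- function(epochs = 3L) smoke_memo("signal_fit", function() {
  ds <- smoke_signal_dataset()
  set.seed(420)
  m <- build_model(smoke_model_config("signal"))
  train(m, ds, smoke_train_config(520), epochs = epochs, restore_best = FALSE)
})

# five independent training trials of the binary variant at 16 filters; each
# trial pairs the trained model with a matched randomly initialized model and
# records the per-PFM information content of both filter banks
smoke_ic_trials <- function(n_trials = 5L, epochs = 6L) {
  smoke_memo("ic_trials", function() {
    ds <- smoke_binary_dataset()
    trials <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      set.seed(400L + t)
      m <- build_model(smoke_model_config("binary", n_filters = 16L))
      fit <- train(m, ds, smoke_train_config(500L + t), epochs = epochs,
                   restore_best = FALSE)
      pos <- smoke_test_positives(fit, ds)
      pfms_tr <- extract_filter_pfms(fit$model, ds$examples[pos])
      set.seed(600L + t)
      m_rand <- build_model(smoke_model_config("binary", n_filters = 16L))
      pfms_rd <- extract_filter_pfms(m_rand, ds$examples[pos])
      trials[[t]] <- list(
        ic_trained = vapply(pfms_tr, information_content, numeric(1)),
        ic_random = vapply(pfms_rd, information_content, numeric(1)),
        best_corr = max(vapply(pfms_tr, function(p) {
          motif_match_score(p, smoke_sim()$config$primary_pwm)$score
        }, numeric(1))))
    }
    trials
  })
}

# cofactor simulation for the spacing analysis (no training involved)
smoke_cofactor_sim <- function() smoke_memo("cofactor_sim", function() {
  simulate_dataset(sim_config(
    primary_pwm = pwm_from_consensus("TGACTCAG", 0.95),
    cofactor_pwm = pwm_from_consensus("CCACGTGG", 0.95),
    cofactor_offset = 40L, seed = 115))
})
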