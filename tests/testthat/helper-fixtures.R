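# Shared fixtures, generated in code at test time.

# small two-syllable song model for fast feature/controller tests
tiny_song_model <- function(jitter = 0, noise_floor_db = -60) {
  song_model(
    syllables = list(
      syllable_template("a", 80, 520, n_harmonics = 8, amplitude_db = -10,
                        entropy_target = 0.05, gap_ms = 30),
      syllable_template("b", 60, 900, n_harmonics = 5, amplitude_db = -9,
                        entropy_target = 0.30, gap_ms = 40)),
    motif_order = c("a", "b"),
    tempo_jitter_sd_ms = jitter, noise_floor_db = noise_floor_db,
    sample_rate_hz = 22050)
}

# classifier trained once per test run on the default song model
trained_default_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- generate_labeled_events(default_song_model(), 30, seed = 42,
                                    cage_noise_events = 10)
      cache <<- train_syllable_classifier(
        tr$summaries[, songgate:::.feature_cols], tr$labels, seed = 43)
    }
    cache
  }
})

# two well-separated Gaussian feature clouds
gaussian_clouds <- function(n_per_class = 100, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep / sqrt(d)), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = as.data.frame(x),
       labels = rep(c("p", "q"), each = n_per_class))
}
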