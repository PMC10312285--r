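# Shared small fixtures, built in code. Sizes are kept small so the whole
# unit suite stays fast; the acceptance tests build their own larger inputs.

small_spec <- function(n = 12, seed = 7, subjects = 3, duration = 300,
                       tr = 0.72) {
  synthetic_spec(n_regions = n, seed = seed, subjects = subjects,
                 duration = duration, tr = tr)
}

small_bundle <- function(...) make_connectome(small_spec(...))

small_map <- function(bundle, seed = 8, smoothness = 20) {
  make_heterogeneity_map(bundle$coords, smoothness, seed = seed)
}

# a deterministic multi-tone matrix: row i is a sinusoid at freqs[i] Hz
tone_matrix <- function(freqs, tr = 0.72, n_samples = 500, amp = 1) {
  t <- (seq_len(n_samples) - 1) * tr
  do.call(rbind, lapply(freqs, function(f) amp * cos(2 * pi * f * t)))
}
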