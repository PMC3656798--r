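# Shared fixtures: the 2x2 walk-through model and a few construction helpers.

we_model <- function() obs_model(obs_var = 1, prior_mean = 0, prior_var = 1)

# run sample_table repeatedly on fresh copies of a state and tabulate where
# customer (j, i) ends up (by dish data signature, label-invariant)
reseat_frequencies <- function(j, i, state, data, model, hyper, ndraw, mode = "direct") {
  out <- character(ndraw)
  for (r in seq_len(ndraw)) {
    s2 <- sample_table(j, i, state, data, model, hyper, mode)
    out[r] <- paste0("t", s2$phi[j, i] %in% state$phi[j, ],
                     ".", s2$phi[j, i])
  }
  table(out) / ndraw
}

# random partition of n items into at most k labels
random_partition <- function(n, k) sample.int(k, n, replace = TRUE)
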