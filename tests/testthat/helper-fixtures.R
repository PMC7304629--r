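# shared fixtures built in code

# homopolymer sequence of one residue letter
poly <- function(letter, n) protein_sequence(strrep(letter, n),
                                             id = paste0("poly", letter))

# flat disorder profile
flat_profile <- function(seq, score = 0.5) {
  disorder_profile(rep(score, seq$n), id = seq$id)
}

# a fixed toy parameter set (not fitted): lambda, gamma chosen by hand
toy_params <- function(lambda = c(2, -1, 0.5), gamma = -0.3) {
  structure(list(lambda = lambda, gamma = gamma,
                 feature_config = default_feature_config()),
            class = "binding_params")
}

# random standard-alphabet sequence
random_seq <- function(n, seed, id = "rand") {
  set.seed(seed)
  protein_sequence(paste(sample(names(kyte_doolittle()), n, replace = TRUE),
                         collapse = ""), id = id)
}

# brute-force window count oracle: all (start, length) pairs containing i
brute_window_count <- function(i, n, min_len = 5, max_len = 9) {
  cnt <- 0L
  for (L in min_len:max_len)
    for (st in 1:max(1, n - L + 1))
      if (st + L - 1 <= n && st <= i && i <= st + L - 1) cnt <- cnt + 1L
  cnt
}
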