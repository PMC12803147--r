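# Small fixtures built in code, shared across test files.

tiny_basis <- function(n_units = 3, n_channels = 4, nt = 31, n_pcs = 5,
                       max_delay = 5, seed = 42, ...) {
  make_synthetic_basis(n_units = n_units, n_channels = n_channels, nt = nt,
                       n_pcs = n_pcs, max_delay = max_delay, seed = seed, ...)
}

# deterministic pseudo-Poisson train with a refractory gap
fixture_train <- function(n, duration, rate = 30000, min_gap = 60, seed = 1) {
  withr::with_seed(seed, {
    x <- sort(sample.int(duration, n)) - 1
    x[c(TRUE, diff(x) > min_gap)]
  })
}

fixture_trains <- function(counts, duration = 30000 * 30, rate = 30000,
                           seed = 1, min_gap = 60) {
  lists <- lapply(seq_along(counts), function(i) {
    fixture_train(counts[i], duration, rate, min_gap, seed = seed + i)
  })
  spike_trains(rep(seq_along(counts), lengths(lists)), unlist(lists),
               duration, rate)
}

# independent plain-R MAD oracle
oracle_mad <- function(x) median(abs(x - median(x))) / 0.6745
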