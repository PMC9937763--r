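# Small phantom fixtures built in code; seeds fixed so every run sees the
# same images.

noiseless_config <- function(seed = 7L, ...) {
  phantom_config(speckle_sigma = 0, seed = seed, ...)
}

# independent single-lesion scans with diameters drawn from the default range
make_scan_pairs <- function(n, seed0, sigma = 0.2) {
  lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    d <- sample(24:60, 1)
    generate_bscan(phantom_config(speckle_sigma = sigma, seed = seed0 + i),
                   diameter = d, seed = seed0 + i)
  })
}

# a tiny network that keeps unit tests fast
tiny_net_args <- list(conv_filters = c(4L, 8L), fc_units = 32L)
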