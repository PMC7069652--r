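# Shared fixture builders: everything is generated in code at test time.

tiny_grid <- function(n = 6, lo = 500, hi = 600) seq(lo, hi, length.out = n)

random_cube <- function(nx = 4, ny = 5, nl = 6, kind = "counts", seed = 1,
                        scale = 1, offset = 0) {
  set.seed(seed)
  hypercube(array(stats::runif(nx * ny * nl) * scale + offset, c(nx, ny, nl)),
            tiny_grid(nl), kind)
}

# Small library + profile shared by correction/synthesis tests.
tiny_library <- function(n_channels = 60) spectrum_library(n_channels)

tiny_profile <- function(lib = tiny_library()) {
  source_profile(lib$source, lib$wavelengths, 800)
}

# Four well-separated Gaussian blobs in p dims: list(x, y) for classifiers.
blob_data <- function(n_per = 60, p = 10, sep = 6, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(4 * p), 4, p) * sep
  x <- do.call(rbind, lapply(1:4, function(k)
    matrix(stats::rnorm(n_per * p, sd = sd), n_per, p) +
      rep(centers[k, ], each = n_per)))
  list(x = x, y = rep(0:3, each = n_per))
}
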