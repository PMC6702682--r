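# shared fixtures, all generated in code

# small random tensor with reproducible entries
rand_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}

# unit-interval harmonic grids for index-space tensor tests
unit_grids <- function(sizes) {
  lapply(sizes, function(n) build_dvr("harmonic", n, c(-1, 1)))
}

# the anharmonic (Morse) reference toy used for decomposition-error studies
morse_toy <- function(seed = 0) toy_reference(seed, f = 3L, morse = TRUE)

# a mock external program echoing a fixed energy
mock_backend <- function(energy = 42.5, lines = sprintf("ENERGY = %.10g", energy)) {
  path <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", paste("echo", shQuote(lines))), path)
  Sys.chmod(path, "0755")
  external_adapter(list(command = path, energy_pattern = "ENERGY = ([-0-9.eE+]+)"))
}
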