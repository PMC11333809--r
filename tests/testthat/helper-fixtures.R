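# Shared lazily-built fixtures: phantoms are generated once per test run
# and reused across files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default study conditions (PSF 4.1 mm, noise on)
phantom_default <- function() {
  fixture("ph_default", generate_phantom(phantom_spec(seed = 8)))
}

# PSF on, noise off: isolates the partial-volume/spillover mechanism
phantom_clean <- function() {
  fixture("ph_clean", generate_phantom(phantom_spec(seed = 8, noise_scale = 0)))
}

# no degradation at all: voxel curves are exactly the model curves
phantom_ideal <- function() {
  fixture("ph_ideal",
          generate_phantom(phantom_spec(seed = 8, noise_scale = 0,
                                        psf_fwhm_mm = 0)))
}

rel_rmse <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
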