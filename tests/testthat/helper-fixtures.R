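# Small shared fixtures: a coarse phantom grid covering the same anatomy as
# the default grid, and cached phantoms/cohorts reused across tests.

test_shape <- c(48L, 36L, 94L)
test_spacing <- c(512 / 48, 384 / 36, 2000 / 94)

tiny_shape <- c(32L, 24L, 64L)
tiny_spacing <- c(512 / 32, 384 / 24, 2000 / 64)

.fixture_env <- new.env()

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

test_reference <- function() fixture("ref", function()
  reference_phantom(test_shape, test_spacing))

test_ref_phantom <- function() fixture("ref_phantom", function()
  generate_phantom(phantom_spec(shape = test_shape, spacing = test_spacing,
                                noise_sd = 0.02), seed = 1))

small_cohort <- function() fixture("small_cohort", function()
  generate_cohort(40, 40, default_calibration(), seed = 7))

test_reference_tiny <- function() fixture("ref_tiny", function()
  reference_phantom(tiny_shape, tiny_spacing))
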