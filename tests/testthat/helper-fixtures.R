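# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fx_fs <- 2048

# one low-HF and one high-HF channel model
fx_models <- function() fixture("models", function()
  synthetic_channel_models(1, 1, fx_fs))

fx_low_model <- function() fx_models()[[1]]
fx_high_model <- function() fx_models()[[2]]

fx_dictionary <- function() fixture("dict", function()
  make_default_dictionary(fx_fs, seed = derive_seed(1, "dict")))

# a 60 s event-free background of the low-HF channel
fx_background <- function() fixture("bkg", function()
  synthesize_background(fx_low_model(), 60, seed = 404))

# classic well-conditioned AR(4) benchmark process (resonances at moderate
# normalized frequencies); used for estimation-accuracy oracles
fx_ar4 <- function() {
  structure(list(channel_id = "ar4", order = 4L,
                 coeffs = c(-2.2137, 2.9403, -2.1697, 0.9606),
                 gain = 1, fs = fx_fs),
            class = "ar_background_model")
}
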