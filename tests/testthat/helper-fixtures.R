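# Shared fixtures, built once per session and cached: the synthetic
# spectrum/absorptivity pair, the default geometry, and the LVRPA table on
# the canonical ferric grid.

pf_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(key, build) {
    if (!exists(key, envir = cache)) assign(key, build(), envir = cache)
    get(key, envir = cache)
  }
})
if (exists(".pf_fixture_cache", envir = globalenv(), inherits = FALSE)) {
  pf_cache <- get(".pf_fixture_cache", envir = globalenv())
} else {
  assign(".pf_fixture_cache", pf_cache, envir = globalenv())
}

fix_geometry <- function() pf_cache("geometry", default_geometry)
fix_spectrum <- function() pf_cache("spectrum", synthetic_lamp_spectrum)
fix_absorptivity <- function() pf_cache("absorptivity",
                                        synthetic_absorptivity_table)
fix_lvrpa_table <- function() pf_cache("lvrpa_table", function()
  build_lvrpa_table(c(0, 2.5, 5, 7.5, 10), fix_geometry(), fix_spectrum(),
                    fix_absorptivity()))
fix_context <- function() pf_cache("context", function()
  model_context(canonical_design(), fix_geometry(), fix_lvrpa_table()))

# noiseless 18-run campaign at the default constants
fix_noiseless_campaign <- function() pf_cache("noiseless", function()
  generate_campaign(canonical_design(), kinetic_params(), fix_geometry(),
                    fix_lvrpa_table(),
                    noise_model = c(PCT = 0, H2O2 = 0, Fe2 = 0, FeTOT = 0),
                    seed = 1))

zero_noise <- c(PCT = 0, H2O2 = 0, Fe2 = 0, FeTOT = 0, TOC = 0)

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}
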