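# Expensive shared fixtures, built once per test run.
# Reduced study scale: 60^3 grid, dx = 0.25, obstacle R = 2.5.
.fixtures <- new.env(parent = emptyenv())

study_params <- function() model_params(grid = c(60, 60, 60))

study_domain <- function(params = study_params()) {
  if (is.null(.fixtures$domain)) {
    .fixtures$domain <- build_phase_field(params, radius = 2.5)
  }
  .fixtures$domain
}

# Pinned scroll relaxed for 30 time units, with its relaxation-probe
# frequency estimate attached.  Reused by the stability, unpinning and
# removal tests.
cached_pinned <- function() {
  if (is.null(.fixtures$pinned)) {
    p <- study_params()
    .fixtures$pinned <- pinned_scroll_init(p, study_domain(p),
                                           relaxation_time = 30)
  }
  .fixtures$pinned
}
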