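# Shared reference simulation for the acceptance checks: the default baking
# scenario (Table-1 constants, fitted transitions, 180 degC program) on the
# coarse 2-D axisymmetric mesh. Computed once per test session on demand.
.ref_env <- new.env(parent = emptyenv())

reference_run <- function() {
  if (is.null(.ref_env$res)) {
    .ref_env$res <- run_paper_scenario(mode = "axisym2d", mesh_level = 2)
  }
  .ref_env$res
}
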