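# Shared fixtures. Everything is generated in code at test time; the heavy
# default-cohort ablation is computed once per test run and shared across
# the acceptance blocks through a session cache.

tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(head_radii = c(40, 40, 40), in_plane_size = c(32L, 32L),
         n_slices = 10L, thick_factor = 5L, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

tiny_model <- function(seed = 1L) model_config(seed = seed)

# A small cohort on disk for I/O and CLI tests.
tiny_cohort <- function(dir, nL = 2L, nU = 2L, nT = 1L, seed = 5L) {
  make_cohort(nL, nU, nT, seed = seed, out_dir = dir,
              base_spec = tiny_spec())
}

.thinseg_test_cache <- new.env(parent = emptyenv())

# Default-conditions ablation (the study conditions of the package): one
# cohort from the default run config, Exp 1/2/3 with shared seeds. Built
# lazily, once.
default_ablation <- function() {
  if (!is.null(.thinseg_test_cache$ablation))
    return(.thinseg_test_cache$ablation)
  cfg <- default_run_config()
  dir <- file.path(tempdir(), "thinseg-default-cohort")
  mpath <- cmd_generate(out_dir = dir)
  ob <- thinseg:::config_objects(cfg)
  ab <- run_ablation(mpath, ob$model, ob$loss, ob$control)
  .thinseg_test_cache$ablation <- list(ablation = ab, manifest = mpath)
  .thinseg_test_cache$ablation
}
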