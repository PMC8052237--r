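# shared fixtures, built once per test run
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_phantom <- function() memo("phantom", build_phantom(phantom_spec()))

default_air <- function() memo("air", threshold_air(default_phantom()))

default_domain <- function() memo("domain", {
  vol <- default_phantom()
  pd <- phantom_probe_defaults(attr(vol, "phantom_spec"))
  extract_airspace(vol, sphere_diam_mm = pd$sphere_diam_mm,
                   cuboid_dims_mm = pd$cuboid_dims_mm)
})

# the full five-subject synthetic study, shared by the acceptance tests
acceptance_run <- function() memo("acceptance_run", {
  run_pipeline(run_config(seed = 1), quiet = TRUE)
})

duct_fine <- function() memo("duct16",
  duct_benchmark(radius_vox = 16, u_plug = 0.02))
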