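# Shared, lazily built fixtures. The expensive objects (reference FI curve,
# constructed reduction) are built once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

ref_params <- function() wbm_params()

ref_fi <- function() fixture("fi_ref", function()
  ramp_fi(wbm_model(ref_params()), 0, 1))

ref_reduction <- function() fixture("reduction", function()
  rinzel_reduce(ref_params()))

ref_pl2d <- function() fixture("pl2d", function()
  pl2d_construct(ref_params(), fit = ref_reduction(), fi_ref = ref_fi()))

# a tiny helper for property loops
expect_all_true <- function(x, info = NULL) expect_true(all(x), info = info)
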