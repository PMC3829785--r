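# Shared fixtures for the test suite.

ref <- reference_case()

# dimensionless numbers of the reference case under both viscosity policies
ref_dims <- function(policy = "apparent") {
  dimensionless_set(ref$fluid, ref$setup, ref$flow,
                    viscosity_policy = policy, shear_rate = ref$shear_rate)
}

# random physically plausible input draws for property tests
draw_inputs <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    sigma = runif(n, 0.02, 0.075),
    rho = runif(n, 912, 1151),
    f = runif(n, 20e3, 130e3),
    P = runif(n, 1, 50),
    A = runif(n, 5e-4, 5e-3),
    C = runif(n, 1400, 1600),
    Q = runif(n, 5e-9, 5e-7),
    mu = runif(n, 0.001, 0.5),
    n_idx = runif(n, 0.5, 1)
  )
}
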