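# Shared fixtures and independent oracles for the test suite.

# Random positive Leslie parameter sets, rates ~ Uniform(0.05, 2).
random_leslie_set <- function(n, seed = 7111) {
  set.seed(seed)
  replicate(n, {
    v <- runif(5, 0.05, 2)
    leslie_params(r1 = v[1], r2 = v[2], c1 = v[3], c2 = v[4], b = v[5])
  }, simplify = FALSE)
}

# Random points on the k-simplex.
random_simplex_point <- function(k) {
  u <- runif(k)
  u / sum(u)
}

# Brute-force numeric determinant, independent of the closed forms.
numeric_det <- function(J) J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]

# Endpoint of dx/dt = -x integrated with the package, vs the closed form.
decay_endpoint_error <- function(method, dt) {
  cfg <- integrator_config(method = method, dt = dt, t_end = 1)
  tr <- integrate_model(function(t, x) -x, c(x = 1), cfg)
  abs(tr[nrow(tr), "x"] - exp(-1))
}
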