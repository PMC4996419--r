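# shared fixtures: the default parameter set and small utilities

default_params <- function(a = 0) cf_params(a = a)

# independent finite-difference Jacobian (central differences)
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (cf_rhs(up, params) - cf_rhs(dn, params)) / (2 * h)
  }
  J
}

# norm of the model RHS at a state
rhs_norm <- function(state, params) sqrt(sum(cf_rhs(pmax(state, 0), params)^2))
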