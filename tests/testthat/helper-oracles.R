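# Independent classical-scheme oracles used to check the beta = 1 reductions.
# These transcribe the textbook formulas directly and stay independent of the
# package's stepping code.

forward_euler_oracle <- function(rhs, t, u, v, h) {
  c(u = u + h * rhs$f1(t, u, v),
    v = v + h * rhs$f2(t, u, v))
}

rk2_midpoint_oracle <- function(rhs, t, u, v, h) {
  k1u <- rhs$f1(t, u, v)
  k1v <- rhs$f2(t, u, v)
  c(u = u + h * rhs$f1(t + h / 2, u + h / 2 * k1u, v + h / 2 * k1v),
    v = v + h * rhs$f2(t + h / 2, u + h / 2 * k1u, v + h / 2 * k1v))
}

random_lv_inputs <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(t = runif(n, 0, 5), u = runif(n, 0.05, 2),
             v = runif(n, 0.05, 2), h = runif(n, 0.01, 0.3))
}
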