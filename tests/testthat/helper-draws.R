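# Random oscillator parameter draws avoiding the critical-damping
# neighbourhood: zeta in (0, 0.95) or (1.05, 5).
draw_oscillator_case <- function() {
  m <- runif(1, 0.5, 3)
  k <- runif(1, 0.5, 3)
  zeta <- if (runif(1) < 0.5) runif(1, 0.05, 0.95) else runif(1, 1.05, 5)
  list(params = oscillator_params(m, k, 2 * zeta * sqrt(k * m)),
       x_init = runif(1, 0.2, 2) * sample(c(-1, 1), 1),
       v_init = runif(1, -2, 2))
}
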