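# reference parameter sets and small scheme builders used across tests

# star-scheme rates of the bursting reference condition (s^-1)
ref_rates <- c(alpha_o = 1500, alpha_c = 27,
               beta_o = 22500, beta_c = 600,
               gamma_o = 127500, gamma_c = 30000)

ref_params <- function() do.call(scheme1_params, as.list(ref_rates))

ref_scheme <- function(i_open = 10) as_gating_scheme(ref_params(), i_open)

# simple two-state C <-> O scheme
two_state <- function(k_open, k_close, i_open = 10) {
  gating_scheme(
    states = data.frame(label = c("C", "O"),
                        class = c("closed", "open"),
                        amplitude = c(0, i_open)),
    rates = data.frame(from = c("C", "O"), to = c("O", "C"),
                       k0 = c(k_open, k_close), z = 0)
  )
}

# random star-scheme parameter draws (log-uniform rates)
random_scheme1 <- function() {
  r <- 10^runif(6, 0, 5)
  scheme1_params(r[1], r[2], r[3], r[4], r[5], r[6])
}

# independent steady-state oracle: null space of the full rate matrix,
# computed by brute-force linear solve on the transposed generator
null_space_open_probability <- function(p, i_open = 10, V = 0) {
  sch <- as_gating_scheme(p, i_open, V)
  Q <- scheme_rate_matrix(sch, V)
  A <- rbind(t(Q), 1)
  pi <- qr.solve(A, c(0, 0, 0, 0, 1))
  unname(pi[1]) # state O is first
}

# event table built directly from vectors
make_events <- function(class, duration, t0 = 0) {
  tibble::tibble(class = class,
                 start = t0 + cumsum(c(0, duration[-length(duration)])),
                 duration = duration)
}
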