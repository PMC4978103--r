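# shared fixtures for the kinetics tests, built in code

sham_truth <- function() default_truth_from_tables()$sham
burn_truth <- function() default_truth_from_tables()$burn

sham_protocol <- function() infusion_protocol(infusion_rate = 1.0)
burn_protocol <- function() infusion_protocol(infusion_rate = 0.85)

# one noiseless animal per group, exact forward model
noiseless_animal <- function(group = "sham") {
  tr <- default_truth_from_tables()[[group]]
  simulate_animal(paste0(group, "_x"), group, tr,
                  infusion_protocol(infusion_rate = tr$infusion_rate))
}

# independent one-pool oracle for plasma enrichment: numerically integrate
# tracer mass dT/dt = i*Ei - lambda*T in a pool of size P = (Q/60 + i)/lambda,
# primed with a bolus of prime_fraction * (ideal prime)
plasma_ode_oracle <- function(Q, i, Ei, t, lambda, prime_fraction,
                              dt = 0.001) {
  R <- Q / 60 + i                      # total appearance, umol/kg/min
  P <- R / lambda                      # pool size implied by lambda
  T_ss <- i * Ei / lambda              # steady-state tracer mass
  Tr <- prime_fraction * T_ss          # priming bolus
  steps <- seq(0, t, by = dt)
  for (s in steps[-1]) Tr <- Tr + dt * (i * Ei - lambda * Tr)
  Tr / P
}

# independent oracle for organ labeling: integrate dE/dt = k (Eo - E)
organ_ode_oracle <- function(k_per_day, Eo, t_min, dt = 0.01) {
  k <- k_per_day / 1440
  E <- 0
  for (s in seq(dt, t_min, by = dt)) E <- E + dt * k * (Eo - E)
  E
}
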