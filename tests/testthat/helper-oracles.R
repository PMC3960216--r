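# Independent oracles the implementation is checked against.

# numerical quadrature of dr / (4 pi D r^2) over a spherical shell
quadrature_resistance <- function(r_in, r_out, D) {
  if (r_in == r_out) return(0)
  stats::integrate(function(r) 1 / (4 * pi * D * r^2), r_in, r_out,
                   rel.tol = 1e-12)$value
}

# fractional release from a homogeneous sphere with uniform initial
# loading and a perfect-sink surface, as a function of dimensionless time
# tau = D * t / R^2 (truncated eigenfunction series; short-time closed
# form below the series' comfortable range)
crank_fraction <- function(tau, terms = 2000) {
  vapply(tau, function(x) {
    if (x <= 0) return(0)
    if (x < 1e-3) return(6 * sqrt(x / pi) - 3 * x)
    n <- seq_len(terms)
    1 - (6 / pi^2) * sum(exp(-n^2 * pi^2 * x) / n^2)
  }, numeric(1))
}

# step-by-step mass-balance simulation of aliquot-and-replenish sampling:
# walks the vessel through every withdraw/replenish cycle and books the
# release implied by each measured concentration
simulate_sampling_ledger <- function(concentrations, V_total, V_aliquot) {
  cum <- numeric(length(concentrations))
  mass_after_sampling <- 0  # drug left in the vessel after each cycle
  removed_total <- 0        # drug carried away by aliquots so far
  for (i in seq_along(concentrations)) {
    mass_now <- V_total * concentrations[i]
    release_since_last <- mass_now - mass_after_sampling
    cum[i] <- removed_total + mass_after_sampling + release_since_last
    removed <- V_aliquot * concentrations[i]
    removed_total <- removed_total + removed
    mass_after_sampling <- mass_now - removed
  }
  cum
}

# default nanoparticle-like geometry used across tests (um, h)
nano_sphere <- function(...) {
  args <- utils::modifyList(
    list(r2 = 0.165, t = 0.02, D1 = 2e-4, D2 = 2e-4, K = 0.02),
    list(...)
  )
  do.call(composite_sphere, args)
}
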