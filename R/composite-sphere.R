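#' Geometry and transport parameters of a PEM-coated particle
#'
#' Constructs a `composite_sphere`, the central description of a coated
#' particle: a spherical polymer core of radius `r2` carrying the drug,
#' wrapped in a polyelectrolyte-multilayer (PEM) shell of thickness `t`
#' whose outer radius is `r3 = r2 + t`. Transport is characterised by the
#' core diffusivity `D1`, the shell diffusivity `D2` and the shell/core
#' partition coefficient `K` (equilibrium concentration ratio at the
#' interface; the shell permeability scales with `K * D2`).
#'
#' The radius `r1 < r2` marks an arbitrary interior sampling radius from
#' which the core-side diffusional resistance is accumulated. Because the
#' steady-state retardation ratio depends on `r1`, it is an explicit
#' parameter (default `r2 / 2`) and is carried along with every result
#' rather than hidden. All lengths must be given in one consistent unit,
#' and diffusivities in (that unit)^2 per time unit.
#'
#' @param r2 Core (particle) outer radius, > 0.
#' @param t PEM shell thickness, >= 0 in the same unit as `r2`.
#' @param D1 Core diffusivity, >= 0 (0 means an impermeable core interior,
#'   i.e. the capsule limit).
#' @param D2 Shell diffusivity, > 0.
#' @param K Shell/core partition coefficient, > 0. Default 1.
#' @param r1 Inner sampling radius, 0 < `r1` < `r2`. Default `r2 / 2`.
#' @return An object of class `composite_sphere`: a list with fields
#'   `r1`, `r2`, `t`, `r3`, `D1`, `D2`, `K`.
#' @examples
#' sp <- composite_sphere(r2 = 0.165, t = 0.02, D1 = 1e-3, D2 = 1e-3, K = 0.01)
#' retardation_ratio(sp)
#' @export
composite_sphere <- function(r2, t, D1, D2, K = 1, r1 = r2 / 2) {
  stop_if_bad <- function(ok, param, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", param, msg), call. = FALSE)
  }
  for (nm in c("r1", "r2", "t", "D1", "D2", "K")) {
    v <- get(nm)
    stop_if_bad(is.numeric(v) && length(v) == 1L && is.finite(v), nm,
                "must be a single finite number")
  }
  stop_if_bad(r2 > 0, "r2", "core radius must be > 0")
  stop_if_bad(t >= 0, "t", "shell thickness must be >= 0")
  stop_if_bad(r1 > 0 && r1 < r2, "r1",
              sprintf("sampling radius must satisfy 0 < r1 < r2 (= %g)", r2))
  stop_if_bad(D1 >= 0, "D1", "core diffusivity must be >= 0")
  stop_if_bad(D2 > 0, "D2", "shell diffusivity must be > 0")
  stop_if_bad(K > 0, "K", "partition coefficient must be > 0")
  structure(
    list(r1 = r1, r2 = r2, t = t, r3 = r2 + t, D1 = D1, D2 = D2, K = K),
    class = "composite_sphere"
  )
}

#' @export
print.composite_sphere <- function(x, ...) {
  cat("Composite sphere (core + PEM shell)\n")
  cat(sprintf("  radii      : r1 = %g, r2 = %g, r3 = r2 + t = %g (t = %g)\n",
              x$r1, x$r2, x$r3, x$t))
  cat(sprintf("  transport  : D1 = %g, D2 = %g, K = %g (shell permeability ~ K*D2 = %g)\n",
              x$D1, x$D2, x$K, x$K * x$D2))
  invisible(x)
}

#' Diffusional resistance of a spherical shell
#'
#' Steady-state resistance to radial diffusion across the shell bounded by
#' radii `r_in` and `r_out` with diffusivity `D`:
#' `(r_out - r_in) / (4 * pi * D * r_in * r_out)`, the quadrature of
#' `dr / (4 pi D r^2)` over the shell. A zero-thickness shell has zero
#' resistance.
#'
#' @param r_in Inner radius, > 0.
#' @param r_out Outer radius, >= `r_in`.
#' @param D Diffusivity, > 0.
#' @return Resistance in time / length^3.
#' @examples
#' shell_resistance(1, 2, 1)  # 1 / (8 * pi)
#' @export
shell_resistance <- function(r_in, r_out, D) {
  if (!is.numeric(r_in) || length(r_in) != 1L || !is.finite(r_in) || r_in <= 0)
    stop("invalid `r_in`: inner radius must be a single positive number",
         call. = FALSE)
  if (!is.numeric(r_out) || length(r_out) != 1L || !is.finite(r_out) ||
      r_out < r_in)
    stop("invalid `r_out`: outer radius must satisfy r_out >= r_in",
         call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("invalid `D`: diffusivity must be a single positive number",
         call. = FALSE)
  (r_out - r_in) / (4 * pi * D * r_in * r_out)
}

#' Series-resistance breakdown of a coated particle
#'
#' Splits the steady-state diffusional resistance between the interior
#' sampling radius `r1` and the PEM outer surface `r3` into the two series
#' contributions: `R_a` from `r1` to the particle surface `r2` (core
#' diffusivity `D1`) and `R_b` across the PEM shell from `r2` to `r3`
#' (effective shell diffusivity `K * D2`, folding the partition coefficient
#' into the shell permeability). The total is `R_T = R_a + R_b`.
#'
#' When `D1 = 0` the core interior is impermeable (the capsule limit):
#' `R_a` is reported as `Inf` and the breakdown is flagged with
#' `core_blocked = TRUE`.
#'
#' @param sphere A [composite_sphere()].
#' @return An object of class `resistance_breakdown`: list with `R_a`,
#'   `R_b`, `R_T` and logical `core_blocked`.
#' @examples
#' sp <- composite_sphere(r2 = 2, t = 0.5, D1 = 1, D2 = 1)
#' total_resistance(sp)
#' @export
total_resistance <- function(sphere) {
  stopifnot(inherits(sphere, "composite_sphere"))
  core_blocked <- sphere$D1 == 0
  R_a <- if (core_blocked) Inf
         else shell_resistance(sphere$r1, sphere$r2, sphere$D1)
  R_b <- if (sphere$t == 0) 0
         else shell_resistance(sphere$r2, sphere$r3, sphere$K * sphere$D2)
  structure(
    list(R_a = R_a, R_b = R_b, R_T = R_a + R_b, core_blocked = core_blocked),
    class = "resistance_breakdown"
  )
}

#' @export
print.resistance_breakdown <- function(x, ...) {
  cat(sprintf("Series resistances: R_a = %g, R_b = %g, R_T = %g%s\n",
              x$R_a, x$R_b, x$R_T,
              if (x$core_blocked) " (core blocked: D1 = 0)" else ""))
  invisible(x)
}

#' Concentration driving force
#'
#' The difference between the concentration `C_i` at the interior sampling
#' radius and the bulk concentration `C_0` outside the particle is the
#' driving force of the steady-state mass-transfer rate; only the
#' difference is consumed downstream.
#'
#' @param C_i Inner concentration.
#' @param C_0 Outer (bulk) concentration, same unit.
#' @return Object of class `driving_force`.
#' @export
driving_force <- function(C_i, C_0) {
  stopifnot(is.numeric(C_i), length(C_i) == 1L, is.finite(C_i),
            is.numeric(C_0), length(C_0) == 1L, is.finite(C_0))
  structure(list(C_i = C_i, C_0 = C_0), class = "driving_force")
}

#' Steady-state mass-transfer rate through the composite sphere
#'
#' `M = (C_i - C_0) / R_T`: the quasi-steady rate at which drug crosses
#' from the interior sampling radius to the bulk, given the total series
#' resistance. The sign follows the concentration difference. An infinite
#' resistance (blocked core) gives rate 0; a zero resistance is a
#' degenerate geometry and raises an error.
#'
#' @param df A [driving_force()].
#' @param rb A `resistance_breakdown` from [total_resistance()].
#' @return Mass per time.
#' @export
mass_transfer_rate <- function(df, rb) {
  stopifnot(inherits(df, "driving_force"), inherits(rb, "resistance_breakdown"))
  if (rb$R_T == 0)
    stop("degenerate geometry: total resistance is zero", call. = FALSE)
  dC <- df$C_i - df$C_0
  if (is.infinite(rb$R_T)) return(0)
  dC / rb$R_T
}

#' Coated/uncoated mass-transfer-rate ratio (retardation ratio)
#'
#' The ratio `M_T / M_0` between the steady-state mass-transfer rate of a
#' PEM-coated particle and that of the same particle uncoated, assuming the
#' same driving force across both (valid at early times, before the coated
#' particle's interior concentration diverges from the uncoated one). Under
#' that assumption the ratio reduces to `R_a / (R_a + R_b)`.
#'
#' A value of 1 means no retardation; smaller values mean a stronger
#' barrier. Two limits are handled exactly rather than through floating
#' point: a zero-thickness shell (`t = 0`, no coating) gives exactly 1, and
#' a blocked core (`D1 = 0`, the capsule limit, where all resistance sits
#' in the core side) also gives exactly 1.
#'
#' @param sphere A [composite_sphere()].
#' @return A fraction in (0, 1].
#' @examples
#' composite_sphere(r2 = 0.2, t = 0.02, D1 = 1, D2 = 1) |> retardation_ratio()
#' @export
retardation_ratio <- function(sphere) {
  stopifnot(inherits(sphere, "composite_sphere"))
  if (sphere$t == 0 || sphere$D1 == 0) return(1)
  rb <- total_resistance(sphere)
  rb$R_a / rb$R_T
}

#' Retardation ratio across a sweep of particle sizes
#'
#' Recomputes the retardation ratio over a set of core radii `r2` with the
#' shell thickness, diffusivities and partition coefficient held fixed and
#' the interior sampling radius scaled as `r1 = r1_fraction * r2`. As the
#' particle grows at fixed shell thickness the shell resistance shrinks
#' relative to the core resistance and the ratio climbs towards 1: the
#' retardation by the coating diminishes with particle size.
#'
#' @param base A [composite_sphere()] supplying `t`, `D1`, `D2`, `K`.
#' @param r2_values Core radii to evaluate (same length unit as `base`).
#' @param r1_fraction Fraction in (0, 1) setting `r1 = r1_fraction * r2`.
#'   Default 0.5.
#' @return A data.frame with columns `r2` and `ratio`, sorted by `r2`, with
#'   the sweep parameters attached as attribute `"params"`.
#' @export
size_sweep <- function(base, r2_values, r1_fraction = 0.5) {
  stopifnot(inherits(base, "composite_sphere"))
  if (!is.numeric(r1_fraction) || length(r1_fraction) != 1L ||
      r1_fraction <= 0 || r1_fraction >= 1)
    stop("invalid `r1_fraction`: must lie strictly between 0 and 1",
         call. = FALSE)
  params <- list(r1_fraction = r1_fraction, t = base$t,
                 D1 = base$D1, D2 = base$D2, K = base$K)
  if (length(r2_values) == 0L) {
    out <- data.frame(r2 = numeric(0), ratio = numeric(0))
    attr(out, "params") <- params
    return(out)
  }
  stopifnot(is.numeric(r2_values), all(is.finite(r2_values)),
            all(r2_values > 0))
  r2s <- sort(r2_values)
  ratio <- vapply(r2s, function(r2) {
    retardation_ratio(composite_sphere(
      r2 = r2, t = base$t, D1 = base$D1, D2 = base$D2, K = base$K,
      r1 = r1_fraction * r2
    ))
  }, numeric(1))
  out <- data.frame(r2 = r2s, ratio = ratio)
  attr(out, "params") <- params
  out
}

#' Write a size sweep to CSV with a JSON parameter sidecar
#'
#' Writes the `(r2, ratio)` table of [size_sweep()] as CSV and the sweep
#' parameters (`r1_fraction`, `t`, `D1`, `D2`, `K`) as a JSON sidecar named
#' `<path>.json`, so that a sweep is reconstructible from its outputs.
#'
#' @param sweep Result of [size_sweep()].
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_size_sweep <- function(sweep, path) {
  stopifnot(is.data.frame(sweep), all(c("r2", "ratio") %in% names(sweep)))
  utils::write.csv(sweep[, c("r2", "ratio")], path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  params <- attr(sweep, "params")
  if (is.null(params)) params <- list()
  jsonlite::write_json(params, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
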