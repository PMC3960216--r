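#' Aliquot-and-replenish sampling protocol
#'
#' Describes the in-vitro release assay schedule: the particles sit in a
#' vessel of volume `V_total`; at each scheduled time an aliquot of volume
#' `V_aliquot` is withdrawn for quantitation and the vessel is topped back
#' up to `V_total` with drug-free buffer. Withdrawn drug never returns, so
#' cumulative release must add back the mass carried away by earlier
#' aliquots.
#'
#' @param V_total Assay volume (> 0), e.g. 1 (mL).
#' @param V_aliquot Withdrawn volume per time point, 0 < `V_aliquot` <=
#'   `V_total`.
#' @param times Strictly increasing sampling times.
#' @return Object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(V_total, V_aliquot, times) {
  stopifnot(is.numeric(V_total), length(V_total) == 1L, V_total > 0,
            is.numeric(V_aliquot), length(V_aliquot) == 1L)
  if (V_aliquot <= 0 || V_aliquot > V_total)
    stop("`V_aliquot` must satisfy 0 < V_aliquot <= V_total", call. = FALSE)
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("sampling `times` must be strictly increasing", call. = FALSE)
  structure(list(V_total = V_total, V_aliquot = V_aliquot, times = times),
            class = "sampling_protocol")
}

#' Cumulative mass released under aliquot-and-replenish sampling
#'
#' Reconstructs the cumulative mass of drug released up to each sampling
#' time from the supernatant concentrations measured in the aliquots. At
#' time point `n` the vessel holds `V_total * C_n` of drug, and each of
#' the earlier aliquots removed `V_aliquot * C_i`, so
#' `cum_n = V_total * C_n + V_aliquot * sum_{i<n} C_i`.
#'
#' With `correct = FALSE` the aliquot term is dropped (`V_total * C_n`
#' only), for sensitivity analysis of reports that may not have applied
#' the correction.
#'
#' @param concentrations Supernatant concentration at each scheduled time
#'   (one per time point, all >= 0).
#' @param protocol A [sampling_protocol()].
#' @param correct Apply the aliquot-removal correction? Default `TRUE`.
#' @return Numeric vector of cumulative released mass per time point.
#' @examples
#' pr <- sampling_protocol(1, 0.1, times = c(1, 2, 3))
#' cumulative_mass_released(c(10, 8, 6), pr)
#' @export
cumulative_mass_released <- function(concentrations, protocol,
                                     correct = TRUE) {
  stopifnot(inherits(protocol, "sampling_protocol"),
            is.numeric(concentrations))
  if (length(concentrations) != length(protocol$times))
    stop("need exactly one concentration per scheduled time", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("negative or non-finite concentration in release data",
         call. = FALSE)
  held <- protocol$V_total * concentrations
  if (!correct) return(held)
  removed <- protocol$V_aliquot *
    c(0, cumsum(concentrations))[seq_along(concentrations)]
  held + removed
}

#' Percent release relative to drug content
#'
#' `100 * mass_released / content`. Use [render_percent()] to mirror
#' one-decimal reported values; full precision is kept internally.
#'
#' @param mass_released Released drug mass (>= 0).
#' @param content Drug content the percentage is based on (> 0).
#' @return Percentage (full precision).
#' @examples
#' percent_release(20, 100)  # 20
#' render_percent(percent_release(5, 85))  # 5.9
#' @export
percent_release <- function(mass_released, content) {
  stopifnot(is.numeric(mass_released), is.numeric(content))
  if (any(content == 0))
    stop("undefined percentage: drug content is zero", call. = FALSE)
  100 * mass_released / content
}

#' Round a percentage for reporting (half away from zero)
#'
#' Reporting-layer rounding to a fixed number of decimals with halves
#' rounded away from zero (so 5.85 renders as 5.9), matching how release
#' and loss percentages are conventionally printed. Internal computations
#' never round.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places. Default 1.
#' @return Rounded numeric vector.
#' @export
render_percent <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Drug content of a particle batch
#'
#' Bundles the measured drug mass in the particles, the particle mass, and
#' the theoretical (intended) drug mass, the three quantities needed for
#' loading and encapsulation-efficiency percentages. A measured drug mass
#' exceeding the theoretical one is physically suspect and is flagged with
#' a warning, not an error.
#'
#' @param mass_drug Measured drug mass in the particles (>= 0).
#' @param mass_particles Particle mass (>= 0).
#' @param theoretical_mass Intended drug mass (>= 0).
#' @return Object of class `drug_content`.
#' @export
drug_content <- function(mass_drug, mass_particles, theoretical_mass) {
  stopifnot(is.numeric(mass_drug), mass_drug >= 0,
            is.numeric(mass_particles), mass_particles >= 0,
            is.numeric(theoretical_mass), theoretical_mass >= 0)
  exceeds <- mass_drug > theoretical_mass
  if (exceeds)
    warning("measured drug mass exceeds theoretical mass", call. = FALSE)
  structure(list(mass_drug = mass_drug, mass_particles = mass_particles,
                 theoretical_mass = theoretical_mass,
                 exceeds_theoretical = exceeds),
            class = "drug_content")
}

#' Drug loading (weight/weight percent)
#'
#' `100 * mass_drug / mass_particles`: drug mass as a percentage of the
#' total particle mass.
#'
#' @param content A [drug_content()].
#' @return Percentage.
#' @export
drug_loading <- function(content) {
  stopifnot(inherits(content, "drug_content"))
  if (content$mass_particles == 0)
    stop("undefined loading: particle mass is zero", call. = FALSE)
  100 * content$mass_drug / content$mass_particles
}

#' Encapsulation efficiency
#'
#' `100 * mass_drug / theoretical_mass`: the measured drug content as a
#' percentage of the intended one.
#'
#' @param content A [drug_content()].
#' @return Percentage.
#' @export
encapsulation_efficiency <- function(content) {
  stopifnot(inherits(content, "drug_content"))
  if (content$theoretical_mass == 0)
    stop("undefined efficiency: theoretical mass is zero", call. = FALSE)
  100 * content$mass_drug / content$theoretical_mass
}

#' Per-step drug losses of one layer-by-layer coating run
#'
#' Records the ordered drug-loss masses of each adsorption and wash step
#' while a polyelectrolyte multilayer is built on drug-loaded particles,
#' for one polyelectrolyte pair and build-up pH condition, together with
#' the drug-content basis its percentages refer to.
#'
#' @param condition Label, e.g. `"PAH/PSS @ pH 9"`.
#' @param steps data.frame with columns `layer` (positive integer,
#'   non-decreasing), `step` (`"adsorption"` or `"wash"`), `loss_mass`
#'   (>= 0).
#' @param content_basis Drug content the loss percentages are based on
#'   (> 0).
#' @return Object of class `coating_run`.
#' @export
coating_run <- function(condition, steps, content_basis) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.data.frame(steps),
            all(c("layer", "step", "loss_mass") %in% names(steps)),
            is.numeric(content_basis), length(content_basis) == 1L,
            content_basis > 0)
  if (nrow(steps) > 0) {
    if (any(!steps$step %in% c("adsorption", "wash")))
      stop("`step` must be 'adsorption' or 'wash'", call. = FALSE)
    if (any(steps$loss_mass < 0))
      stop("loss masses must be >= 0", call. = FALSE)
    if (any(diff(steps$layer) < 0))
      stop("layer indices must be non-decreasing", call. = FALSE)
  }
  structure(list(condition = condition, steps = steps,
                 content_basis = content_basis),
            class = "coating_run")
}

#' Summarise the drug losses of a coating run
#'
#' Converts each step's loss mass into a percent of the drug-content
#' basis, totals them per layer and overall, and flags whether the
#' first-layer wash loses more drug than the first-layer adsorption — the
#' pH-dependent signature of the protein's charge state: below its
#' isoelectric point the (positive) protein is not held by the adsorbed
#' polycation and keeps desorbing into the wash.
#'
#' @param run A [coating_run()].
#' @return List with `per_step` (data.frame: layer, step, loss_mass,
#'   percent), `per_layer` (data.frame: layer, percent), `total_percent`,
#'   and logical `wash_exceeds_adsorption` (`NA` if layer 1 lacks either
#'   step).
#' @export
loss_summary <- function(run) {
  stopifnot(inherits(run, "coating_run"))
  steps <- run$steps
  if (nrow(steps) == 0L) {
    return(list(per_step = data.frame(layer = integer(0),
                                      step = character(0),
                                      loss_mass = numeric(0),
                                      percent = numeric(0)),
                per_layer = data.frame(layer = integer(0),
                                       percent = numeric(0)),
                total_percent = numeric(0),
                wash_exceeds_adsorption = NA))
  }
  per_step <- data.frame(layer = steps$layer, step = steps$step,
                         loss_mass = steps$loss_mass,
                         percent = 100 * steps$loss_mass / run$content_basis)
  agg <- stats::aggregate(percent ~ layer, data = per_step, FUN = sum)
  l1a <- per_step$percent[per_step$layer == min(per_step$layer) &
                            per_step$step == "adsorption"]
  l1w <- per_step$percent[per_step$layer == min(per_step$layer) &
                            per_step$step == "wash"]
  flag <- if (length(l1a) && length(l1w)) sum(l1w) > sum(l1a) else NA
  list(per_step = per_step,
       per_layer = agg[order(agg$layer), ],
       total_percent = sum(per_step$percent),
       wash_exceeds_adsorption = flag)
}

#' Mean total coating loss across conditions
#'
#' Arithmetic mean of per-condition total loss percentages (use
#' [render_percent()] for the one-decimal reported form).
#'
#' @param totals Numeric vector of total loss percentages, length >= 1.
#' @return Mean percentage, full precision.
#' @examples
#' render_percent(mean_total_loss(c(8.0, 5.4, 6.8, 3.7, 5.0, 3.7)))  # 5.4
#' @export
mean_total_loss <- function(totals) {
  if (length(totals) == 0L)
    stop("no totals supplied", call. = FALSE)
  stopifnot(is.numeric(totals), all(is.finite(totals)))
  mean(totals)
}

#' Re-express percent release on the post-loss content basis
#'
#' When a fraction of the drug is lost during coating, a release later
#' reported as a percentage of the *measured* (post-loss) content is
#' inflated relative to the original basis. Given a release percentage
#' expressed on the original content and the loss percentage, this returns
#' the percentage the same released mass represents of the post-loss
#' content: `release_percent / (1 - loss_percent / 100)`. It reproduces
#' the cautionary arithmetic that a drop from 20% to 5.9% "release" can
#' reflect drug loss, not barrier action: losing 15 of 100 mass units
#' leaves 85, so releasing 5 units registers as 5.9%, not 5%.
#'
#' @param release_percent_of_original Release as percent of the original
#'   (pre-loss) drug content.
#' @param loss_percent Percent of the original content lost during
#'   coating, < 100.
#' @return Percent of the post-loss content.
#' @examples
#' render_percent(loss_adjusted_release(5, 15))  # 5.9
#' @export
loss_adjusted_release <- function(release_percent_of_original, loss_percent) {
  stopifnot(is.numeric(release_percent_of_original),
            is.numeric(loss_percent))
  if (any(loss_percent >= 100))
    stop("loss of 100% or more leaves no content basis", call. = FALSE)
  release_percent_of_original / (1 - loss_percent / 100)
}
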