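## Surface-saturation planning for protein-coated microspheres, and the
## mass/molar concentration conversion used for ligand inputs.

#' Coating specification for microsphere saturation
#'
#' Units follow the conventional mixed system of the saturation formula
#' `S = 6 C / (rho d)`: capacity in mg protein per m^2, particle density in
#' g/cm^3, diameter in micrometres, giving S in mg protein per gram of
#' microspheres. Because silent unit mix-ups are the main failure mode of
#' this formula, the constructor rejects values that look SI-coherent
#' (e.g. a diameter in metres or a density in kg/m^3).
#'
#' @param capacity Surface capacity C, mg protein per m^2 (>= 0).
#' @param density Particle material density, g/cm^3.
#' @param diameter Mean particle diameter, micrometres.
#' @param excess_factor Dose multiplier over the theoretical saturation
#'   amount (default 10, the usual excess for monolayer formation).
#' @return Object of class `coating_spec`.
#' @examples
#' coating_spec(capacity = 3, density = 1.19, diameter = 4.8)
#' @export
coating_spec <- function(capacity = 3, density = 1.19, diameter = 4.8,
                         excess_factor = 10) {
  .check_positive(capacity, "capacity", strict = FALSE)
  .check_positive(density, "density")
  .check_positive(diameter, "diameter")
  .check_positive(excess_factor, "excess_factor")
  if (capacity > 1e3)
    stop("'capacity' implausibly large; supply mg protein per m^2",
         call. = FALSE)
  if (density >= 50)
    stop("'density' looks like kg/m^3; supply g/cm^3", call. = FALSE)
  if (density < 0.05)
    stop("'density' implausibly small for a solid; supply g/cm^3",
         call. = FALSE)
  if (diameter < 0.01)
    stop("'diameter' looks like metres; supply micrometres", call. = FALSE)
  if (diameter > 1e5)
    stop("'diameter' implausibly large; supply micrometres", call. = FALSE)
  structure(list(capacity = capacity, density = density, diameter = diameter,
                 excess_factor = excess_factor),
            class = "coating_spec")
}

#' Protein amount required for surface saturation
#'
#' `S = 6 C / (rho d)` with C in mg/m^2, rho in g/cm^3 and d in um: the mass
#' of protein (mg) needed to saturate one gram of microspheres, from the
#' surface-to-mass ratio of a sphere (6 / (rho d) is the surface area per
#' unit mass in the mixed-unit convention).
#'
#' @param spec A [coating_spec()].
#' @return Saturation amount S, mg protein per g microspheres.
#' @examples
#' saturation_amount(coating_spec(3, 1.19, 4.8))  # ~3.15 mg/g
#' @export
saturation_amount <- function(spec) {
  stopifnot(inherits(spec, "coating_spec"))
  6 * spec$capacity / (spec$density * spec$diameter)
}

#' Coating plan for a given particle mass
#'
#' @param spec A [coating_spec()].
#' @param particle_mass Mass of microspheres to coat, g.
#' @return List with `saturation_mg_per_g`, `protein_mg` (theoretical) and
#'   `dose_mg` (excess-multiplied).
#' @export
plan_coating <- function(spec, particle_mass = 1) {
  .check_positive(particle_mass, "particle_mass")
  s <- saturation_amount(spec)
  list(saturation_mg_per_g = s,
       protein_mg = s * particle_mass,
       dose_mg = s * particle_mass * spec$excess_factor)
}

#' Convert a mass concentration to molarity
#'
#' @param mass_conc Mass concentration, ug/mL (>= 0).
#' @param molecular_weight Molecular weight, kDa (> 0).
#' @return Molar concentration, mol/L.
#' @examples
#' molar_concentration(10, 66)  # ~1.52e-7 M
#' @export
molar_concentration <- function(mass_conc, molecular_weight) {
  if (!is.numeric(mass_conc) || any(!is.finite(mass_conc)) ||
      any(mass_conc < 0))
    stop("'mass_conc' must be finite and non-negative (ug/mL)", call. = FALSE)
  .check_positive(molecular_weight, "molecular_weight")
  ## ug/mL = mg/L = 1e-3 g/L; kDa = 1e3 g/mol
  (mass_conc * 1e-3) / (molecular_weight * 1e3)
}
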