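#' Define a target material
#'
#' A material is an elemental composition (one row per element with atomic
#' number, mass number in g/mol approximation, and stoichiometry in atoms per
#' formula unit), a bulk density, and a mean excitation energy I. The
#' effective (Z/A) of the material used by the Bethe equation is the
#' stoichiometry-weighted sum of Z over the stoichiometry-weighted sum of A,
#' which is identical to the mass-fraction-weighted sum of per-element Z/A
#' (Bragg additivity holds by construction).
#'
#' @param name Character identifier.
#' @param components data.frame with columns `Z_elem`, `A_elem`,
#'   `stoichiometry` (and optionally `symbol`).
#' @param density Bulk density, g cm^-3.
#' @param mean_excitation_energy Mean excitation energy I, eV.
#' @return Object of class `material`.
#' @export
#' @examples
#' material("water",
#'   data.frame(symbol = c("H", "O"), Z_elem = c(1, 8),
#'              A_elem = c(1.008, 15.999), stoichiometry = c(2, 1)),
#'   density = 1.0, mean_excitation_energy = 75)
material <- function(name, components, density, mean_excitation_energy) {
  stopifnot(is.character(name), length(name) == 1L)
  req <- c("Z_elem", "A_elem", "stoichiometry")
  if (!is.data.frame(components) || !all(req %in% names(components)))
    stop("`components` must be a data.frame with columns Z_elem, A_elem, stoichiometry")
  with(components, {
    if (any(Z_elem < 1)) stop("Z_elem must be >= 1")
    if (any(A_elem < Z_elem)) stop("A_elem must be >= Z_elem")
    if (any(stoichiometry <= 0)) stop("stoichiometry must be positive")
  })
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  if (!is.numeric(mean_excitation_energy) || mean_excitation_energy <= 0)
    stop("mean_excitation_energy must be positive")
  if (is.null(components$symbol))
    components$symbol <- paste0("Z", components$Z_elem)
  m <- list(
    name = name,
    components = components,
    density = density,
    mean_excitation_energy = mean_excitation_energy
  )
  class(m) <- "material"
  m
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %g g/cm3, I = %g eV, Z/A = %.4f)\n",
              x$name, x$density, x$mean_excitation_energy, material_zoa(x)))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Formula mass of a material (g/mol)
#' @param mat A `material`.
#' @return Numeric scalar, sum of stoichiometry * A over components.
#' @export
formula_mass <- function(mat) {
  stopifnot(inherits(mat, "material"))
  sum(mat$components$stoichiometry * mat$components$A_elem)
}

#' Effective Z/A of a material
#' @param mat A `material`.
#' @return Numeric scalar (Z/A)_mat.
#' @export
material_zoa <- function(mat) {
  stopifnot(inherits(mat, "material"))
  sum(mat$components$stoichiometry * mat$components$Z_elem) / formula_mass(mat)
}

#' Built-in materials
#'
#' Water (rho 1.0, I 75 eV), high-density polyethylene CH2 (rho 0.97,
#' I 57.4 eV) and aluminum (rho 2.699, I 166 eV). Mean excitation energies are
#' the ICRU standard values; the density of polyethylene matches the moderator
#' used in the Bragg-curve measurements this package reanalyses.
#'
#' @param name One of `"water"`, `"polyethylene"`, `"aluminum"`.
#' @return A `material`.
#' @export
#' @examples
#' builtin_material("polyethylene")$density
builtin_material <- function(name = c("water", "polyethylene", "aluminum")) {
  name <- match.arg(name)
  switch(name,
    water = material("water",
      data.frame(symbol = c("H", "O"), Z_elem = c(1, 8),
                 A_elem = c(1.008, 15.999), stoichiometry = c(2, 1)),
      density = 1.0, mean_excitation_energy = 75),
    polyethylene = material("polyethylene",
      data.frame(symbol = c("C", "H"), Z_elem = c(6, 1),
                 A_elem = c(12.011, 1.008), stoichiometry = c(1, 2)),
      density = 0.97, mean_excitation_energy = 57.4),
    aluminum = material("aluminum",
      data.frame(symbol = "Al", Z_elem = 13, A_elem = 27,
                 stoichiometry = 1),
      density = 2.699, mean_excitation_energy = 166)
  )
}

#' Load a materials registry from a YAML file
#'
#' The file maps material names to entries with `density`,
#' `mean_excitation_energy`, and an `elements` list of (symbol, Z, A,
#' stoichiometry).
#'
#' @param path Path to YAML file.
#' @return Named list of `material` objects.
#' @export
read_materials_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    comp <- do.call(rbind, lapply(e$elements, function(el)
      data.frame(symbol = el$symbol %||% paste0("Z", el$Z),
                 Z_elem = el$Z, A_elem = el$A,
                 stoichiometry = el$stoichiometry)))
    material(nm, comp, e$density, e$mean_excitation_energy)
  })
  names(out) <- names(raw)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define an ion (projectile or fragment) state
#'
#' @param Z Charge number (>= 1).
#' @param A Mass number (>= Z, except the proton Z = A = 1).
#' @param energy_per_nucleon Kinetic energy, MeV/nuc (>= 0).
#' @return Object of class `ion_state`.
#' @export
#' @examples
#' ion_state(6, 12, 200)
ion_state <- function(Z, A, energy_per_nucleon) {
  if (Z < 1) stop("Z must be >= 1")
  if (A < Z) stop("A must be >= Z")
  if (any(energy_per_nucleon < 0)) stop("energy_per_nucleon must be >= 0")
  structure(list(Z = Z, A = A, energy_per_nucleon = energy_per_nucleon),
            class = "ion_state")
}

#' @export
print.ion_state <- function(x, ...) {
  cat(sprintf("<ion> Z=%d A=%d  E = %s MeV/nuc\n", x$Z, x$A,
              paste(signif(x$energy_per_nucleon, 5), collapse = ", ")))
  invisible(x)
}
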