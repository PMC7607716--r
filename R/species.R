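#' @importFrom stats approx integrate median optimize rnorm runif sd setNames uniroot
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

# Standard atomic weights (IUPAC 2021, conventional values), g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, Na = 22.990, K = 39.098,
  Mg = 24.305, Ca = 40.078, Cl = 35.45, Fe = 55.845
)

#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as `"C6H12O6"` into a named integer vector
#' of element counts. Only element symbols with a known standard atomic
#' weight are accepted.
#'
#' @param formula Character scalar, e.g. `"C6H10O3N"`.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula string: '", formula, "'")
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(.ATOMIC_WEIGHTS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  storage.mode(counts) <- "integer"
  c(counts)
}

#' Molar mass of a formula
#'
#' @param formula Named integer vector of element counts (see
#'   [parseFormula()]) or a formula string.
#' @return Molar mass in g/mol.
#' @export
molarMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  stopifnot(all(formula > 0), all(formula == round(formula)))
  sum(.ATOMIC_WEIGHTS[names(formula)] * formula)
}

#' Carbon mass fraction of a molecular formula
#'
#' Mass of carbon divided by total molar mass; the quantity that converts a
#' species mass into the carbon it carries in the process carbon balance.
#'
#' @inheritParams molarMass
#' @return Dimensionless fraction in (0, 1].
#' @examples
#' carbonFraction("CO2")     # 0.2729
#' carbonFraction("C6H12O6") # 0.4000
#' @export
carbonFraction <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  if (!"C" %in% names(formula) || formula[["C"]] <= 0) {
    stop("formula contains no carbon")
  }
  unname(formula[["C"]] * .ATOMIC_WEIGHTS[["C"]] / molarMass(formula))
}

#' Construct a chemical species
#'
#' A species couples a name, a molecular formula, its molar mass and its
#' carbon mass fraction. The carbon fraction may be overridden for species
#' whose exact composition is unknown (the bundled `"lipid"` species uses a
#' fixed fraction typical of C16/C18 triacylglycerol/FAME mixtures instead
#' of a formula).
#'
#' @param name Species name.
#' @param formula Formula string in Hill notation, or `NULL` if only a
#'   carbon fraction is known.
#' @param carbon_fraction Optional explicit carbon mass fraction overriding
#'   the one computed from the formula.
#' @return An object of class `chem_species`.
#' @examples
#' chemSpecies("glucose", "C6H12O6")
#' chemSpecies("lipid", NULL, carbon_fraction = 0.77)
#' @export
chemSpecies <- function(name, formula, carbon_fraction = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  counts <- NULL
  mm <- NA_real_
  if (!is.null(formula)) {
    counts <- if (is.character(formula)) parseFormula(formula) else formula
    mm <- molarMass(counts)
    if (is.null(carbon_fraction)) carbon_fraction <- carbonFraction(counts)
  }
  if (is.null(carbon_fraction)) {
    stop("either a formula or an explicit carbon_fraction is required")
  }
  stopifnot(carbon_fraction > 0, carbon_fraction <= 1)
  structure(
    list(name = name, formula = counts, molar_mass = mm,
         carbon_mass_fraction = carbon_fraction),
    class = "chem_species"
  )
}

#' @export
print.chem_species <- function(x, ...) {
  f <- if (is.null(x$formula)) "<no formula>" else
    paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""), collapse = "")
  cat(sprintf("<chem_species> %s  %s  M = %s g/mol  wC = %.4f\n",
              x$name, f,
              if (is.na(x$molar_mass)) "NA" else sprintf("%.3f", x$molar_mass),
              x$carbon_mass_fraction))
  invisible(x)
}

#' Carbon mass carried by a given mass of a species
#'
#' @param species A [chemSpecies()] object.
#' @param mass Mass in g; must be non-negative.
#' @return Carbon mass in g. Linear and additive in `mass`.
#' @export
carbonMass <- function(species, mass) {
  stopifnot(inherits(species, "chem_species"))
  if (any(mass < 0)) stop("mass must be non-negative")
  mass * species$carbon_mass_fraction
}

#' Default species registry
#'
#' The species used throughout the package: glucose, xylose, CO2, gluconic
#' acid, xylonic acid, lipid-free yeast biomass (empirical formula C6H10O3N
#' for baker's yeast cell mass), and a lipid pseudo-species with a
#' configurable carbon mass fraction (default 0.77, typical of a C16/C18
#' triacylglycerol/FAME mixture).
#'
#' @param lipid_carbon_fraction Carbon mass fraction assumed for lipids.
#' @return Named list of `chem_species`.
#' @export
speciesRegistry <- function(lipid_carbon_fraction = 0.77) {
  list(
    glucose       = chemSpecies("glucose", "C6H12O6"),
    xylose        = chemSpecies("xylose", "C5H10O5"),
    co2           = chemSpecies("co2", "CO2"),
    gluconic_acid = chemSpecies("gluconic_acid", "C6H12O7"),
    xylonic_acid  = chemSpecies("xylonic_acid", "C5H10O6"),
    biomass       = chemSpecies("biomass_lipid_free", "C6H10O3N"),
    lipid         = chemSpecies("lipid", NULL,
                                carbon_fraction = lipid_carbon_fraction)
  )
}

#' Load a species registry from a YAML config file
#'
#' The file maps species names to entries with a `formula` (Hill notation)
#' and/or an explicit `carbon_fraction` override:
#' ```yaml
#' glucose: {formula: C6H12O6}
#' lipid:   {carbon_fraction: 0.77}
#' ```
#' Entries merge over the defaults from [speciesRegistry()].
#'
#' @param path Path to the YAML file.
#' @param ... Passed on to [speciesRegistry()] for the defaults.
#' @return Named list of `chem_species`.
#' @export
readSpeciesConfig <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  reg <- speciesRegistry(...)
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    reg[[nm]] <- chemSpecies(
      name = nm,
      formula = entry$formula,
      carbon_fraction = entry$carbon_fraction
    )
  }
  reg
}
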