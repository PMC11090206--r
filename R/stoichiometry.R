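# element symbols accepted in formulas; modest set covering media chemistry
.known_elements <- c("C", "H", "O", "N", "S", "P", "Fe", "Na", "K", "Cl",
                     "Ca", "Mg", "Mn", "Ar")

#' Define a chemical compound
#'
#' A compound carries an elemental formula (fractional counts allowed, e.g.
#' the generic biomass formula CH2O0.5N0.15), a signed charge, a phase and an
#' optional standard transformed Gibbs free energy of formation at pH 7.
#'
#' @param name Identifier, e.g. `"NO3"`.
#' @param formula Named numeric vector of element counts, e.g.
#'   `c(N = 1, O = 3)`. Counts must be non-negative and at least one element
#'   must be present.
#' @param charge Signed charge (real; default 0).
#' @param phase One of `"aqueous"`, `"gas"`, `"liquid"`.
#' @param gf_prime Optional standard Gibbs free energy of formation at pH 7
#'   (kJ/mol); `NA` when unknown.
#' @return An object of class `"compound"`.
#' @examples
#' compound("NO2", c(N = 1, O = 2), charge = -1)
#' @export
compound <- function(name, formula, charge = 0,
                     phase = c("aqueous", "gas", "liquid"),
                     gf_prime = NA_real_) {
  phase <- match.arg(phase)
  formula <- unlist(formula)
  if (length(formula) == 0L || is.null(names(formula)) || any(names(formula) == ""))
    stop("compound '", name, "': formula must be a named vector with at least one element")
  bad <- setdiff(names(formula), .known_elements)
  if (length(bad))
    stop("compound '", name, "': unknown element symbol(s): ",
         paste(bad, collapse = ", "))
  formula <- vapply(formula, as.numeric, numeric(1))
  if (any(formula < 0) || all(formula == 0))
    stop("compound '", name, "': element counts must be >= 0 with at least one positive")
  structure(list(name = name, formula = formula, charge = as.numeric(charge),
                 phase = phase, gf_prime = as.numeric(gf_prime)),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  f <- paste0(names(x$formula), ifelse(x$formula == 1, "", x$formula),
              collapse = "")
  cat(sprintf("<compound> %s  [%s]  charge %+g  phase %s", x$name, f,
              x$charge, x$phase))
  if (!is.na(x$gf_prime)) cat(sprintf("  Gf' %.2f kJ/mol", x$gf_prime))
  cat("\n")
  invisible(x)
}

#' Define a stoichiometric reaction
#'
#' Coefficients are signed: reactants negative, products positive. The
#' reference compound fixes the per-mole basis on which reaction energies
#' are reported.
#'
#' @param name Identifier.
#' @param stoich Named numeric vector of signed coefficients; names must be
#'   compound names present in `compounds`.
#' @param compounds Named list of [compound()] objects covering every species
#'   in `stoich`.
#' @param reference Name of the reference compound (must have a nonzero
#'   coefficient).
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(name, stoich, compounds, reference) {
  stoich <- unlist(stoich)
  if (!any(stoich < 0) || !any(stoich > 0))
    stop("reaction '", name, "': needs at least one reactant (negative) and one product (positive)")
  missing <- setdiff(names(stoich), names(compounds))
  if (length(missing))
    stop("reaction '", name, "': compounds not defined: ",
         paste(missing, collapse = ", "))
  if (!reference %in% names(stoich) || stoich[[reference]] == 0)
    stop("reaction '", name, "': reference compound '", reference,
         "' must carry a nonzero coefficient")
  structure(list(name = name, stoich = stoich,
                 compounds = compounds[names(stoich)], reference = reference),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(s) paste(sprintf("%s%s",
                                    ifelse(abs(s) == 1, "", paste0(abs(s), " ")),
                                    names(s)), collapse = " + ")
  cat(sprintf("<reaction> %s: %s -> %s  (per mol %s)\n", x$name,
              side(x$stoich[x$stoich < 0]), side(x$stoich[x$stoich > 0]),
              x$reference))
  invisible(x)
}

#' Element balance of a reaction
#'
#' Sums coefficient x element-count over all species; an exactly balanced
#' reaction has zero residual for every element. Fractional literature
#' coefficients (e.g. the two-decimal anammox stoichiometry) leave small
#' nonzero residuals.
#'
#' @param rxn A [reaction()].
#' @return Named numeric vector of residuals (mol element per mol of
#'   reaction as written), one entry per element occurring in the reaction.
#' @examples
#' reg <- default_registry()
#' element_balance(reg$reactions$propane_nitrite_to_n2)
#' @export
element_balance <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  elements <- unique(unlist(lapply(rxn$compounds, function(cp) names(cp$formula))))
  res <- setNames(numeric(length(elements)), elements)
  for (nm in names(rxn$stoich)) {
    f <- rxn$compounds[[nm]]$formula
    res[names(f)] <- res[names(f)] + rxn$stoich[[nm]] * f
  }
  res
}

#' Charge balance of a reaction
#'
#' @param rxn A [reaction()].
#' @return Signed residual charge (products minus reactants).
#' @export
charge_balance <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  sum(vapply(names(rxn$stoich),
             function(nm) rxn$stoich[[nm]] * rxn$compounds[[nm]]$charge,
             numeric(1)))
}

# mean oxidation state of `element` in a compound: O is -II, H is +I and the
# named element balances the total charge (standard bookkeeping convention)
oxidation_state <- function(cp, element) {
  if (!element %in% names(cp$formula) || cp$formula[[element]] == 0)
    stop("compound '", cp$name, "' contains no ", element)
  n <- cp$formula[[element]]
  others <- 0
  if (element != "H" && "H" %in% names(cp$formula))
    others <- others + 1 * cp$formula[["H"]]
  if (element != "O" && "O" %in% names(cp$formula))
    others <- others + -2 * cp$formula[["O"]]
  (cp$charge - others) / n
}

#' Electrons transferred per mole of a compound under a redox conversion
#'
#' Oxidation-state accounting for the registered redox conversions of the
#' consortium (alkane oxidation to CO2, ammonium oxidation to N2, and the
#' nitrate/nitrite reduction steps). The electron count is
#' |delta oxidation state| x atoms of the redox element per mole, e.g. 20
#' electrons per mole of propane (C at -8/3 to +4, 3 atoms). Applied to the
#' conversion's product the count is zero.
#'
#' @param cp A [compound()], or the name of one in `registry`.
#' @param conversion Name of a registered conversion, e.g.
#'   `"propane_to_co2"`, `"nitrate_to_n2"`.
#' @param registry A reaction registry, see [default_registry()].
#' @return Electrons per mole of `cp` (non-negative).
#' @examples
#' electrons_per_mole("NO3", "nitrate_to_n2")  # 5
#' @export
electrons_per_mole <- function(cp, conversion, registry = default_registry()) {
  conv <- registry$conversions[[conversion]]
  if (is.null(conv))
    stop("unsupported redox conversion '", conversion, "'; registered: ",
         paste(names(registry$conversions), collapse = ", "))
  if (is.character(cp)) cp <- registry_compound(registry, cp)
  stopifnot(inherits(cp, "compound"))
  from <- registry_compound(registry, conv$from)
  to <- registry_compound(registry, conv$to)
  if (cp$name == to$name) return(0)
  if (cp$name != from$name)
    stop("compound '", cp$name, "' is neither substrate nor product of conversion '",
         conversion, "'")
  delta <- oxidation_state(to, conv$element) - oxidation_state(from, conv$element)
  abs(delta) * cp$formula[[conv$element]]
}

#' Standard transformed Gibbs free energy of a reaction
#'
#' Sums coefficient x formation energy and normalizes by the reference
#' compound's coefficient, giving kJ per mole of reference compound. The
#' bundled formation table encodes the pH-7 convention in its H+ entry;
#' reported values are table-dependent at the percent level.
#'
#' @param rxn A [reaction()].
#' @param formation Optional named numeric vector overriding/extending the
#'   formation energies carried by the reaction's compounds (kJ/mol).
#' @return Reaction energy in kJ per mol of the reference compound.
#' @examples
#' reg <- default_registry()
#' delta_g_prime(reg$reactions$propane_nitrate_to_nitrite)  # about -1368
#' @export
delta_g_prime <- function(rxn, formation = NULL) {
  stopifnot(inherits(rxn, "reaction"))
  gf <- vapply(names(rxn$stoich), function(nm) {
    if (!is.null(formation) && nm %in% names(formation))
      return(as.numeric(formation[[nm]]))
    rxn$compounds[[nm]]$gf_prime
  }, numeric(1))
  if (anyNA(gf))
    stop("no formation energy for compound(s): ",
         paste(names(rxn$stoich)[is.na(gf)], collapse = ", "))
  sum(rxn$stoich * gf) / abs(rxn$stoich[[rxn$reference]])
}

#' Load a reaction registry
#'
#' Reads a YAML registry of compounds (formula, charge, phase, optional
#' formation energy), reactions and registered redox conversions. The bundled
#' registry holds the three consortium reactions (alkane-driven nitrate
#' reduction to nitrite, anammox with biomass synthesis, alkane-driven
#' denitrification of nitrite) plus their butane analogues.
#'
#' @param path Path to a registry YAML file; defaults to the bundled one.
#' @return A list with elements `compounds`, `reactions`, `conversions`.
#' @export
load_registry <- function(path = system.file("extdata", "reactions.yaml",
                                             package = "alkanammox")) {
  raw <- yaml::read_yaml(path)
  compounds <- lapply(names(raw$compounds), function(nm) {
    spec <- raw$compounds[[nm]]
    compound(nm, unlist(spec$formula), charge = spec$charge %||% 0,
             phase = spec$phase %||% "aqueous",
             gf_prime = spec$gf_prime %||% NA_real_)
  })
  names(compounds) <- names(raw$compounds)
  reactions <- lapply(names(raw$reactions), function(nm) {
    spec <- raw$reactions[[nm]]
    reaction(nm, unlist(spec$stoich), compounds, spec$reference)
  })
  names(reactions) <- names(raw$reactions)
  structure(list(compounds = compounds, reactions = reactions,
                 conversions = raw$conversions, path = path),
            class = "reaction_registry")
}

registry_compound <- function(registry, name) {
  cp <- registry$compounds[[name]]
  if (is.null(cp)) stop("compound '", name, "' not in registry")
  cp
}

.pkg_env <- new.env(parent = emptyenv())

#' Bundled reaction registry (cached)
#'
#' @return The registry shipped with the package, loaded once per session.
#' @export
default_registry <- function() {
  if (is.null(.pkg_env$registry)) .pkg_env$registry <- load_registry()
  .pkg_env$registry
}

#' Anammox stoichiometric constants
#'
#' Coefficients of the literature anammox reaction on a per-mol-NH4+ basis:
#' 1.32 NO2- consumed, 0.26 NO3- produced, 1.02 N2 (2.04 N2-N) produced,
#' 0.066 biomass C-mol synthesized, and the 0.02 N closing the nitrogen
#' ledger into biomass at the printed two-decimal precision.
#'
#' @return Named list of coefficients.
#' @export
anammox_coefficients <- function() {
  list(no2 = 1.32, no3 = 0.26, n2 = 1.02, n2_n = 2.04,
       biomass = 0.066, h = 0.13, n_assim = 0.02)
}

#' Printed bioreactor performance rates
#'
#' The steady-state consumption rates and balance totals reported for the
#' propane- and butane-fed consortium bioreactors and their anammox-free
#' predecessors, bundled as input data for balance calculations.
#'
#' @return A data frame with columns `system`, `quantity`, `value`, `sd`,
#'   `unit`.
#' @export
study_rates <- function() {
  utils::read.csv(system.file("extdata", "study_rates.csv",
                              package = "alkanammox"),
                  stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
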