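#' Construct a species record
#'
#' @param id Identifier string, unique within a network.
#' @param name Display name; defaults to `id`.
#' @param initial_concentration Initial concentration in nM (non-negative).
#' @param boundary Logical; boundary species have their concentration held
#'   fixed (zero derivative) during simulation.
#' @param compartment Compartment id the species lives in.
#' @return A one-row data frame with species fields.
#' @export
species <- function(id, name = id, initial_concentration = 0,
                    boundary = FALSE, compartment = "default") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.finite(initial_concentration) || initial_concentration < 0)
    stop("initial_concentration must be a non-negative finite number for species '",
         id, "'", call. = FALSE)
  data.frame(id = id, name = name,
             initial_concentration = as.numeric(initial_concentration),
             boundary = isTRUE(boundary), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Construct a reaction record
#'
#' Reactants and products are given as named numeric vectors mapping species
#' ids to positive stoichiometries; modifiers are species ids that appear in
#' the rate law without being consumed or produced.
#'
#' @param id Identifier string.
#' @param reactants,products Named numeric vectors (may be empty).
#' @param modifiers Character vector of species ids.
#' @param kinetic_law An R language object (e.g. `quote(k1 * A)`) over species
#'   ids, parameter ids and the time symbol `time`.
#' @param reversible Logical flag (annotation only; reversibility must be
#'   encoded in the rate law itself).
#' @param name Display name.
#' @return A list of class `"pd_reaction"`.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = character(), kinetic_law, reversible = FALSE,
                     name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  chk_stoich <- function(x, side) {
    if (length(x) == 0L) return(invisible())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("all ", side, " of reaction '", id, "' must be named", call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0))
      stop("stoichiometries must be positive in reaction '", id, "'", call. = FALSE)
  }
  chk_stoich(reactants, "reactants")
  chk_stoich(products, "products")
  if (!is.language(kinetic_law) && !is.numeric(kinetic_law))
    stop("kinetic_law of reaction '", id, "' must be an R language object or constant",
         call. = FALSE)
  structure(list(id = id, name = name,
                 reactants = reactants, products = products,
                 modifiers = as.character(modifiers),
                 kinetic_law = kinetic_law,
                 reversible = isTRUE(reversible)),
            class = "pd_reaction")
}

#' Assemble a reaction network
#'
#' The central container: species, reactions, parameters and compartments
#' parsed from (or destined for) SBML. Referential integrity is enforced on
#' construction.
#'
#' @param species Data frame of species rows (rbind of [species()] calls).
#' @param reactions List of [reaction()] objects.
#' @param parameters Named numeric vector of global parameter values
#'   (reaction-local parameters are namespaced as `<reaction id>__<id>` on
#'   SBML import).
#' @param compartments Named numeric vector of constant compartment volumes;
#'   defaults to a single unit-volume compartment.
#' @param id Model identifier.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, reactions = list(), parameters = numeric(),
                             compartments = c(default = 1), id = "model") {
  if (is.list(species) && !is.data.frame(species))
    species <- do.call(rbind, species)
  stopifnot(is.data.frame(species))
  if (nrow(species) < 1L)
    stop("a reaction network needs at least one species", call. = FALSE)
  if (anyDuplicated(species$id))
    stop("duplicate species id: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "),
         call. = FALSE)
  if (length(parameters) && anyDuplicated(names(parameters)))
    stop("duplicate parameter id", call. = FALSE)
  net <- structure(list(id = id, species = species, reactions = reactions,
                        parameters = parameters, compartments = compartments),
                   class = "reaction_network")
  validate_network(net)
}

#' Validate a reaction network's referential integrity
#'
#' Checks that every species referenced by a reaction (reactant, product,
#' modifier) is declared, that every free symbol in every kinetic law resolves
#' to a species, a parameter, a compartment or the time symbol, and that
#' initial concentrations are non-negative.
#'
#' @param net A `reaction_network`.
#' @return The network, invisibly unchanged, or an error.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  sids <- net$species$id
  if (any(net$species$initial_concentration < 0))
    stop("negative initial concentration", call. = FALSE)
  known <- c(sids, names(net$parameters), names(net$compartments), "time", "pi")
  for (rx in net$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    bad <- setdiff(refs, sids)
    if (length(bad))
      stop("reaction '", rx$id, "' references undeclared species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    free <- if (is.numeric(rx$kinetic_law)) character() else all.vars(rx$kinetic_law)
    unk <- setdiff(free, known)
    if (length(unk))
      stop("kinetic law of reaction '", rx$id, "' has unresolvable symbol(s): ",
           paste(unk, collapse = ", "), call. = FALSE)
  }
  rids <- vapply(net$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id", call. = FALSE)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> '", x$id, "': ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$parameters),
      " parameters\n", sep = "")
  cat("  species:   ", paste(utils::head(x$species$id, 8), collapse = ", "),
      if (nrow(x$species) > 8) ", ..." else "", "\n", sep = "")
  if (length(x$reactions)) {
    rids <- vapply(x$reactions, `[[`, "", "id")
    cat("  reactions: ", paste(utils::head(rids, 8), collapse = ", "),
        if (length(rids) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.pd_reaction <- function(x, ...) {
  side <- function(v) if (length(v) == 0) "0" else
    paste(ifelse(v == 1, names(v), paste0(v, " ", names(v))), collapse = " + ")
  cat("<reaction> ", x$id, ": ", side(x$reactants),
      if (x$reversible) " <-> " else " -> ", side(x$products),
      "   v = ", deparse(x$kinetic_law), "\n", sep = "")
  invisible(x)
}

# internal: reaction ids in declaration order
reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

# internal: net stoichiometry matrix (species x reactions), boundary rows zeroed
stoichiometry_matrix <- function(net) {
  sids <- net$species$id
  rids <- reaction_ids(net)
  S <- matrix(0, nrow = length(sids), ncol = length(rids),
              dimnames = list(sids, rids))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (s in names(rx$reactants)) S[s, j] <- S[s, j] - rx$reactants[[s]]
    for (s in names(rx$products))  S[s, j] <- S[s, j] + rx$products[[s]]
  }
  S[net$species$boundary, ] <- 0
  S
}
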