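#' @name schemes
#' @title Mass-action binding reaction schemes
#'
#' @description
#' A binding mechanism is represented as a [reaction_scheme()]: a set of
#' species (each with a chemical role) plus elementary mass-action reactions
#' (unimolecular or bimolecular, optionally reversible). Five mechanisms of
#' ligand (L) binding to a receptor RNA (R) ship as presets:
#'
#' \describe{
#'   \item{model1}{one reversible bimolecular step: R + L <-> B.}
#'   \item{model2}{conformational selection: an inactive receptor
#'     pre-equilibrates with the binding-competent form
#'     (Rin <-> Ract, rates `k_pre`/`k_unpre`) which then binds ligand
#'     reversibly (Ract + L <-> B, rates `k_on`/`k_off`).}
#'   \item{model3}{two irreversible steps: R + L -> I -> B.}
#'   \item{model4}{induced fit, both steps reversible:
#'     R + L <-> I <-> B.}
#'   \item{model5}{reversible association then irreversible locking:
#'     R + L <-> I -> B.}
#' }
#'
#' I denotes the initial encounter complex and B the final ligand-bound
#' complex. Rate symbols follow the usual k1, k_m1 (= k-1), k2, k_m2
#' convention except for model2, where the preformation rates would collide
#' with the binding rates and are therefore namespaced (`k_pre`, `k_unpre`,
#' `k_on`, `k_off`); [paper_rate_labels()] maps them back to the
#' conventional k1...k-2 labels for reporting.
NULL

.species_roles <- c("receptor", "ligand", "intermediate-complex",
                    "final-complex", "inactive-receptor")

#' Define a species of a binding scheme
#'
#' @param name Species identifier (unique within a scheme).
#' @param role One of `"receptor"`, `"ligand"`, `"intermediate-complex"`,
#'   `"final-complex"`, `"inactive-receptor"`. The role determines which
#'   conservation pool (ligand and/or receptor) the species belongs to and
#'   which species carry fluorescence response factors.
#' @return A `species` object.
#' @export
species <- function(name, role) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, .species_roles)
  structure(list(name = name, role = role), class = "apt_species")
}

#' Define an elementary mass-action reaction
#'
#' Stoichiometry is 1 for every listed species: unimolecular steps have one
#' reactant, bimolecular steps two. A reaction with a `reverse` rate symbol
#' is treated as a reversible pair of elementary steps.
#'
#' @param reactants Character vector of 1 or 2 species names.
#' @param products Character vector of 1 or 2 species names.
#' @param forward Rate symbol (identifier) of the forward step.
#' @param reverse Rate symbol of the reverse step, or `NULL` for an
#'   irreversible reaction.
#' @return A `reaction` object.
#' @export
reaction <- function(reactants, products, forward, reverse = NULL) {
  stopifnot(is.character(reactants), length(reactants) %in% 1:2,
            is.character(products), length(products) %in% 1:2,
            is.character(forward), length(forward) == 1L)
  if (!is.null(reverse)) stopifnot(is.character(reverse), length(reverse) == 1L)
  structure(list(reactants = reactants, products = products,
                 forward = forward, reverse = reverse),
            class = "apt_reaction")
}

#' Assemble and validate a reaction scheme
#'
#' @param id Scheme identifier (`"model1"`..`"model5"` for the presets, or
#'   any user-chosen label).
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `reaction_scheme` object.
#' @details Validation enforces: unique species names; exactly one species
#'   with role ligand; every rate symbol used in exactly one reaction
#'   direction; every species appearing in at least one reaction; all
#'   reaction participants declared as species.
#' @export
reaction_scheme <- function(id, species, reactions) {
  stopifnot(is.character(id), length(id) == 1L, is.list(species),
            is.list(reactions), length(reactions) >= 1L)
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate species names: ", paste(nm[duplicated(nm)], collapse = ", "))
  roles <- vapply(species, function(s) s$role, character(1))
  if (sum(roles == "ligand") != 1L)
    stop("a scheme must contain exactly one species with role 'ligand'")
  syms <- unlist(lapply(reactions, function(r) c(r$forward, r$reverse)))
  if (anyDuplicated(syms))
    stop("rate symbol used in more than one reaction direction: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  used <- unique(unlist(lapply(reactions, function(r) c(r$reactants, r$products))))
  unknown <- setdiff(used, nm)
  if (length(unknown))
    stop("reaction references undeclared species: ", paste(unknown, collapse = ", "))
  idle <- setdiff(nm, used)
  if (length(idle))
    stop("species not appearing in any reaction: ", paste(idle, collapse = ", "))
  structure(list(id = id, species = species, reactions = reactions),
            class = "reaction_scheme")
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat("<reaction_scheme '", x$id, "'>\n", sep = "")
  for (r in x$reactions) {
    arrow <- if (is.null(r$reverse)) paste0(" --", r$forward, "--> ")
             else paste0(" <=", r$forward, "/", r$reverse, "=> ")
    cat(" ", paste(r$reactants, collapse = " + "), arrow,
        paste(r$products, collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Species names of a scheme
#' @param scheme A [reaction_scheme()].
#' @return Character vector of species names, in declaration order.
#' @export
species_names <- function(scheme) {
  vapply(scheme$species, function(s) s$name, character(1))
}

#' Species names of a given role
#' @param scheme A [reaction_scheme()].
#' @param roles Character vector of roles to select.
#' @return Character vector of matching species names.
#' @export
species_of_role <- function(scheme, roles) {
  nm <- species_names(scheme)
  rl <- vapply(scheme$species, function(s) s$role, character(1))
  nm[rl %in% roles]
}

#' Rate symbols required by a scheme
#' @param scheme A [reaction_scheme()].
#' @return Character vector of rate symbols, forward before reverse, in
#'   reaction order.
#' @export
rate_symbols <- function(scheme) {
  unlist(lapply(scheme$reactions, function(r) c(r$forward, r$reverse)))
}

#' Built-in binding schemes
#'
#' @param id One of `"model1"`..`"model5"` (see [schemes]).
#' @return A [reaction_scheme()].
#' @examples
#' scheme_preset("model4")
#' @export
scheme_preset <- function(id) {
  id <- match.arg(id, paste0("model", 1:5))
  switch(id,
    model1 = reaction_scheme("model1",
      list(species("R", "receptor"), species("L", "ligand"),
           species("B", "final-complex")),
      list(reaction(c("R", "L"), "B", "k1", "k_m1"))),
    model2 = reaction_scheme("model2",
      list(species("Rin", "inactive-receptor"), species("Ract", "receptor"),
           species("L", "ligand"), species("B", "final-complex")),
      list(reaction("Rin", "Ract", "k_pre", "k_unpre"),
           reaction(c("Ract", "L"), "B", "k_on", "k_off"))),
    model3 = reaction_scheme("model3",
      list(species("R", "receptor"), species("L", "ligand"),
           species("I", "intermediate-complex"), species("B", "final-complex")),
      list(reaction(c("R", "L"), "I", "k1"),
           reaction("I", "B", "k2"))),
    model4 = reaction_scheme("model4",
      list(species("R", "receptor"), species("L", "ligand"),
           species("I", "intermediate-complex"), species("B", "final-complex")),
      list(reaction(c("R", "L"), "I", "k1", "k_m1"),
           reaction("I", "B", "k2", "k_m2"))),
    model5 = reaction_scheme("model5",
      list(species("R", "receptor"), species("L", "ligand"),
           species("I", "intermediate-complex"), species("B", "final-complex")),
      list(reaction(c("R", "L"), "I", "k1", "k_m1"),
           reaction("I", "B", "k2"))))
}

#' Conventional labels for a scheme's rate symbols
#'
#' Maps the package's namespaced rate symbols to the conventional
#' k1, k-1, k2, k-2 labels used in kinetic tables.
#'
#' @param scheme A [reaction_scheme()].
#' @return Named character vector: names are the scheme's rate symbols,
#'   values the display labels.
#' @export
paper_rate_labels <- function(scheme) {
  syms <- rate_symbols(scheme)
  if (identical(scheme$id, "model2")) {
    lab <- c(k_pre = "k1", k_unpre = "k-1", k_on = "k2", k_off = "k-2")
    return(lab[syms])
  }
  setNames(gsub("^k_m", "k-", syms), syms)
}

#' Serialize a scheme to a JSON config string
#'
#' The five presets and any user-defined scheme round-trip losslessly
#' through this plain-text representation.
#'
#' @param scheme A [reaction_scheme()].
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
scheme_to_config <- function(scheme, path = NULL) {
  obj <- list(
    id = scheme$id,
    species = lapply(scheme$species, function(s) list(name = s$name, role = s$role)),
    reactions = lapply(scheme$reactions, function(r) {
      out <- list(reactants = as.list(r$reactants), products = as.list(r$products),
                  forward = r$forward)
      if (!is.null(r$reverse)) out$reverse <- r$reverse
      out
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Read a scheme from a JSON config
#' @param path File path, or a JSON string.
#' @return A validated [reaction_scheme()].
#' @export
scheme_from_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reaction_scheme(
    id = obj$id,
    species = lapply(obj$species, function(s) species(s$name, s$role)),
    reactions = lapply(obj$reactions, function(r)
      reaction(unlist(r$reactants), unlist(r$products), r$forward,
               if (!is.null(r$reverse)) r$reverse)))
}
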