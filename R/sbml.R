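# SBML Level 2 (V4) / Level 3 (V1) core subset: species, compartments,
# parameters, reactions with MathML kinetic laws. Events, rules, function
# definitions, constraints, piecewise and delay math are rejected with an
# unsupported-feature error: intervention regimes are supplied externally.

SBML_UNSUPPORTED_LISTS <- c("listOfEvents", "listOfRules",
                            "listOfFunctionDefinitions", "listOfConstraints",
                            "listOfInitialAssignments")

# ---- MathML <-> R expression -------------------------------------------------

mathml_op_map <- c(plus = "+", minus = "-", times = "*", divide = "/",
                   power = "^")

# parse a (namespace-stripped) MathML element into an R language object
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("malformed <math> element (expected one child)", call. = FALSE)
    return(mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(parse_cn(node))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url, fixed = TRUE)) return(as.name("time"))
    if (!is.na(url) && grepl("delay", url, fixed = TRUE))
      stop("unsupported math construct: delay", call. = FALSE)
    stop("unsupported math construct: csymbol '", url, "'", call. = FALSE)
  }
  if (nm == "pi") return(as.name("pi"))
  if (nm %in% c("piecewise", "lambda"))
    stop("unsupported math construct: ", nm, call. = FALSE)
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    if (!op %in% names(mathml_op_map))
      stop("unsupported math construct: operator '", op, "'", call. = FALSE)
    rop <- as.name(mathml_op_map[[op]])
    if (op == "minus" && length(args) == 1L) return(as.call(c(rop, args)))
    if (length(args) < 2L)
      stop("malformed <apply> for operator '", op, "'", call. = FALSE)
    out <- args[[1]]
    for (a in args[-1]) out <- as.call(list(rop, out, a))
    return(out)
  }
  stop("unsupported math construct: <", nm, ">", call. = FALSE)
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) type <- "real"
  txt <- xml2::xml_text(node)
  if (type %in% c("real", "integer")) return(as.numeric(trimws(txt)))
  if (type == "e-notation" || type == "rational") {
    parts <- strsplit(trimws(txt), "\\s+")[[1]]
    parts <- as.numeric(parts[nzchar(parts)])
    if (length(parts) != 2L || any(!is.finite(parts)))
      stop("malformed <cn type='", type, "'>", call. = FALSE)
    return(if (type == "e-notation") parts[1] * 10^parts[2]
           else parts[1] / parts[2])
  }
  stop("unsupported math construct: <cn type='", type, "'>", call. = FALSE)
}

# serialize an R language object to MathML (content markup), as a string
expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(num_to_cn(e))
  if (is.name(e)) {
    s <- as.character(e)
    if (s == "time")
      return(paste0('<csymbol encoding="text" definitionURL=',
                    '"http://www.sbml.org/sbml/symbols/time"> time </csymbol>'))
    return(paste0("<ci> ", s, " </ci>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_to_mathml(e[[2]]))
    mop <- names(mathml_op_map)[match(op, mathml_op_map)]
    if (is.na(mop))
      stop("cannot serialize operator '", op, "' to SBML math", call. = FALSE)
    args <- vapply(as.list(e)[-1], expr_to_mathml, "")
    return(paste0("<apply><", mop, "/>", paste(args, collapse = ""),
                  "</apply>"))
  }
  stop("cannot serialize kinetic law component of class ", class(e)[1],
       call. = FALSE)
}

num_to_cn <- function(x) {
  if (x == round(x) && abs(x) < 1e15)
    paste0('<cn type="integer"> ', format(x, scientific = FALSE), " </cn>")
  else
    paste0("<cn> ", sprintf("%.17g", x), " </cn>")
}

# substitute symbols in a language object (old name -> new name)
rename_symbols <- function(e, map) {
  if (is.name(e)) {
    s <- as.character(e)
    if (s %in% names(map)) return(as.name(map[[s]]))
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- rename_symbols(e[[i]], map)
    return(e)
  }
  e
}

# ---- reading -----------------------------------------------------------------

#' Load an SBML model into a reaction network
#'
#' Supports the SBML Level 2 / Level 3 core subset: compartments (constant
#' volume), species (amounts are converted to concentrations by dividing by
#' the compartment volume), global and reaction-local parameters (local ones
#' are namespaced as `<reaction>__<parameter>`), and reactions with MathML
#' kinetic laws over `+ - * / power`. Events, rules, function definitions and
#' piecewise/delay math raise an unsupported-feature error; interventions are
#' expressed externally as [regime()]s instead.
#'
#' @param path Path to an SBML file.
#' @return A [reaction_network()].
#' @export
load_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML format error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("SBML format error: root element is <", xml2::xml_name(root),
         ">, expected <sbml>", call. = FALSE)
  level <- xml2::xml_attr(root, "level")
  if (!level %in% c("2", "3"))
    stop("unsupported SBML level: ", level, call. = FALSE)
  model <- xml2::xml_find_first(root, "./model")
  if (inherits(model, "xml_missing"))
    stop("SBML format error: missing <model> element", call. = FALSE)

  for (l in SBML_UNSUPPORTED_LISTS) {
    node <- xml2::xml_find_first(model, paste0("./", l))
    if (!inherits(node, "xml_missing") && length(xml2::xml_children(node)))
      stop("unsupported SBML feature: ", l, call. = FALSE)
  }

  attr_or <- function(node, a, default) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  if (length(comp_nodes)) {
    comps <- vapply(comp_nodes, function(n)
      as.numeric(attr_or(n, "size", "1")), 0)
    names(comps) <- xml2::xml_attr(comp_nodes, "id")
  } else comps <- c(default = 1)

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(sp_nodes))
    stop("SBML format error: model declares no species", call. = FALSE)
  sp <- do.call(rbind, lapply(sp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    cid <- attr_or(n, "compartment", names(comps)[1])
    vol <- if (cid %in% names(comps)) comps[[cid]] else 1
    conc <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(conc)) {
      amt <- xml2::xml_attr(n, "initialAmount")
      conc <- if (is.na(amt)) 0 else as.numeric(amt) / vol
    } else conc <- as.numeric(conc)
    species(id, name = attr_or(n, "name", id),
            initial_concentration = conc,
            boundary = attr_or(n, "boundaryCondition", "false") == "true",
            compartment = cid)
  }))

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  params <- numeric()
  if (length(par_nodes)) {
    params <- vapply(par_nodes, function(n)
      as.numeric(attr_or(n, "value", "0")), 0)
    names(params) <- xml2::xml_attr(par_nodes, "id")
  }

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    n <- rx_nodes[[i]]
    rid <- xml2::xml_attr(n, "id")
    get_side <- function(xp) {
      refs <- xml2::xml_find_all(n, xp)
      if (!length(refs)) return(numeric())
      st <- vapply(refs, function(r) as.numeric(attr_or(r, "stoichiometry", "1")), 0)
      names(st) <- xml2::xml_attr(refs, "species")
      # collapse duplicate references to the same species
      tapply_named(st)
    }
    reac <- get_side("./listOfReactants/speciesReference")
    prod <- get_side("./listOfProducts/speciesReference")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(n, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("SBML format error: reaction '", rid, "' has no kineticLaw",
           call. = FALSE)
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      stop("SBML format error: kineticLaw of reaction '", rid,
           "' has no <math>", call. = FALSE)
    expr <- mathml_to_expr(math)
    # reaction-local parameters: namespace and hoist to global scope
    loc <- xml2::xml_find_all(
      kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    if (length(loc)) {
      lv <- vapply(loc, function(p) as.numeric(attr_or(p, "value", "0")), 0)
      lids <- xml2::xml_attr(loc, "id")
      map <- stats::setNames(paste0(rid, "__", lids), lids)
      expr <- rename_symbols(expr, as.list(map))
      names(lv) <- unname(map)
      params <- c(params, lv)
    }
    reactions[[i]] <- reaction(
      rid,
      reactants = reac, products = prod, modifiers = mods,
      kinetic_law = expr,
      reversible = attr_or(n, "reversible", if (level == "2") "true" else "false") == "true",
      name = attr_or(n, "name", rid))
  }

  reaction_network(sp, reactions, params, comps,
                   id = attr_or(model, "id", "model"))
}

tapply_named <- function(x) {
  if (!anyDuplicated(names(x))) return(x)
  out <- tapply(x, names(x), sum)
  stats::setNames(as.numeric(out), names(out))
}

# ---- writing -----------------------------------------------------------------

#' Write a reaction network as SBML Level 3 Version 1
#'
#' The emitted file re-loads via [load_sbml()] to a structurally equal
#' network (round-trip identity).
#'
#' @param net A valid [reaction_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  validate_network(net)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  ln <- character()
  add <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'level="3" version="1">')
  add('  <model id="', esc(net$id), '">')
  add('    <listOfCompartments>')
  for (cid in names(net$compartments))
    add('      <compartment id="', esc(cid), '" size="',
        num(net$compartments[[cid]]),
        '" spatialDimensions="3" constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    add('      <species id="', esc(s$id), '" name="', esc(s$name),
        '" compartment="', esc(s$compartment),
        '" initialConcentration="', num(s$initial_concentration),
        '" boundaryCondition="', if (s$boundary) "true" else "false",
        '" hasOnlySubstanceUnits="false" constant="false"/>')
  }
  add('    </listOfSpecies>')
  if (length(net$parameters)) {
    add('    <listOfParameters>')
    for (pid in names(net$parameters))
      add('      <parameter id="', esc(pid), '" value="',
          num(net$parameters[[pid]]), '" constant="true"/>')
    add('    </listOfParameters>')
  }
  add('    <listOfReactions>')
  for (rx in net$reactions) {
    add('      <reaction id="', esc(rx$id), '" name="', esc(rx$name),
        '" reversible="', if (rx$reversible) "true" else "false",
        '" fast="false">')
    side <- function(tag, v) {
      if (!length(v)) return()
      add('        <', tag, '>')
      for (s in names(v))
        add('          <speciesReference species="', esc(s),
            '" stoichiometry="', num(v[[s]]), '" constant="true"/>')
      add('        </', tag, '>')
    }
    side("listOfReactants", rx$reactants)
    side("listOfProducts", rx$products)
    if (length(rx$modifiers)) {
      add('        <listOfModifiers>')
      for (m in rx$modifiers)
        add('          <modifierSpeciesReference species="', esc(m), '"/>')
      add('        </listOfModifiers>')
    }
    add('        <kineticLaw>')
    add('          <math xmlns="http://www.w3.org/1998/Math/MathML">',
        expr_to_mathml(rx$kinetic_law), '</math>')
    add('        </kineticLaw>')
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ln, con, sep = "\n")
  invisible(path)
}

# ---- drug catalogue ----------------------------------------------------------

#' Load a drug catalogue and bind it to a network
#'
#' The catalogue is a delimited text file (comma or tab, autodetected) with
#' three columns: drug name, default dosage in nM, and the id of the species
#' the drug maps to in the model. A header row is optional.
#'
#' @param path Path to the catalogue file.
#' @param net The [reaction_network()] the catalogue targets.
#' @return A data frame of class `"drug_catalogue"` with columns
#'   `name`, `dosage_nM`, `target`.
#' @export
load_drug_catalogue <- function(path, net) {
  stopifnot(inherits(net, "reaction_network"))
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  empty <- data.frame(name = character(), dosage_nM = numeric(),
                      target = character(), stringsAsFactors = FALSE)
  class(empty) <- c("drug_catalogue", "data.frame")
  if (!length(raw)) return(empty)
  sep <- if (sum(grepl("\t", raw)) >= sum(grepl(",", raw))) "\t" else ","
  cells <- strsplit(raw, sep, fixed = TRUE)
  if (any(lengths(cells) < 3L))
    stop("catalogue rows need 3 fields (name, dosage_nM, target_species)",
         call. = FALSE)
  # optional header: second field of first row not numeric
  if (is.na(suppressWarnings(as.numeric(trimws(cells[[1]][2])))))
    cells <- cells[-1]
  if (!length(cells)) return(empty)
  cat_df <- data.frame(
    name = vapply(cells, function(r) trimws(r[1]), ""),
    dosage_nM = vapply(cells, function(r)
      suppressWarnings(as.numeric(trimws(r[2]))), 0),
    target = vapply(cells, function(r) trimws(r[3]), ""),
    stringsAsFactors = FALSE)
  if (anyNA(cat_df$dosage_nM))
    stop("catalogue dosage is not numeric", call. = FALSE)
  if (any(cat_df$dosage_nM < 0))
    stop("catalogue dosage must be non-negative", call. = FALSE)
  if (anyDuplicated(cat_df$name))
    stop("duplicate drug name in catalogue", call. = FALSE)
  missing_sp <- setdiff(cat_df$target, net$species$id)
  if (length(missing_sp))
    stop("catalogue targets species absent from the network: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  class(cat_df) <- c("drug_catalogue", "data.frame")
  cat_df
}
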