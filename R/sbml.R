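#' Parsed SBML model handle
#'
#' Wraps an SBML Level 2/3 core document (an `xml2` tree) behind typed
#' accessors. All curation transforms operate on deep copies, never on the
#' caller's tree.
#'
#' @param x raw vector, character scalar of XML, file path, or `xml2` document.
#' @return object of class `sbml_handle`.
#' @export
read_sbml <- function(x) {
  doc <- tryCatch({
    if (inherits(x, "xml_document")) x
    else if (is.raw(x)) xml2::read_xml(x)
    else if (is.character(x) && length(x) == 1 && !grepl("<", x)) xml2::read_xml(x)
    else xml2::read_xml(paste(x, collapse = "\n"))
  }, error = function(e) vk_stop("bad-model", conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    vk_stop("bad-model", paste("root element is", xml2::xml_name(root)))
  }
  structure(list(doc = doc), class = "sbml_handle")
}

#' @export
print.sbml_handle <- function(x, ...) {
  sp <- sbml_species(x); pa <- sbml_parameters(x); re <- sbml_reactions(x)
  cat("<sbml_handle> ", nrow(sp), " species, ", nrow(pa), " parameters, ",
      length(re), " reactions\n", sep = "")
  invisible(x)
}

#' Serialize an SBML handle back to bytes
#' @param model an `sbml_handle`.
#' @return raw vector of XML bytes.
#' @export
write_sbml <- function(model) {
  stopifnot(inherits(model, "sbml_handle"))
  charToRaw(as.character(model$doc))
}

sbml_copy <- function(model) {
  structure(list(doc = xml2::read_xml(as.character(model$doc))),
            class = "sbml_handle")
}

sbml_ns_uri <- function(model) {
  xml2::xml_ns(model$doc)[["d1"]] %||% ""
}

sbml_model_node <- function(model) {
  xml2::xml_find_first(model$doc, "./*[local-name()='model']")
}

# children of listOfX, ignoring namespaces
sb_list <- function(parent, list_name, item_name) {
  xml2::xml_find_all(parent, sprintf(
    "./*[local-name()='%s']/*[local-name()='%s']", list_name, item_name))
}

attr_or <- function(node, attr, default = NA_character_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

logical_attr <- function(node, attr, default = FALSE) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else identical(tolower(v), "true")
}

#' @rdname sbml_accessors
#' @export
sbml_species <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfSpecies", "species")
  data.frame(
    id = vapply(nodes, function(n) attr_or(n, "id"), ""),
    compartment = vapply(nodes, function(n) attr_or(n, "compartment"), ""),
    initial_amount = vapply(nodes, function(n)
      parse_sbml_number(attr_or(n, "initialAmount")), 0),
    initial_concentration = vapply(nodes, function(n)
      parse_sbml_number(attr_or(n, "initialConcentration")), 0),
    constant = vapply(nodes, function(n) logical_attr(n, "constant"), TRUE),
    boundary = vapply(nodes, function(n)
      logical_attr(n, "boundaryCondition"), TRUE),
    substance_units_only = vapply(nodes, function(n)
      logical_attr(n, "hasOnlySubstanceUnits"), TRUE),
    stringsAsFactors = FALSE
  )
}

#' SBML component accessors
#'
#' Tabular views over the parsed document: species, global parameters,
#' compartments, rules, initial assignments, function definitions, reactions.
#' @param model an `sbml_handle`.
#' @name sbml_accessors
#' @return data frames (or lists of records for reactions/rules) in document
#'   order.
#' @export
sbml_parameters <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfParameters", "parameter")
  data.frame(
    id = vapply(nodes, function(n) attr_or(n, "id"), ""),
    value = vapply(nodes, function(n) parse_sbml_number(attr_or(n, "value")), 0),
    constant = vapply(nodes, function(n) logical_attr(n, "constant", TRUE),
                      TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname sbml_accessors
#' @export
sbml_compartments <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfCompartments", "compartment")
  data.frame(
    id = vapply(nodes, function(n) attr_or(n, "id"), ""),
    size = vapply(nodes, function(n) {
      v <- parse_sbml_number(attr_or(n, "size"))
      if (is.na(v)) v <- parse_sbml_number(attr_or(n, "volume"))
      if (is.na(v)) 1 else v
    }, 0),
    constant = vapply(nodes, function(n) logical_attr(n, "constant", TRUE),
                      TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname sbml_accessors
#' @export
sbml_rules <- function(model) {
  lo <- xml2::xml_find_all(sbml_model_node(model),
                           "./*[local-name()='listOfRules']/*")
  lapply(lo, function(n) {
    nm <- xml2::xml_name(n)
    type <- switch(nm, assignmentRule = "assignment", rateRule = "rate",
                   algebraicRule = "algebraic", nm)
    math <- xml2::xml_find_first(n, "./*[local-name()='math']")
    list(type = type, variable = attr_or(n, "variable"),
         math = if (!inherits(math, "xml_missing")) parse_mathml(math))
  })
}

#' @rdname sbml_accessors
#' @export
sbml_initial_assignments <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfInitialAssignments",
                   "initialAssignment")
  lapply(nodes, function(n) {
    math <- xml2::xml_find_first(n, "./*[local-name()='math']")
    list(symbol = attr_or(n, "symbol"),
         math = if (!inherits(math, "xml_missing")) parse_mathml(math))
  })
}

#' @rdname sbml_accessors
#' @export
sbml_function_definitions <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfFunctionDefinitions",
                   "functionDefinition")
  out <- lapply(nodes, function(n) {
    lam <- xml2::xml_find_first(
      n, "./*[local-name()='math']/*[local-name()='lambda']")
    bvars <- xml2::xml_find_all(
      lam, "./*[local-name()='bvar']/*[local-name()='ci']")
    body_node <- xml2::xml_children(lam)
    body_node <- body_node[xml2::xml_name(body_node) != "bvar"]
    list(id = attr_or(n, "id"),
         args = vapply(bvars, function(b) trimws(xml2::xml_text(b)), ""),
         body = parse_mathml(body_node[[1]]))
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' @rdname sbml_accessors
#' @export
sbml_reactions <- function(model) {
  nodes <- sb_list(sbml_model_node(model), "listOfReactions", "reaction")
  lapply(nodes, function(n) {
    refs <- function(list_name) {
      rr <- sb_list(n, list_name, "speciesReference")
      data.frame(
        species = vapply(rr, function(r) attr_or(r, "species"), ""),
        stoichiometry = vapply(rr, function(r) {
          v <- parse_sbml_number(attr_or(r, "stoichiometry"))
          if (is.na(v)) 1 else v
        }, 0),
        stringsAsFactors = FALSE)
    }
    kl <- xml2::xml_find_first(n, "./*[local-name()='kineticLaw']")
    math <- NULL; locals <- data.frame(id = character(), value = numeric())
    if (!inherits(kl, "xml_missing")) {
      m <- xml2::xml_find_first(kl, "./*[local-name()='math']")
      if (!inherits(m, "xml_missing")) math <- parse_mathml(m)
      lp <- c(sb_list(kl, "listOfLocalParameters", "localParameter"),
              sb_list(kl, "listOfParameters", "parameter"))
      locals <- data.frame(
        id = vapply(lp, function(p) attr_or(p, "id"), ""),
        value = vapply(lp, function(p)
          parse_sbml_number(attr_or(p, "value")), 0),
        stringsAsFactors = FALSE)
    }
    list(id = attr_or(n, "id"),
         reversible = logical_attr(n, "reversible", FALSE),
         reactants = refs("listOfReactants"),
         products = refs("listOfProducts"),
         kinetic_math = math,
         local_parameters = locals)
  })
}

# every id defined anywhere in the model (for target resolution)
sbml_all_ids <- function(model) {
  nodes <- xml2::xml_find_all(sbml_model_node(model), ".//*[@id]")
  unique(c(attr_or(sbml_model_node(model), "id", character(0)),
           vapply(nodes, function(n) xml2::xml_attr(n, "id"), "")))
}

# Does the model use constructs outside the supported ODE subset?
sbml_unsupported_features <- function(model) {
  mn <- sbml_model_node(model)
  feats <- character(0)
  if (length(sb_list(mn, "listOfEvents", "event")) > 0) feats <- c(feats, "event")
  if (length(xml2::xml_find_all(
    mn, "./*[local-name()='listOfRules']/*[local-name()='algebraicRule']")) > 0) {
    feats <- c(feats, "algebraicRule")
  }
  if (length(xml2::xml_find_all(
    mn, ".//*[local-name()='csymbol'][contains(@definitionURL,'delay')]")) > 0) {
    feats <- c(feats, "delay")
  }
  if (length(sb_list(mn, "listOfConstraints", "constraint")) > 0) {
    feats <- c(feats, "constraint")
  }
  feats
}
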