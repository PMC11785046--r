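# SBML-side fixes and workarounds: meaning-preserving transforms that let
# engines with narrower capability run a model unchanged in semantics.

prep_log <- function(code = character(), location = character(),
                     before = character(), after = character()) {
  data.frame(code = as.character(code), location = as.character(location),
             before = as.character(before), after = as.character(after),
             stringsAsFactors = FALSE)
}

# Inline user-defined function calls into an expression.
inline_functions <- function(expr, fdefs) {
  if (!is.call(expr)) return(expr)
  op <- expr[[1]]
  args <- lapply(as.list(expr)[-1], inline_functions, fdefs = fdefs)
  if (is.name(op) && as.character(op) %in% names(fdefs)) {
    fd <- fdefs[[as.character(op)]]
    if (length(args) != length(fd$args)) {
      vk_stop("unsupported-mathml",
              paste("arity mismatch calling", as.character(op)))
    }
    return(expr_substitute(fd$body, stats::setNames(args, fd$args)))
  }
  as.call(c(op, args))
}

# Numeric environment of every quantity resolvable at t = 0, before rules.
# Species values follow their unit convention (amount when
# hasOnlySubstanceUnits, concentration otherwise).
model_initial_env <- function(model) {
  env <- list(time = 0)
  comp <- sbml_compartments(model)
  for (i in seq_len(nrow(comp))) env[[comp$id[i]]] <- comp$size[i]
  par <- sbml_parameters(model)
  for (i in seq_len(nrow(par))) env[[par$id[i]]] <- par$value[i]
  sp <- sbml_species(model)
  for (i in seq_len(nrow(sp))) {
    size <- if (sp$compartment[i] %in% comp$id)
      comp$size[comp$id == sp$compartment[i]] else 1
    amt <- sp$initial_amount[i]
    conc <- sp$initial_concentration[i]
    val <- if (sp$substance_units_only[i]) {
      if (!is.na(amt)) amt else conc * size
    } else {
      if (!is.na(conc)) conc else amt / size
    }
    env[[sp$id[i]]] <- val
  }
  env
}

#' Promote local kinetic-law parameters to global parameters
#'
#' Simulation engines differ in whether reaction-local parameters can be
#' inspected or changed at run time, so each local parameter is lifted to a
#' global parameter named `<reactionId>_<localId>` (deduplicated with numeric
#' suffixes `_2`, `_3`, ... against existing ids) and the kinetic-law math is
#' rewritten to the new id. The transform preserves trajectories exactly.
#'
#' @param model an `sbml_handle`.
#' @return list with `model` (transformed copy) and `renames`, a data frame
#'   with columns `reaction`, `old`, `new`.
#' @export
promote_local_parameters <- function(model) {
  model <- sbml_copy(model)
  mn <- sbml_model_node(model)
  renames <- data.frame(reaction = character(), old = character(),
                        new = character(), stringsAsFactors = FALSE)
  taken <- sbml_all_ids(model)
  reactions <- sb_list(mn, "listOfReactions", "reaction")
  for (rn in reactions) {
    rid <- attr_or(rn, "id", "reaction")
    kl <- xml2::xml_find_first(rn, "./*[local-name()='kineticLaw']")
    if (inherits(kl, "xml_missing")) next
    lps <- c(sb_list(kl, "listOfLocalParameters", "localParameter"),
             sb_list(kl, "listOfParameters", "parameter"))
    if (length(lps) == 0) next
    plist <- xml2::xml_find_first(mn, "./*[local-name()='listOfParameters']")
    if (inherits(plist, "xml_missing")) {
      plist <- xml2::xml_add_child(mn, "listOfParameters")
    }
    for (lp in lps) {
      old <- attr_or(lp, "id")
      new <- paste0(rid, "_", old)
      k <- 2
      while (new %in% taken) { new <- paste0(rid, "_", old, "_", k); k <- k + 1 }
      if (k > 1000) vk_stop("rename-failure", "cannot find free name")
      taken <- c(taken, new)
      gp <- xml2::xml_add_child(plist, "parameter", id = new,
                                value = attr_or(lp, "value", "0"),
                                constant = "true")
      invisible(gp)
      # rewrite ci references inside this kinetic law only (local scope)
      cis <- xml2::xml_find_all(kl, ".//*[local-name()='ci']")
      for (ci in cis) {
        if (trimws(xml2::xml_text(ci)) == old) {
          xml2::xml_set_text(ci, paste0(" ", new, " "))
        }
      }
      renames <- rbind(renames,
                       data.frame(reaction = rid, old = old, new = new,
                                  stringsAsFactors = FALSE))
    }
    for (ln in c("listOfLocalParameters", "listOfParameters")) {
      lo <- xml2::xml_find_first(kl, sprintf("./*[local-name()='%s']", ln))
      if (!inherits(lo, "xml_missing")) xml2::xml_remove(lo)
    }
  }
  list(model = model, renames = renames)
}

#' Inline initial assignments as numeric initial values
#'
#' Evaluates every `initialAssignment` at t = 0 (in dependency order, with
#' function definitions inlined), writes the numeric result as the target's
#' initial value attribute, and removes the assignment. Needed for engines
#' that do not support initial assignments.
#'
#' @param model an `sbml_handle`.
#' @return transformed `sbml_handle` (copy).
#' @section Errors: `"cyclic-initial-assignments"` on a dependency cycle;
#'   `"unresolved-symbol"` when a formula references an unknown quantity.
#' @export
inline_initial_assignments <- function(model) {
  model <- sbml_copy(model)
  ias <- sbml_initial_assignments(model)
  if (length(ias) == 0) return(model)
  fdefs <- sbml_function_definitions(model)
  maths <- lapply(ias, function(ia) inline_functions(ia$math, fdefs))
  targets <- vapply(ias, `[[`, "", "symbol")
  deps <- stats::setNames(lapply(maths, function(m) {
    intersect(expr_symbols(m), targets)
  }), targets)
  order <- topo_sort(targets, deps, "cyclic-initial-assignments")
  env <- model_initial_env(model)
  values <- stats::setNames(numeric(length(targets)), targets)
  for (tgt in order) {
    m <- maths[[which(targets == tgt)]]
    syms <- expr_symbols(m)
    unknown <- setdiff(syms, names(env))
    if (length(unknown) > 0) {
      vk_stop("unresolved-symbol",
              paste("initial assignment for", tgt, "references",
                    paste(unknown, collapse = ", ")))
    }
    val <- eval(m, env, baseenv())
    env[[tgt]] <- val
    values[[tgt]] <- val
  }
  mn <- sbml_model_node(model)
  sp <- sbml_species(model)
  for (tgt in targets) {
    val <- values[[tgt]]
    node <- xml2::xml_find_first(mn, sprintf(".//*[@id='%s']", tgt))
    if (!inherits(node, "xml_missing")) {
      nm <- xml2::xml_name(node)
      if (nm == "species") {
        conc_based <- !sp$substance_units_only[sp$id == tgt]
        if (isTRUE(conc_based[1])) {
          xml2::xml_set_attr(node, "initialConcentration",
                             format_sbml_number(val))
          xml2::xml_set_attr(node, "initialAmount", NULL)
        } else {
          xml2::xml_set_attr(node, "initialAmount", format_sbml_number(val))
          xml2::xml_set_attr(node, "initialConcentration", NULL)
        }
      } else if (nm == "compartment") {
        xml2::xml_set_attr(node, "size", format_sbml_number(val))
      } else {
        xml2::xml_set_attr(node, "value", format_sbml_number(val))
      }
    }
  }
  lo <- xml2::xml_find_first(mn, "./*[local-name()='listOfInitialAssignments']")
  if (!inherits(lo, "xml_missing")) xml2::xml_remove(lo)
  model
}

# symbols referenced by any math, rule variable, or event in the document
sbml_used_symbols <- function(model) {
  mn <- sbml_model_node(model)
  cis <- xml2::xml_find_all(mn, ".//*[local-name()='ci']")
  used <- vapply(cis, function(n) trimws(xml2::xml_text(n)), "")
  vars <- xml2::xml_find_all(mn, ".//*[@variable]")
  used <- c(used, vapply(vars, function(n) xml2::xml_attr(n, "variable"), ""))
  syms <- xml2::xml_find_all(
    mn, "./*[local-name()='listOfInitialAssignments']/*[@symbol]")
  used <- c(used, vapply(syms, function(n) xml2::xml_attr(n, "symbol"), ""))
  unique(used)
}

#' Reset non-finite unused parameters
#'
#' Parameters initialized to infinity or NaN that are referenced by no math
#' expression, rule, or event anywhere in the model cannot affect results;
#' they are reset to 0 and logged. A non-finite parameter that IS used is a
#' modeling error this function refuses to paper over: it is reported as a
#' fatal issue and left unchanged.
#'
#' @param model an `sbml_handle`.
#' @return list with `model` (copy), `log` (repair-style data frame), and
#'   `issues` (code `nonfinite-used-parameter` rows, empty when none).
#' @export
scrub_nonfinite_parameters <- function(model) {
  model <- sbml_copy(model)
  used <- sbml_used_symbols(model)
  log <- prep_log(); issues <- vk_no_issues()
  mn <- sbml_model_node(model)
  nodes <- sb_list(mn, "listOfParameters", "parameter")
  for (n in nodes) {
    val <- parse_sbml_number(attr_or(n, "value"))
    if (is.na(val) && !is.nan(val)) next
    if (is.finite(val)) next
    id <- attr_or(n, "id")
    if (id %in% used) {
      issues <- rbind_issues(issues, vk_issues(
        "nonfinite-used-parameter", id,
        sprintf("parameter %s = %s is referenced by model math", id,
                attr_or(n, "value"))))
    } else {
      log <- rbind(log, prep_log("scrub-nonfinite-parameter", id,
                                 attr_or(n, "value"), "0"))
      xml2::xml_set_attr(n, "value", "0")
    }
  }
  list(model = model, log = log, issues = issues)
}

# Very small structural validation of visualization-package subtrees: every
# layout needs a dimensions child; every render colorDefinition needs an id.
package_subtree_valid <- function(node) {
  nm <- xml2::xml_name(node)
  if (grepl("listOfLayouts|layout", nm, ignore.case = TRUE)) {
    layouts <- xml2::xml_find_all(node, ".//*[local-name()='layout']")
    if (xml2::xml_name(node) == "layout") layouts <- c(layouts, node)
    for (l in layouts) {
      dim <- xml2::xml_find_first(l, "./*[local-name()='dimensions']")
      if (inherits(dim, "xml_missing")) return(FALSE)
    }
  }
  cds <- xml2::xml_find_all(node, ".//*[local-name()='colorDefinition']")
  for (cd in cds) {
    if (is.na(xml2::xml_attr(cd, "id"))) return(FALSE)
  }
  TRUE
}

#' Remove invalid visualization-package payloads
#'
#' Layout/Render package subtrees that fail package-level structural
#' validation are removed (they carry only visualization data, so the core
#' model simulates identically); valid subtrees are retained.
#'
#' @param model an `sbml_handle`.
#' @return list with `model` (copy) and `log`.
#' @export
strip_invalid_package_payloads <- function(model) {
  model <- sbml_copy(model)
  mn <- sbml_model_node(model)
  log <- prep_log()
  kids <- xml2::xml_children(mn)
  nsdef <- tryCatch(xml2::xml_ns(model$doc), error = function(e) character(0))
  for (k in kids) {
    qname <- xml2::xml_name(k, ns = nsdef)
    full_uri <- if (grepl(":", qname)) {
      pref <- sub(":.*$", "", qname)
      nsdef[[pref]] %||% ""
    } else ""
    is_pkg <- grepl("layout|render", full_uri, ignore.case = TRUE) ||
      grepl("listOfLayouts|renderInformation", xml2::xml_name(k),
            ignore.case = TRUE)
    if (!is_pkg) next
    if (!package_subtree_valid(k)) {
      log <- rbind(log, prep_log("strip-invalid-package", xml2::xml_name(k),
                                 "invalid package subtree", "removed"))
      xml2::xml_remove(k)
    }
  }
  list(model = model, log = log)
}

#' Default ontology prefix registry for annotation checking
#'
#' Maps common ontology prefixes (case-insensitive match) to regular
#' expressions their full identifiers must satisfy.
#' @return named list of regex strings.
#' @export
default_prefix_registry <- function() {
  list(
    GO = "^GO:\\d{7}$",
    CHEBI = "^CHEBI:\\d+$",
    UNIPROT = "^[A-NR-Z0-9][A-Z0-9]{5,9}$",
    KEGG.COMPOUND = "^C\\d{5}$",
    EC = "^\\d+\\.\\d+\\.\\d+\\.\\d+$",
    TAXONOMY = "^\\d+$",
    PUBMED = "^\\d+$",
    BIOMODELS.DB = "^(BIOMD|MODEL)\\d{10}$",
    SBO = "^SBO:\\d{7}$"
  )
}

#' Syntactic check of annotation resource URIs
#'
#' Every `rdf:resource` annotation URI is checked against a registry of known
#' ontology prefixes and identifier patterns: unknown (often misspelled)
#' prefixes yield `unknown-prefix`; URIs missing or malforming the identifier
#' segment yield `malformed-reference`. Purely syntactic; no network access.
#'
#' @param model an `sbml_handle`.
#' @param prefix_registry named list mapping prefixes to identifier regexes;
#'   defaults to [default_prefix_registry()].
#' @return issue data frame (`code`, `location`, `detail`).
#' @export
check_annotation_uris <- function(model,
                                  prefix_registry = default_prefix_registry()) {
  nodes <- xml2::xml_find_all(model$doc, ".//*[@*[local-name()='resource']]")
  iss <- vk_no_issues()
  names(prefix_registry) <- toupper(names(prefix_registry))
  for (n in nodes) {
    uri <- xml2::xml_attr(n, "resource")
    if (is.na(uri)) next
    if (!grepl("^https?://identifiers\\.org/", uri) &&
        !grepl("^urn:miriam:", uri)) {
      next  # other URI schemes are out of scope for this check
    }
    rest <- sub("^https?://identifiers\\.org/", "", uri)
    rest <- sub("^urn:miriam:", "", rest)
    rest <- gsub(":", "/", sub("%3A", ":", rest, fixed = TRUE))
    segs <- strsplit(rest, "/", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    last <- if (length(segs) > 0) segs[length(segs)] else ""
    if (grepl(":", last)) {
      prefix <- toupper(sub(":.*$", "", last))
      ident <- last
    } else if (length(segs) >= 2) {
      prefix <- toupper(segs[1])
      ident <- last
    } else {
      iss <- rbind_issues(iss, vk_issues("malformed-reference", uri,
                                         "identifier segment missing"))
      next
    }
    if (!(prefix %in% names(prefix_registry))) {
      iss <- rbind_issues(iss, vk_issues("unknown-prefix", uri,
                                         paste("prefix", prefix)))
      next
    }
    pat <- prefix_registry[[prefix]]
    if (!grepl(pat, ident) &&
        !grepl(pat, paste0(prefix, ":", ident))) {
      iss <- rbind_issues(iss, vk_issues("malformed-reference", uri,
                                         paste("identifier", ident)))
    }
  }
  iss
}

#' List the model's dynamic (time-varying) variables
#'
#' Species not declared constant (excluding purely constant boundary species
#' that no rule governs), plus non-species quantities governed by rate or
#' assignment rules, in document order. This single definition of "variable
#' species" is shared by template generation and the engines.
#'
#' @param model an `sbml_handle`.
#' @return character vector of ids.
#' @export
list_dynamic_variables <- function(model) {
  sp <- sbml_species(model)
  rules <- sbml_rules(model)
  ruled <- vapply(rules, function(r) r$variable %||% NA_character_, "")
  out <- character(0)
  for (i in seq_len(nrow(sp))) {
    if (sp$constant[i]) next
    if (sp$boundary[i] && !(sp$id[i] %in% ruled)) next
    out <- c(out, sp$id[i])
  }
  par <- sbml_parameters(model)
  comp <- sbml_compartments(model)
  for (id in ruled[!is.na(ruled)]) {
    if (id %in% c(par$id, comp$id)) out <- c(out, id)
  }
  unique(out)
}
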