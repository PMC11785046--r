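# Synthetic fixtures: mass-action chain models with Bateman closed forms,
# multi-scale initial values, and deliberately defective entries. Everything
# the pipeline needs to be exercised is generated here, offline, as a pure
# function of arguments and seed.

SBML_L3V2_NS <- "http://www.sbml.org/sbml/level3/version2/core"

#' Kinds of deliberate defects
#'
#' The defect catalogue mirrors what turns up in legacy curated entries:
#' fictitious `model.xml` sources, pointers to nonexistent model elements,
#' never-used simulations, duplicated ids, unprefixed pointers, requests for
#' millions of output points, parameters initialized to NaN/infinity, and
#' invalid visualization-package payloads.
#' @export
DEFECT_KINDS <- c("model-xml-source", "dangling-target", "unused-simulation",
                  "duplicate-id", "malformed-target", "excessive-points",
                  "nonfinite-parameter", "invalid-package-payload")

#' Generate an irreversible unimolecular mass-action chain model
#'
#' Builds valid SBML L3V2 for `S1 -> S2 -> ... -> Sn` in one unit
#' compartment, with mass-action kinetics `v_i = k_i * S_i`. Species carry
#' amounts (`hasOnlySubstanceUnits`), so with distinct rate constants the
#' Bateman closed form ([chain_closed_form()]) is the exact solution — the
#' analytic oracle the reference engine is verified against.
#'
#' @param n_species chain length (>= 1).
#' @param rate_constants `n_species - 1` positive rates.
#' @param initial_amounts `n_species` non-negative initial amounts.
#' @param local_params store rates as reaction-local parameters instead of
#'   globals (exercises local-parameter promotion).
#' @param model_id SBML model id.
#' @return raw vector of SBML bytes.
#' @section Errors: `"bad-spec"` on length mismatch.
#' @export
make_chain_model <- function(n_species, rate_constants, initial_amounts,
                             local_params = FALSE, model_id = "chain") {
  n_species <- as.integer(n_species)
  if (n_species < 1 || length(initial_amounts) != n_species ||
      length(rate_constants) != n_species - 1L) {
    vk_stop("bad-spec", sprintf(
      "need %d initial values and %d rate constants", n_species,
      max(n_species - 1L, 0L)))
  }
  if (any(rate_constants <= 0) || any(initial_amounts < 0)) {
    vk_stop("bad-spec", "rates must be positive, initial amounts non-negative")
  }
  root <- xml2::xml_new_root("sbml", xmlns = SBML_L3V2_NS,
                             level = "3", version = "2")
  mod <- xml2::xml_add_child(root, "model", id = model_id)
  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "c", size = "1",
                      spatialDimensions = "3", constant = "true")
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(n_species)) {
    xml2::xml_add_child(los, "species", id = paste0("S", i),
                        compartment = "c",
                        initialAmount = format_sbml_number(initial_amounts[i]),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  if (!local_params && n_species > 1) {
    lop <- xml2::xml_add_child(mod, "listOfParameters")
    for (i in seq_len(n_species - 1L)) {
      xml2::xml_add_child(lop, "parameter", id = paste0("k", i),
                          value = format_sbml_number(rate_constants[i]),
                          constant = "true")
    }
  }
  if (n_species > 1) {
    lor <- xml2::xml_add_child(mod, "listOfReactions")
    for (i in seq_len(n_species - 1L)) {
      rx <- xml2::xml_add_child(lor, "reaction", id = paste0("J", i),
                                reversible = "false")
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      xml2::xml_add_child(lre, "speciesReference",
                          species = paste0("S", i), stoichiometry = "1",
                          constant = "true")
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      xml2::xml_add_child(lpr, "speciesReference",
                          species = paste0("S", i + 1), stoichiometry = "1",
                          constant = "true")
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      kname <- if (local_params) "k" else paste0("k", i)
      math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      ci1 <- xml2::xml_add_child(ap, "ci"); xml2::xml_set_text(ci1, kname)
      ci2 <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci2, paste0("S", i))
      if (local_params) {
        llp <- xml2::xml_add_child(kl, "listOfLocalParameters")
        xml2::xml_add_child(llp, "localParameter", id = "k",
                            value = format_sbml_number(rate_constants[i]))
      }
    }
  }
  charToRaw(as.character(root))
}

#' Bateman closed form of the linear decay chain
#'
#' Exact solution of `S1 -> S2 -> ... -> Sn` with distinct positive rates,
#' by superposition of Bateman chains started from each species' initial
#' amount. The terminal species has removal rate zero. Serves as the
#' analytic oracle, fully independent of the numeric integrator.
#'
#' @param rate_constants `n - 1` distinct positive rates.
#' @param initial_amounts `n` initial amounts.
#' @param times numeric vector of evaluation times.
#' @return matrix `length(times) x n`, columns named `S1..Sn`.
#' @section Errors: `"degenerate-rates"` for repeated rate constants (the
#'   distinct-rate Bateman formula does not apply).
#' @export
chain_closed_form <- function(rate_constants, initial_amounts, times) {
  n <- length(initial_amounts)
  stopifnot(length(rate_constants) == n - 1)
  if (anyDuplicated(rate_constants) || any(rate_constants == 0)) {
    vk_stop("degenerate-rates", "rate constants must be distinct and nonzero")
  }
  k <- c(rate_constants, 0)  # terminal species decays at rate 0
  out <- matrix(0, nrow = length(times), ncol = n,
                dimnames = list(NULL, paste0("S", seq_len(n))))
  for (i in seq_len(n)) {
    a0 <- initial_amounts[i]
    if (a0 == 0) next
    for (j in i:n) {
      kk <- k[i:j]
      prod_rates <- if (j > i) prod(k[i:(j - 1)]) else 1
      contrib <- numeric(length(times))
      for (m in seq_along(kk)) {
        denom <- prod(kk[-m] - kk[m])
        if (length(kk) == 1) denom <- 1
        contrib <- contrib + exp(-kk[m] * times) / denom
      }
      out[, j] <- out[, j] + a0 * prod_rates * contrib
    }
  }
  out
}

#' Generate a stiff mass-action model with multi-scale initial values
#'
#' Species `S1..Sn` start at `10^scale_i`. With three or more species the
#' first three are coupled by the classic stiff autocatalytic triad
#' (`S1 -> S2` slow; `2 S2 -> S2 + S3` fast bimolecular;
#' `S2 + S3 -> S1 + S3`), whose intermediate lives many orders of magnitude
#' below the bulk species; any further species hang off `S3` as a slow
#' linear chain. Total mass is conserved by every reaction. This is the
#' phenotype for which a loose scalar absolute tolerance silently wrecks
#' (or drives negative) the smallest variable while an
#' initial-value-scaled tolerance vector does not. With fewer than three
#' species a plain linear chain is emitted.
#'
#' @param scales numeric vector of decades (e.g. `c(0, -6, -12)`), one per
#'   species.
#' @param stiff_rates rates of the triad: slow feed, fast bimolecular,
#'   intermediate quench.
#' @return raw vector of SBML bytes; species `S1..Sn`.
#' @export
make_multiscale_model <- function(scales,
                                  stiff_rates = c(0.04, 3e7, 1e4)) {
  n <- length(scales)
  stopifnot(n >= 1)
  amounts <- 10^scales
  if (n < 3) {
    return(make_chain_model(n, if (n == 2) 0.7 else numeric(0), amounts,
                            model_id = "multiscale"))
  }
  root <- xml2::xml_new_root("sbml", xmlns = SBML_L3V2_NS,
                             level = "3", version = "2")
  mod <- xml2::xml_add_child(root, "model", id = "multiscale")
  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "c", size = "1",
                      spatialDimensions = "3", constant = "true")
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(n)) {
    xml2::xml_add_child(los, "species", id = paste0("S", i),
                        compartment = "c",
                        initialAmount = format_sbml_number(amounts[i]),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in 1:3) {
    xml2::xml_add_child(lop, "parameter", id = paste0("k", i),
                        value = format_sbml_number(stiff_rates[i]),
                        constant = "true")
  }
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  add_rx <- function(id, reactants, products, math_factors) {
    rx <- xml2::xml_add_child(lor, "reaction", id = id, reversible = "false")
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in names(reactants)) {
      xml2::xml_add_child(lre, "speciesReference", species = s,
                          stoichiometry = format(reactants[[s]]),
                          constant = "true")
    }
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (s in names(products)) {
      xml2::xml_add_child(lpr, "speciesReference", species = s,
                          stoichiometry = format(products[[s]]),
                          constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    for (f in math_factors) {
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci, f)
    }
  }
  add_rx("J1", c(S1 = 1), c(S2 = 1), c("k1", "S1"))
  add_rx("J2", c(S2 = 2), c(S2 = 1, S3 = 1), c("k2", "S2", "S2"))
  add_rx("J3", c(S2 = 1, S3 = 1), c(S1 = 1, S3 = 1), c("k3", "S2", "S3"))
  if (n > 3) {
    lop2 <- xml2::xml_find_first(mod, "./*[local-name()='listOfParameters']")
    for (i in 4:n) {
      kid <- paste0("k", i)
      xml2::xml_add_child(lop2, "parameter", id = kid,
                          value = format_sbml_number(0.1 + 0.05 * i),
                          constant = "true")
      add_rx(paste0("J", i), stats::setNames(1, paste0("S", i - 1)),
             stats::setNames(1, paste0("S", i)),
             c(kid, paste0("S", i - 1)))
    }
  }
  charToRaw(as.character(root))
}

#' Bundle model and experiment into a runnable archive
#'
#' @param model raw vector of SBML bytes (must parse).
#' @param sedml optional raw vector of SED-ML bytes.
#' @param model_location,sedml_location archive-internal paths.
#' @return an [omex_archive()] with the model as master.
#' @section Errors: `"bad-model"` when the model does not parse.
#' @export
make_entry <- function(model, sedml = NULL,
                       model_location = "biomodel.xml",
                       sedml_location = "simulation.sedml") {
  read_sbml(model)  # errors "bad-model" if unparseable
  entries <- data.frame(location = model_location,
                        format = omex_format_uri("sbml"), master = TRUE,
                        stringsAsFactors = FALSE)
  payload <- stats::setNames(list(model), model_location)
  if (!is.null(sedml)) {
    entries <- rbind(entries,
                     data.frame(location = sedml_location,
                                format = omex_format_uri("sedml"),
                                master = FALSE, stringsAsFactors = FALSE))
    payload[[sedml_location]] <- sedml
  }
  omex_archive(entries, payload)
}

# Convenience: chain model + its template experiment as a runnable archive.
make_template_entry <- function(model_bytes,
                                model_location = "biomodel.xml") {
  h <- read_sbml(model_bytes)
  doc <- build_template(h, model_location)
  make_entry(model_bytes, write_sedml(doc), model_location)
}

#' Inject a single deliberate defect into a valid entry
#'
#' Returns an archive exhibiting exactly the named defect and no other;
#' deterministic for a fixed seed (the seed only picks among equivalent
#' injection sites). Compound defects are built by chaining calls.
#'
#' @param base a valid, runnable [omex_archive()].
#' @param defect one of [DEFECT_KINDS].
#' @param seed integer.
#' @return defective [omex_archive()].
#' @section Errors: `"inapplicable-defect"` when the base lacks the
#'   structure the defect needs.
#' @export
make_defective_entry <- function(base, defect, seed = 1L) {
  defect <- match.arg(defect, DEFECT_KINDS)
  stopifnot(inherits(base, "omex_archive"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  sed_locs <- archive_locations_of(base, "sedml")
  sbml_locs <- archive_locations_of(base, "sbml")
  need_sedml <- !(defect %in% c("nonfinite-parameter",
                                "invalid-package-payload"))
  if (need_sedml && length(sed_locs) == 0) {
    vk_stop("inapplicable-defect", "base entry has no SED-ML")
  }

  if (need_sedml) {
    loc <- sort(sed_locs)[1]
    doc <- parse_sedml(base$payload[[loc]])
    doc <- switch(defect,
      "model-xml-source" = {
        if (length(doc$models) == 0) {
          vk_stop("inapplicable-defect", "document has no model")
        }
        doc$models[[1]]$source <- "model.xml"
        doc
      },
      "dangling-target" = {
        cand <- which(vapply(doc$data_generators, function(d) {
          any(vapply(d$variables, function(v) !is.na(v$target %||% NA),
                     logical(1)))
        }, logical(1)))
        if (length(cand) == 0) {
          vk_stop("inapplicable-defect", "no targeted data generator")
        }
        i <- cand[sample.int(length(cand), 1)]
        for (j in seq_along(doc$data_generators[[i]]$variables)) {
          v <- doc$data_generators[[i]]$variables[[j]]
          if (!is.na(v$target %||% NA)) {
            pt <- parse_target(v$target)
            doc$data_generators[[i]]$variables[[j]]$target <-
              gsub(paste0("'", pt$id, "'"),
                   paste0("'", pt$id, "_missing'"), v$target)
            break
          }
        }
        doc
      },
      "unused-simulation" = {
        if (length(doc$simulations) == 0) {
          vk_stop("inapplicable-defect", "document has no simulation")
        }
        extra <- doc$simulations[[1]]
        extra$id <- paste0(extra$id, "_unused")
        doc$simulations[[length(doc$simulations) + 1]] <- extra
        doc
      },
      "duplicate-id" = {
        if (length(doc$simulations) == 0) {
          vk_stop("inapplicable-defect", "document has no simulation")
        }
        doc$simulations[[length(doc$simulations) + 1]] <- doc$simulations[[1]]
        doc
      },
      "malformed-target" = {
        cand <- which(vapply(doc$data_generators, function(d) {
          any(vapply(d$variables, function(v) !is.na(v$target %||% NA),
                     logical(1)))
        }, logical(1)))
        if (length(cand) == 0) {
          vk_stop("inapplicable-defect", "no targeted data generator")
        }
        i <- cand[sample.int(length(cand), 1)]
        for (j in seq_along(doc$data_generators[[i]]$variables)) {
          v <- doc$data_generators[[i]]$variables[[j]]
          if (!is.na(v$target %||% NA)) {
            doc$data_generators[[i]]$variables[[j]]$target <-
              gsub("sbml:", "", v$target, fixed = TRUE)
            break
          }
        }
        doc
      },
      "excessive-points" = {
        utc <- which(vapply(doc$simulations, function(s) {
          identical(s$type, "uniformTimeCourse")
        }, logical(1)))
        if (length(utc) == 0) {
          vk_stop("inapplicable-defect", "no uniform time course")
        }
        doc$simulations[[utc[1]]]$number_of_steps <- 2000000L
        doc
      })
    base$payload[[loc]] <- write_sedml(doc)
  } else {
    if (length(sbml_locs) == 0) {
      vk_stop("inapplicable-defect", "base entry has no SBML")
    }
    loc <- sort(sbml_locs)[1]
    h <- read_sbml(base$payload[[loc]])
    mn <- sbml_model_node(h)
    if (defect == "nonfinite-parameter") {
      lop <- xml2::xml_find_first(mn, "./*[local-name()='listOfParameters']")
      if (inherits(lop, "xml_missing")) {
        lop <- xml2::xml_add_child(mn, "listOfParameters")
      }
      xml2::xml_add_child(lop, "parameter", id = "p_unused_nonfinite",
                          value = "NaN", constant = "true")
    } else {
      # a layout without its required dimensions child
      snippet <- xml2::read_xml(paste0(
        '<layout:listOfLayouts xmlns:layout=',
        '"http://www.sbml.org/sbml/level3/version1/layout/version1">',
        '<layout:layout layout:id="badLayout"/></layout:listOfLayouts>'))
      xml2::xml_add_child(mn, xml2::xml_root(snippet))
    }
    base$payload[[loc]] <- write_sbml(h)
  }
  base
}
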