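# SED-ML Level 1 Version 3/4: the uniform-time-course subset used for
# cross-engine verification. Documents are plain R lists behind constructor
# functions; XML I/O lives in parse_sedml()/write_sedml().

SEDML_NS <- c("1.3" = "http://sed-ml.org/sed-ml/level1/version3",
              "1.4" = "http://sed-ml.org/sed-ml/level1/version4")

#' KiSAO identifiers used by the pipeline
#'
#' CVODE-family deterministic ODE integration plus the algorithm parameters
#' the engines understand. The id of the absolute-tolerance adjustment factor
#' is configurable because engines registered it late; see
#' [solver_settings()].
#' @export
KISAO <- list(
  cvode = "KISAO:0000019",
  relative_tolerance = "KISAO:0000209",
  absolute_tolerance = "KISAO:0000211",
  max_internal_steps = "KISAO:0000415",
  seed = "KISAO:0000488",
  atol_adjustment_factor = "KISAO:0000571"
)

#' Construct SED-ML document components
#'
#' Builders for the in-memory representation: a document bundles models,
#' simulations, tasks, data generators, and outputs, all referenced by id.
#'
#' @param level,version SED-ML level/version, `(1,3)` or `(1,4)`.
#' @param models,simulations,tasks,data_generators,outputs lists of the
#'   respective component records.
#' @param notes character vector of parser notes (`unsupported-feature`,
#'   `duplicate-id`), empty for documents built in code.
#' @return list of class `sed_document`.
#' @export
sed_document <- function(models = list(), simulations = list(),
                         tasks = list(), data_generators = list(),
                         outputs = list(), level = 1L, version = 4L,
                         notes = character(0)) {
  structure(list(level = as.integer(level), version = as.integer(version),
                 models = models, simulations = simulations, tasks = tasks,
                 data_generators = data_generators, outputs = outputs,
                 notes = notes),
            class = "sed_document")
}

#' @rdname sed_document
#' @param id element id.
#' @param source model location (archive-relative path).
#' @param language model-language URN; defaults to SBML.
#' @param changes list of `list(target =, new_value =)` attribute changes.
#' @export
sed_model <- function(id, source,
                      language = "urn:sedml:language:sbml", changes = list()) {
  list(id = id, source = source, language = language, changes = changes)
}

#' @rdname sed_document
#' @param initial_time,output_start_time,output_end_time simulation times.
#' @param number_of_steps output intervals (>= 1); the output grid has
#'   `number_of_steps + 1` points.
#' @param algorithm KiSAO id of the integration algorithm.
#' @param algorithm_parameters named character vector, KiSAO id -> value.
#' @export
sed_uniform_timecourse <- function(id, initial_time = 0,
                                   output_start_time = 0,
                                   output_end_time = 10,
                                   number_of_steps = 100L,
                                   algorithm = KISAO$cvode,
                                   algorithm_parameters = character(0)) {
  list(id = id, type = "uniformTimeCourse",
       initial_time = as.numeric(initial_time),
       output_start_time = as.numeric(output_start_time),
       output_end_time = as.numeric(output_end_time),
       number_of_steps = as.integer(number_of_steps),
       algorithm = algorithm,
       algorithm_parameters = algorithm_parameters)
}

#' @rdname sed_document
#' @param model_ref,simulation_ref ids of the task's model and simulation.
#' @export
sed_task <- function(id, model_ref, simulation_ref) {
  list(id = id, model_ref = model_ref, simulation_ref = simulation_ref)
}

#' @rdname sed_document
#' @param variables list of `list(id =, task_ref =, target = or symbol =)`.
#' @param parameters named numeric vector of datagen-local constants.
#' @param math R expression over the variable/parameter ids (from
#'   `parse_mathml()` or built with `quote()`).
#' @export
sed_data_generator <- function(id, variables, math,
                               parameters = stats::setNames(numeric(0), character(0))) {
  list(id = id, variables = variables, parameters = parameters, math = math)
}

#' @rdname sed_document
#' @param kind `"report"` or `"plot2d"`.
#' @param items for a report, list of `list(label =, ref =)`; for a plot2d,
#'   list of `list(x =, y =)` data-generator references.
#' @export
sed_output <- function(kind = c("report", "plot2d"), id, items) {
  kind <- match.arg(kind)
  list(kind = kind, id = id, items = items)
}

TIME_SYMBOL <- "urn:sedml:symbol:time"

sed_all_ids <- function(doc) {
  c(vapply(doc$models, `[[`, "", "id"),
    vapply(doc$simulations, `[[`, "", "id"),
    vapply(doc$tasks, `[[`, "", "id"),
    vapply(doc$data_generators, `[[`, "", "id"),
    vapply(doc$outputs, `[[`, "", "id"))
}

#' @export
print.sed_document <- function(x, ...) {
  cat(sprintf("<sed_document L%dV%d> %d model(s), %d simulation(s), %d task(s), %d data generator(s), %d output(s)\n",
              x$level, x$version, length(x$models), length(x$simulations),
              length(x$tasks), length(x$data_generators), length(x$outputs)))
  if (length(x$notes) > 0) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Parse a SED-ML document
#'
#' Reads the supported subset (uniform time courses, attribute changes,
#' reports and 2D plots). Unsupported constructs (repeated tasks, steady
#' state, one-step, scans, 3D plots) are recorded as `unsupported-feature`
#' notes rather than silently dropped; duplicate ids are preserved with a
#' `duplicate-id` note, since fixing them is the repair module's job.
#'
#' @param content raw vector or character scalar of SED-ML XML.
#' @return a [sed_document()].
#' @section Errors: `"parse-error"` when the content is not XML.
#' @export
parse_sedml <- function(content) {
  doc <- tryCatch(xml2::read_xml(content),
                  error = function(e) vk_stop("parse-error",
                                              conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sedML") {
    vk_stop("parse-error", paste("root element is", xml2::xml_name(root)))
  }
  level <- as.integer(attr_or(root, "level", "1"))
  version <- as.integer(attr_or(root, "version", "4"))
  notes <- character(0)
  num_attr <- function(n, a, d = 0) {
    v <- xml2::xml_attr(n, a); if (is.na(v)) d else as.numeric(v)
  }

  models <- lapply(sb_list(root, "listOfModels", "model"), function(n) {
    changes <- lapply(sb_list(n, "listOfChanges", "changeAttribute"),
                      function(ch) list(target = attr_or(ch, "target"),
                                        new_value = attr_or(ch, "newValue")))
    sed_model(attr_or(n, "id"), attr_or(n, "source"),
              attr_or(n, "language", "urn:sedml:language:sbml"), changes)
  })

  sims <- list()
  for (n in xml2::xml_find_all(root,
                               "./*[local-name()='listOfSimulations']/*")) {
    nm <- xml2::xml_name(n)
    if (nm == "uniformTimeCourse") {
      steps_attr <- if (!is.na(xml2::xml_attr(n, "numberOfSteps")))
        "numberOfSteps" else "numberOfPoints"
      alg <- xml2::xml_find_first(n, "./*[local-name()='algorithm']")
      kisao <- if (!inherits(alg, "xml_missing")) attr_or(alg, "kisaoID",
                                                          KISAO$cvode)
               else KISAO$cvode
      ap <- character(0)
      if (!inherits(alg, "xml_missing")) {
        apn <- sb_list(alg, "listOfAlgorithmParameters", "algorithmParameter")
        if (length(apn) > 0) {
          ap <- stats::setNames(
            vapply(apn, function(p) attr_or(p, "value"), ""),
            vapply(apn, function(p) attr_or(p, "kisaoID"), ""))
        }
        nested <- xml2::xml_find_all(alg, ".//*[local-name()='algorithm']")
        if (length(nested) > 0) {
          notes <- c(notes, "unsupported-feature: nested algorithm")
        }
      }
      sims[[length(sims) + 1]] <- sed_uniform_timecourse(
        attr_or(n, "id"),
        num_attr(n, "initialTime"), num_attr(n, "outputStartTime"),
        num_attr(n, "outputEndTime"), as.integer(num_attr(n, steps_attr, 100)),
        kisao, ap)
    } else {
      notes <- c(notes, paste0("unsupported-feature: simulation type ", nm))
      sims[[length(sims) + 1]] <- list(id = attr_or(n, "id"), type = nm)
    }
  }

  tasks <- list()
  for (n in xml2::xml_find_all(root, "./*[local-name()='listOfTasks']/*")) {
    nm <- xml2::xml_name(n)
    if (nm == "task") {
      tasks[[length(tasks) + 1]] <- sed_task(attr_or(n, "id"),
                                             attr_or(n, "modelReference"),
                                             attr_or(n, "simulationReference"))
    } else {
      notes <- c(notes, paste0("unsupported-feature: task type ", nm))
    }
  }

  dgs <- lapply(sb_list(root, "listOfDataGenerators", "dataGenerator"),
                function(n) {
    vars <- lapply(sb_list(n, "listOfVariables", "variable"), function(v) {
      list(id = attr_or(v, "id"), task_ref = attr_or(v, "taskReference"),
           target = attr_or(v, "target", NA_character_),
           symbol = attr_or(v, "symbol", NA_character_))
    })
    pars_n <- sb_list(n, "listOfParameters", "parameter")
    pars <- stats::setNames(
      vapply(pars_n, function(p) as.numeric(attr_or(p, "value", "0")), 0),
      vapply(pars_n, function(p) attr_or(p, "id"), ""))
    mathn <- xml2::xml_find_first(n, "./*[local-name()='math']")
    math <- if (!inherits(mathn, "xml_missing")) parse_mathml(mathn)
    sed_data_generator(attr_or(n, "id"), vars, math, pars)
  })

  outs <- list()
  for (n in xml2::xml_find_all(root, "./*[local-name()='listOfOutputs']/*")) {
    nm <- xml2::xml_name(n)
    if (nm == "report") {
      ds <- lapply(sb_list(n, "listOfDataSets", "dataSet"), function(d) {
        list(label = attr_or(d, "label"), ref = attr_or(d, "dataReference"))
      })
      outs[[length(outs) + 1]] <- sed_output("report", attr_or(n, "id"), ds)
    } else if (nm == "plot2D") {
      cv <- lapply(sb_list(n, "listOfCurves", "curve"), function(d) {
        list(x = attr_or(d, "xDataReference"),
             y = attr_or(d, "yDataReference"))
      })
      outs[[length(outs) + 1]] <- sed_output("plot2d", attr_or(n, "id"), cv)
    } else {
      notes <- c(notes, paste0("unsupported-feature: output type ", nm))
    }
  }

  out <- sed_document(models, sims, tasks, dgs, outs, level, version, notes)
  dup <- unique(sed_all_ids(out)[duplicated(sed_all_ids(out))])
  if (length(dup) > 0) {
    out$notes <- c(out$notes, paste0("duplicate-id: ", dup))
  }
  out
}

#' Serialize a SED-ML document
#'
#' Emits XML at the document's own level/version (attribute
#' `numberOfPoints` at L1V3, `numberOfSteps` at L1V4), such that
#' `parse_sedml(write_sedml(doc))` reproduces `doc`.
#'
#' @param doc a [sed_document()] satisfying its invariants.
#' @return raw vector of XML bytes.
#' @section Errors: `"invalid-document"` when a reference dangles.
#' @export
write_sedml <- function(doc) {
  stopifnot(inherits(doc, "sed_document"))
  check_refs_resolve(doc)
  lv <- paste0(doc$level, ".", doc$version)
  ns <- SEDML_NS[[lv]]
  if (is.null(ns)) vk_stop("invalid-document", paste("level/version", lv))
  root <- xml2::xml_new_root("sedML", xmlns = ns,
                             level = as.character(doc$level),
                             version = as.character(doc$version))
  if (length(doc$models) > 0) {
    lom <- xml2::xml_add_child(root, "listOfModels")
    for (m in doc$models) {
      mn <- xml2::xml_add_child(lom, "model", id = m$id, source = m$source,
                                language = m$language)
      if (length(m$changes) > 0) {
        loc <- xml2::xml_add_child(mn, "listOfChanges")
        for (ch in m$changes) {
          xml2::xml_add_child(loc, "changeAttribute", target = ch$target,
                              newValue = ch$new_value)
        }
      }
    }
  }
  if (length(doc$simulations) > 0) {
    los <- xml2::xml_add_child(root, "listOfSimulations")
    for (s in doc$simulations) {
      if (!identical(s$type, "uniformTimeCourse")) {
        vk_stop("invalid-document",
                paste("cannot serialize simulation type", s$type))
      }
      steps_attr <- if (doc$version >= 4) "numberOfSteps" else "numberOfPoints"
      sn <- xml2::xml_add_child(los, "uniformTimeCourse", id = s$id)
      xml2::xml_set_attr(sn, "initialTime", format(s$initial_time))
      xml2::xml_set_attr(sn, "outputStartTime", format(s$output_start_time))
      xml2::xml_set_attr(sn, "outputEndTime", format(s$output_end_time))
      xml2::xml_set_attr(sn, steps_attr, format(s$number_of_steps))
      an <- xml2::xml_add_child(sn, "algorithm", kisaoID = s$algorithm)
      if (length(s$algorithm_parameters) > 0) {
        lap <- xml2::xml_add_child(an, "listOfAlgorithmParameters")
        for (i in seq_along(s$algorithm_parameters)) {
          xml2::xml_add_child(lap, "algorithmParameter",
                              kisaoID = names(s$algorithm_parameters)[i],
                              value = s$algorithm_parameters[[i]])
        }
      }
    }
  }
  if (length(doc$tasks) > 0) {
    lot <- xml2::xml_add_child(root, "listOfTasks")
    for (t in doc$tasks) {
      xml2::xml_add_child(lot, "task", id = t$id, modelReference = t$model_ref,
                          simulationReference = t$simulation_ref)
    }
  }
  if (length(doc$data_generators) > 0) {
    lod <- xml2::xml_add_child(root, "listOfDataGenerators")
    for (d in doc$data_generators) {
      dn <- xml2::xml_add_child(lod, "dataGenerator", id = d$id)
      if (length(d$variables) > 0) {
        lov <- xml2::xml_add_child(dn, "listOfVariables")
        for (v in d$variables) {
          vn <- xml2::xml_add_child(lov, "variable", id = v$id,
                                    taskReference = v$task_ref)
          if (!is.na(v$target %||% NA)) xml2::xml_set_attr(vn, "target", v$target)
          if (!is.na(v$symbol %||% NA)) xml2::xml_set_attr(vn, "symbol", v$symbol)
        }
      }
      if (length(d$parameters) > 0) {
        lop <- xml2::xml_add_child(dn, "listOfParameters")
        for (i in seq_along(d$parameters)) {
          xml2::xml_add_child(lop, "parameter", id = names(d$parameters)[i],
                              value = format(d$parameters[[i]]))
        }
      }
      xml2::xml_add_child(dn, xml2::xml_root(mathml_to_xml(d$math)))
    }
  }
  if (length(doc$outputs) > 0) {
    loo <- xml2::xml_add_child(root, "listOfOutputs")
    for (o in doc$outputs) {
      if (o$kind == "report") {
        on <- xml2::xml_add_child(loo, "report", id = o$id)
        lods <- xml2::xml_add_child(on, "listOfDataSets")
        for (it in o$items) {
          xml2::xml_add_child(lods, "dataSet",
                              id = paste0(o$id, "_", it$ref),
                              label = it$label, dataReference = it$ref)
        }
      } else {
        on <- xml2::xml_add_child(loo, "plot2D", id = o$id)
        locv <- xml2::xml_add_child(on, "listOfCurves")
        for (i in seq_along(o$items)) {
          it <- o$items[[i]]
          xml2::xml_add_child(locv, "curve",
                              id = paste0(o$id, "_curve", i),
                              logX = "false", logY = "false",
                              xDataReference = it$x, yDataReference = it$y)
        }
      }
    }
  }
  charToRaw(as.character(root))
}

check_refs_resolve <- function(doc) {
  model_ids <- vapply(doc$models, `[[`, "", "id")
  sim_ids <- vapply(doc$simulations, `[[`, "", "id")
  task_ids <- vapply(doc$tasks, `[[`, "", "id")
  dg_ids <- vapply(doc$data_generators, `[[`, "", "id")
  for (t in doc$tasks) {
    if (!(t$model_ref %in% model_ids))
      vk_stop("invalid-document", paste("task", t$id, "model ref", t$model_ref))
    if (!(t$simulation_ref %in% sim_ids))
      vk_stop("invalid-document", paste("task", t$id, "sim ref",
                                        t$simulation_ref))
  }
  for (d in doc$data_generators) {
    for (v in d$variables) {
      if (!(v$task_ref %in% task_ids))
        vk_stop("invalid-document", paste("datagen", d$id, "task ref",
                                          v$task_ref))
    }
  }
  for (o in doc$outputs) {
    refs <- if (o$kind == "report") vapply(o$items, `[[`, "", "ref")
            else unlist(lapply(o$items, function(it) c(it$x, it$y)))
    bad <- setdiff(refs, dg_ids)
    if (length(bad) > 0)
      vk_stop("invalid-document", paste("output", o$id, "datagen ref",
                                        paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# --- target pointers -------------------------------------------------------

CANONICAL_TARGET_RE <- paste0(
  "^/sbml:sbml/sbml:model",
  "(/sbml:listOf[A-Za-z]+/sbml:[A-Za-z]+\\[@id='[^']+'\\])+$")

# Parse an XPath-ish pointer into what we need: the addressed id (if any),
# whether the pointer is in the canonical prefixed id-selector form, and the
# attribute addressed (for changeAttribute semantics).
parse_target <- function(target) {
  if (is.null(target) || is.na(target) || !nzchar(target)) {
    return(list(valid = FALSE, id = NA_character_, canonical = FALSE))
  }
  ids <- regmatches(target,
                    gregexpr("\\[@id=['\"]([^'\"]+)['\"]\\]", target))[[1]]
  id <- if (length(ids) > 0) {
    sub("\\[@id=['\"]([^'\"]+)['\"]\\]", "\\1", ids[length(ids)])
  } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", target)) {
    target  # bare id shorthand
  } else {
    NA_character_
  }
  list(valid = !is.na(id), id = id,
       canonical = grepl(CANONICAL_TARGET_RE, target))
}

canonical_target_for <- function(model, id) {
  node <- xml2::xml_find_first(sbml_model_node(model),
                               sprintf(".//*[@id='%s']", id))
  if (inherits(node, "xml_missing")) return(NA_character_)
  kind <- xml2::xml_name(node)
  list_name <- paste0("listOf", toupper(substring(kind, 1, 1)),
                      substring(kind, 2),
                      if (grepl("s$", kind)) "es" else "s")
  # species pluralizes to listOfSpecies
  if (kind == "species") list_name <- "listOfSpecies"
  sprintf("/sbml:sbml/sbml:model/sbml:%s/sbml:%s[@id='%s']",
          list_name, kind, id)
}

#' Semantic validation of a SED-ML document against its archive
#'
#' Cross-checks the document against itself and, when an archive is given,
#' against the SBML models it references: missing model sources, dangling
#' element targets (each pointer is resolved inside the referenced SBML),
#' simulations or models no task uses, duplicated ids, malformed pointers,
#' excessive output-point requests, and unknown algorithm parameters.
#'
#' @param doc a [sed_document()].
#' @param archive optional [omex_archive()] holding the model sources.
#' @param excessive_points_threshold flag time courses requesting more output
#'   points than this (default 100000).
#' @param known_algorithm_parameters character vector of recognized KiSAO
#'   parameter ids.
#' @return issue data frame; zero rows iff clean. Codes among
#'   `missing-model-source`, `dangling-target`, `unused-simulation`,
#'   `unused-model`, `duplicate-id`, `malformed-target`, `excessive-points`,
#'   `unknown-algorithm-parameter`.
#' @export
validate_semantics <- function(doc, archive = NULL,
                               excessive_points_threshold = 100000L,
                               known_algorithm_parameters =
                                 unlist(KISAO[-1], use.names = FALSE)) {
  iss <- vk_no_issues()
  ids <- sed_all_ids(doc)
  for (d in unique(ids[duplicated(ids)])) {
    iss <- rbind_issues(iss, vk_issues("duplicate-id", d, "id defined twice"))
  }

  models_by_id <- stats::setNames(doc$models,
                                  vapply(doc$models, `[[`, "", "id"))
  tasks_by_id <- stats::setNames(doc$tasks, vapply(doc$tasks, `[[`, "", "id"))
  handles <- list()
  for (m in doc$models) {
    if (is.null(archive)) next
    if (!(m$source %in% names(archive$payload))) {
      iss <- rbind_issues(iss, vk_issues("missing-model-source", m$id,
                                         paste("source", m$source,
                                               "not in archive")))
    } else {
      handles[[m$id]] <- tryCatch(read_sbml(archive$payload[[m$source]]),
                                  error = function(e) NULL)
    }
  }

  check_target <- function(target, where, model_id) {
    pt <- parse_target(target)
    if (!pt$valid || !pt$canonical) {
      iss <<- rbind_issues(iss, vk_issues("malformed-target", where,
                                          target %||% ""))
      if (!pt$valid) return(invisible(NULL))
    }
    h <- handles[[model_id %||% ""]]
    if (!is.null(h) && !(pt$id %in% sbml_all_ids(h))) {
      iss <<- rbind_issues(iss, vk_issues("dangling-target", where,
                                          paste("no element with id", pt$id)))
    }
  }

  for (m in doc$models) {
    for (i in seq_along(m$changes)) {
      check_target(m$changes[[i]]$target,
                   paste0("model:", m$id, "/change", i), m$id)
    }
  }
  for (d in doc$data_generators) {
    for (v in d$variables) {
      if (!is.na(v$symbol %||% NA)) next
      task <- tasks_by_id[[v$task_ref %||% ""]]
      check_target(v$target, paste0("dataGenerator:", d$id, "/", v$id),
                   task$model_ref %||% NULL)
    }
  }

  used_tasks <- unique(unlist(lapply(doc$data_generators, function(d) {
    vapply(d$variables, `[[`, "", "task_ref")
  })))
  used_sims <- unique(vapply(tasks_by_id[intersect(names(tasks_by_id),
                                                   used_tasks)],
                             `[[`, "", "simulation_ref"))
  used_models <- unique(vapply(tasks_by_id[intersect(names(tasks_by_id),
                                                     used_tasks)],
                               `[[`, "", "model_ref"))
  all_task_sims <- unique(vapply(doc$tasks, `[[`, "", "simulation_ref"))
  all_task_models <- unique(vapply(doc$tasks, `[[`, "", "model_ref"))
  for (s in doc$simulations) {
    if (!(s$id %in% all_task_sims)) {
      iss <- rbind_issues(iss, vk_issues("unused-simulation", s$id,
                                         "referenced by no task"))
    }
  }
  for (m in doc$models) {
    if (!(m$id %in% all_task_models)) {
      iss <- rbind_issues(iss, vk_issues("unused-model", m$id,
                                         "referenced by no task"))
    }
  }

  for (s in doc$simulations) {
    if (!identical(s$type, "uniformTimeCourse")) next
    if (s$number_of_steps > excessive_points_threshold) {
      iss <- rbind_issues(iss, vk_issues(
        "excessive-points", s$id,
        sprintf("%d output points requested", s$number_of_steps + 1L)))
    }
    unknown <- setdiff(names(s$algorithm_parameters),
                       known_algorithm_parameters)
    for (u in unknown) {
      iss <- rbind_issues(iss, vk_issues("unknown-algorithm-parameter",
                                         s$id, u))
    }
  }
  iss
}
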