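# The engine-adapter contract and the built-in reference ODE engine.
#
# An adapter turns an archive (or a parsed document plus model) into a
# ResultSet and never raises past its boundary: failures are captured in the
# status field. The reference engine compiles the SBML reaction network to
# dx/dt = N v(x, t) plus rate rules and integrates it with deSolve's
# variable-step stiff solvers under two interchangeable configurations
# (lsoda and vode/BDF), which gives an internal two-engine verification
# route without any external simulator.

#' Solver settings
#'
#' @param algorithm KiSAO id of the integration algorithm.
#' @param relative_tolerance positive real; default `1e-8`. Production
#'   engines commonly default to `1e-6`, but a built-in engine whose role is
#'   to serve as the reference in cross-engine comparisons is kept two
#'   orders tighter so its own numerical error stays far below the
#'   replication tolerance; override per experiment via SED-ML algorithm
#'   parameters.
#' @param base_absolute_tolerance positive real; default `1e-12`, the engine
#'   default shipped by the mainstream ODE biosimulators.
#' @param atol_adjustment_factor positive real or `NULL`. When set, the
#'   effective absolute tolerance becomes a per-variable vector scaled by the
#'   initial value of each variable (see [make_atol_vector()]); when unset, a
#'   uniform scalar tolerance is used.
#' @param max_internal_steps integer cap on internal solver steps.
#' @param method deSolve integrator: `"lsoda"` (default) or `"vode"` (BDF) —
#'   two independent step controllers over the same model compilation.
#' @param atol_adjustment_factor_id KiSAO id under which the adjustment
#'   factor is read from SED-ML algorithm parameters (configurable because
#'   the ontology term was registered late).
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(algorithm = KISAO$cvode,
                            relative_tolerance = 1e-8,
                            base_absolute_tolerance = 1e-12,
                            atol_adjustment_factor = NULL,
                            max_internal_steps = 20000L,
                            method = c("lsoda", "vode"),
                            atol_adjustment_factor_id =
                              KISAO$atol_adjustment_factor) {
  stopifnot(relative_tolerance > 0, base_absolute_tolerance > 0,
            is.null(atol_adjustment_factor) || atol_adjustment_factor > 0)
  structure(list(algorithm = algorithm,
                 relative_tolerance = relative_tolerance,
                 base_absolute_tolerance = base_absolute_tolerance,
                 atol_adjustment_factor = atol_adjustment_factor,
                 max_internal_steps = as.integer(max_internal_steps),
                 method = match.arg(method),
                 atol_adjustment_factor_id = atol_adjustment_factor_id),
            class = "solver_settings")
}

# Overlay SED-ML algorithm parameters (by KiSAO id) onto settings.
settings_from_simulation <- function(sim, settings = solver_settings()) {
  ap <- sim$algorithm_parameters %||% character(0)
  num <- function(id) {
    if (id %in% names(ap)) suppressWarnings(as.numeric(ap[[id]])) else NULL
  }
  v <- num(KISAO$relative_tolerance)
  if (!is.null(v) && !is.na(v)) settings$relative_tolerance <- v
  v <- num(KISAO$absolute_tolerance)
  if (!is.null(v) && !is.na(v)) settings$base_absolute_tolerance <- v
  v <- num(KISAO$max_internal_steps)
  if (!is.null(v) && !is.na(v)) settings$max_internal_steps <- as.integer(v)
  v <- num(settings$atol_adjustment_factor_id)
  if (!is.null(v) && !is.na(v)) settings$atol_adjustment_factor <- v
  if (!is.null(sim$algorithm)) settings$algorithm <- sim$algorithm
  settings
}

#' Per-variable absolute-tolerance vector
#'
#' Mirrors the tolerance semantics that made multi-scale models replicate
#' across engines: when the adjustment factor is set, each variable's
#' absolute tolerance is the factor times the magnitude of its initial
#' value, so state variables living at 1e-12 are integrated as carefully as
#' those at 1. Variables starting at exactly zero get the scalar base
#' tolerance as a floor (a zero tolerance would be meaningless to the
#' solver).
#'
#' @param settings a [solver_settings()].
#' @param initial_state numeric vector of initial values.
#' @return numeric vector, one tolerance per state variable.
#' @export
make_atol_vector <- function(settings, initial_state) {
  stopifnot(inherits(settings, "solver_settings"))
  n <- length(initial_state)
  if (is.null(settings$atol_adjustment_factor)) {
    return(rep(settings$base_absolute_tolerance, n))
  }
  atol <- settings$atol_adjustment_factor * abs(initial_state)
  atol[initial_state == 0] <- settings$base_absolute_tolerance
  atol
}

#' Apply SED-ML attribute changes to a model
#'
#' Overwrites attribute values addressed by pointer targets before
#' compilation. Element-level targets pick the natural value attribute for
#' their kind (species initial amount/concentration, parameter value,
#' compartment size); a trailing `/@attr` selects an explicit attribute.
#' Local kinetic parameters become changeable after
#' [promote_local_parameters()].
#'
#' @param model an `sbml_handle`.
#' @param changes list of `list(target =, new_value =)`.
#' @return transformed `sbml_handle` (copy).
#' @section Errors: `"dangling-target"` when a target does not resolve;
#'   `"bad-value"` when a numeric attribute receives a non-numeric value.
#' @export
apply_changes <- function(model, changes) {
  if (length(changes) == 0) return(model)
  model <- sbml_copy(model)
  mn <- sbml_model_node(model)
  for (ch in changes) {
    target <- ch$target
    attr_name <- NULL
    if (grepl("/@", target)) {
      attr_name <- sub("^.*/@", "", target)
      target <- sub("/@[^/]*$", "", target)
    }
    pt <- parse_target(target)
    if (!pt$valid) vk_stop("dangling-target", paste("target", ch$target))
    node <- xml2::xml_find_first(mn, sprintf(".//*[@id='%s']", pt$id))
    if (inherits(node, "xml_missing")) {
      vk_stop("dangling-target", paste("no element with id", pt$id))
    }
    kind <- xml2::xml_name(node)
    if (is.null(attr_name)) {
      attr_name <- switch(kind,
        species = if (!is.na(xml2::xml_attr(node, "initialConcentration")))
          "initialConcentration" else "initialAmount",
        compartment = "size",
        "value")
    }
    numeric_attrs <- c("value", "size", "initialAmount",
                       "initialConcentration", "stoichiometry")
    if (attr_name %in% numeric_attrs) {
      val <- parse_sbml_number(ch$new_value)
      if (is.na(val) && !is.nan(val)) {
        vk_stop("bad-value", paste("non-numeric value", ch$new_value,
                                   "for", attr_name))
      }
    }
    xml2::xml_set_attr(node, attr_name, ch$new_value)
  }
  model
}

#' Compile an SBML model to an ODE system
#'
#' Builds `dx/dt = N v(x, t)` over the reaction network, adds rate-rule
#' derivatives, evaluates assignment rules before every right-hand-side
#' evaluation, inlines function definitions and initial assignments, and
#' handles amount vs concentration per compartment size. The supported
#' subset excludes events, delays, and algebraic rules.
#'
#' @param model an `sbml_handle`.
#' @return list of class `ode_system` with `state_ids`, `initial_state`,
#'   `rhs(t, state)`, `observables(t, state)` (named values of every dynamic
#'   variable, in document order), `output_ids`, and `constants` (named
#'   values of quantities fixed for the run).
#' @section Errors: `"unsupported-model-feature"` listing the offending
#'   constructs.
#' @export
compile_odes <- function(model) {
  feats <- sbml_unsupported_features(model)
  if (length(feats) > 0) {
    vk_stop("unsupported-model-feature", paste(feats, collapse = ", "))
  }
  if (length(sbml_initial_assignments(model)) > 0) {
    model <- inline_initial_assignments(model)
  }
  fdefs <- sbml_function_definitions(model)
  sp <- sbml_species(model)
  par <- sbml_parameters(model)
  comp <- sbml_compartments(model)
  rules <- sbml_rules(model)
  reactions <- sbml_reactions(model)

  asg <- Filter(function(r) r$type == "assignment", rules)
  rate <- Filter(function(r) r$type == "rate", rules)
  asg_vars <- vapply(asg, `[[`, "", "variable")
  rate_vars <- vapply(rate, `[[`, "", "variable")
  asg_math <- lapply(asg, function(r) inline_functions(r$math, fdefs))
  rate_math <- lapply(rate, function(r) inline_functions(r$math, fdefs))
  deps <- stats::setNames(lapply(asg_math, function(m) {
    intersect(expr_symbols(m), asg_vars)
  }), asg_vars)
  asg_order <- if (length(asg_vars) > 0) {
    topo_sort(asg_vars, deps, "cyclic-assignment-rules")
  } else character(0)
  asg_math <- asg_math[match(asg_order, asg_vars)]
  asg_vars <- asg_order

  # state selection
  state_species <- sp$id[!sp$constant & !(sp$id %in% asg_vars) &
                           (!sp$boundary | sp$id %in% rate_vars)]
  state_other <- intersect(rate_vars, c(par$id, comp$id))
  state_ids <- c(state_species, state_other)
  if (length(state_ids) == 0 && length(asg_vars) == 0 &&
      nrow(sp[!sp$constant, ]) == 0) {
    # all-constant model: still valid, zero-dimensional state
  }

  env0 <- model_initial_env(model)
  comp_size <- stats::setNames(comp$size, comp$id)
  sp_comp <- stats::setNames(sp$compartment, sp$id)
  sp_substance <- stats::setNames(sp$substance_units_only, sp$id)

  # initial state in solver units (amounts for species)
  size_of <- function(id) {
    s <- comp_size[sp_comp[[id]]]
    if (length(s) == 0 || is.na(s)) 1 else s
  }
  initial_state <- vapply(state_ids, function(id) {
    v <- env0[[id]] %||% NA_real_
    if (id %in% sp$id && !sp_substance[[id]]) v <- v * size_of(id)
    v
  }, 0)
  names(initial_state) <- state_ids

  # stoichiometry over state species
  n_rx <- length(reactions)
  N <- matrix(0, nrow = length(state_ids), ncol = n_rx,
              dimnames = list(state_ids, NULL))
  rx_exprs <- vector("list", n_rx)
  for (j in seq_len(n_rx)) {
    rx <- reactions[[j]]
    if (is.null(rx$kinetic_math)) {
      vk_stop("unsupported-model-feature",
              paste("reaction", rx$id, "lacks a kinetic law"))
    }
    e <- inline_functions(rx$kinetic_math, fdefs)
    if (nrow(rx$local_parameters) > 0) {
      e <- expr_substitute(e, stats::setNames(
        as.list(rx$local_parameters$value), rx$local_parameters$id))
    }
    rx_exprs[[j]] <- e
    for (i in seq_len(nrow(rx$reactants))) {
      s <- rx$reactants$species[i]
      if (s %in% state_species) {
        N[s, j] <- N[s, j] - rx$reactants$stoichiometry[i]
      }
    }
    for (i in seq_len(nrow(rx$products))) {
      s <- rx$products$species[i]
      if (s %in% state_species) {
        N[s, j] <- N[s, j] + rx$products$stoichiometry[i]
      }
    }
  }

  const_env <- env0
  is_species_state <- state_ids %in% sp$id

  load_env <- function(t, y) {
    env <- const_env
    env$time <- t
    # non-species states first so compartment sizes are current
    for (i in seq_along(state_ids)) {
      if (!is_species_state[i]) env[[state_ids[i]]] <- y[[i]]
    }
    for (i in seq_along(state_ids)) {
      if (is_species_state[i]) {
        id <- state_ids[i]
        v <- y[[i]]
        if (!sp_substance[[id]]) {
          size <- env[[sp_comp[[id]]]] %||% 1
          v <- v / size
        }
        env[[id]] <- v
      }
    }
    for (i in seq_along(asg_vars)) {
      env[[asg_vars[i]]] <- eval(asg_math[[i]], env, baseenv())
    }
    env
  }

  rhs <- function(t, y) {
    env <- load_env(t, y)
    dy <- numeric(length(state_ids))
    if (n_rx > 0) {
      v <- vapply(rx_exprs, function(e) eval(e, env, baseenv()), 0)
      dy <- as.numeric(N %*% v)
    }
    for (i in seq_along(rate_vars)) {
      id <- rate_vars[i]
      k <- match(id, state_ids)
      if (is.na(k)) next
      d <- eval(rate_math[[i]], env, baseenv())
      if (id %in% sp$id && !sp_substance[[id]]) {
        d <- d * (env[[sp_comp[[id]]]] %||% 1)  # d(conc)/dt -> d(amount)/dt
      }
      dy[k] <- dy[k] + d
    }
    dy
  }

  output_ids <- list_dynamic_variables(model)
  observables <- function(t, y) {
    env <- load_env(t, y)
    vapply(output_ids, function(id) as.numeric(env[[id]] %||% NA_real_), 0)
  }
  constants <- env0[setdiff(names(env0),
                            c(output_ids, state_ids, "time"))]

  structure(list(state_ids = state_ids, initial_state = initial_state,
                 rhs = rhs, observables = observables,
                 output_ids = output_ids, constants = constants),
            class = "ode_system")
}

#' Run a uniform time course on a compiled system
#'
#' Variable-step stiff-capable integration (deSolve) honoring the relative
#' tolerance and the per-variable absolute-tolerance vector. The output grid
#' spans `output_start_time` to `output_end_time` in `number_of_steps` equal
#' intervals; integration itself starts at `initial_time`.
#'
#' @param system an `ode_system` from [compile_odes()].
#' @param sim a [sed_uniform_timecourse()].
#' @param settings a [solver_settings()]; algorithm parameters carried by
#'   `sim` override it.
#' @return numeric matrix, one row per output point; columns `time` plus the
#'   system's dynamic variables.
#' @section Errors: `"integration-failure"` with solver diagnostics.
#' @export
run_timecourse <- function(system, sim, settings = solver_settings()) {
  stopifnot(inherits(system, "ode_system"))
  settings <- settings_from_simulation(sim, settings)
  if (sim$output_start_time == sim$output_end_time) {
    grid <- sim$output_start_time
  } else {
    grid <- seq(sim$output_start_time, sim$output_end_time,
                length.out = sim$number_of_steps + 1)
  }
  y0 <- system$initial_state
  out_rows <- matrix(NA_real_, nrow = length(grid),
                     ncol = length(system$output_ids),
                     dimnames = list(NULL, system$output_ids))
  if (length(y0) == 0 ||
      (length(grid) == 1 && grid[1] == sim$initial_time)) {
    for (i in seq_along(grid)) {
      out_rows[i, ] <- system$observables(grid[i], y0)
    }
    return(cbind(time = grid, out_rows))
  }
  times <- grid
  prepended <- FALSE
  if (sim$initial_time < times[1]) {
    times <- c(sim$initial_time, times)
    prepended <- TRUE
  } else if (sim$initial_time > times[1]) {
    vk_stop("integration-failure",
            "initial time after output start is not supported")
  }
  atol <- make_atol_vector(settings, y0)
  func <- function(t, y, parms) list(system$rhs(t, y))
  sol <- tryCatch(
    withCallingHandlers(
      deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                   method = settings$method,
                   rtol = settings$relative_tolerance, atol = atol,
                   maxsteps = settings$max_internal_steps),
      warning = function(w) {
        vk_stop("integration-failure", conditionMessage(w))
      }),
    error = function(e) {
      if (inherits(e, "verikit_error")) stop(e)
      vk_stop("integration-failure", conditionMessage(e))
    })
  sol <- unclass(sol)
  if (prepended) sol <- sol[-1, , drop = FALSE]
  if (nrow(sol) != length(grid) || any(!is.finite(sol))) {
    vk_stop("integration-failure", "solver returned non-finite state")
  }
  for (i in seq_along(grid)) {
    y <- sol[i, -1]
    names(y) <- system$state_ids
    out_rows[i, ] <- system$observables(grid[i], y)
  }
  cbind(time = grid, out_rows)
}

# --- ResultSet -------------------------------------------------------------

#' Labeled numeric trajectories per report
#'
#' The unit of cross-engine comparison: per report, column labels, a
#' row-major value matrix, and the time grid; plus engine id and a status
#' that captures failures instead of raising them.
#'
#' @param engine_id engine identifier string.
#' @param status `"success"` or `"failure"`.
#' @param message failure message, `""` on success.
#' @param reports named list (by report id) of `list(labels =, values =,
#'   time =)`.
#' @param doc_id optional document identifier.
#' @return object of class `result_set`.
#' @export
result_set <- function(engine_id, status = c("success", "failure"),
                       message = "", reports = list(), doc_id = "") {
  status <- match.arg(status)
  for (r in reports) {
    stopifnot(length(r$labels) == ncol(r$values))
  }
  structure(list(engine_id = engine_id, status = status, message = message,
                 reports = reports, doc_id = doc_id),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set engine=%s status=%s> %d report(s)\n",
              x$engine_id, x$status, length(x$reports)))
  if (x$status == "failure") cat("  message:", x$message, "\n")
  for (id in names(x$reports)) {
    r <- x$reports[[id]]
    cat(sprintf("  %s: %d x %d [%s]\n", id, nrow(r$values), ncol(r$values),
                paste(r$labels, collapse = ", ")))
  }
  invisible(x)
}

#' Evaluate data generators over task trajectories
#'
#' Each data generator's math is evaluated per output point with its
#' variables bound to trajectory columns (or to the time grid for the time
#' symbol). Constant model quantities requested as variables are
#' materialized as constant columns, since several engines will not export
#' constant parameters without help.
#'
#' @param doc a [sed_document()].
#' @param trajectories named list (by task id) of matrices from
#'   [run_timecourse()].
#' @param model the `sbml_handle` the tasks simulated (used to resolve
#'   constants).
#' @param engine_id recorded in the result.
#' @return a [result_set()] holding one entry per report output.
#' @section Errors: `"dangling-target"` for unresolvable variable targets;
#'   `"bad-datagen"` when math references an undeclared symbol.
#' @export
evaluate_data_generators <- function(doc, trajectories, model,
                                     engine_id = "reference") {
  columns <- list()
  n_points <- NULL
  for (d in doc$data_generators) {
    env <- as.list(d$parameters)
    for (v in d$variables) {
      traj <- trajectories[[v$task_ref %||% ""]]
      if (is.null(traj)) {
        vk_stop("bad-datagen", paste("no trajectory for task", v$task_ref))
      }
      if (!is.na(v$symbol %||% NA)) {
        if (!identical(v$symbol, TIME_SYMBOL)) {
          vk_stop("bad-datagen", paste("unknown symbol", v$symbol))
        }
        env[[v$id]] <- traj[, "time"]
        next
      }
      pt <- parse_target(v$target)
      if (!pt$valid) vk_stop("dangling-target", paste("target", v$target))
      if (pt$id %in% colnames(traj)) {
        env[[v$id]] <- traj[, pt$id]
      } else {
        cst <- constant_quantity_value(model, pt$id)
        if (is.null(cst)) {
          vk_stop("dangling-target", paste("no quantity with id", pt$id))
        }
        env[[v$id]] <- rep(cst, nrow(traj))
      }
    }
    syms <- expr_symbols(d$math)
    undeclared <- setdiff(syms, c(names(env), "time"))
    if (length(undeclared) > 0) {
      vk_stop("bad-datagen", paste("undeclared symbols:",
                                   paste(undeclared, collapse = ", ")))
    }
    col <- eval(d$math, env, baseenv())
    n <- max(vapply(env, length, 1L), 1L)
    columns[[d$id]] <- rep_len(as.numeric(col), n)
    n_points <- n
  }
  reports <- list()
  for (o in doc$outputs) {
    if (o$kind != "report") next
    labels <- vapply(o$items, `[[`, "", "label")
    refs <- vapply(o$items, `[[`, "", "ref")
    values <- do.call(cbind, columns[refs])
    colnames(values) <- labels
    time_col <- if ("time" %in% labels) values[, "time"]
                else seq_len(nrow(values))
    reports[[o$id]] <- list(labels = labels, values = values,
                            time = as.numeric(time_col))
  }
  result_set(engine_id, "success", reports = reports)
}

constant_quantity_value <- function(model, id) {
  par <- sbml_parameters(model)
  if (id %in% par$id) return(par$value[par$id == id][1])
  comp <- sbml_compartments(model)
  if (id %in% comp$id) return(comp$size[comp$id == id][1])
  sp <- sbml_species(model)
  if (id %in% sp$id) {
    env <- model_initial_env(model)
    return(env[[id]])
  }
  NULL
}

# --- engine registry -------------------------------------------------------

the_engines <- new.env(parent = emptyenv())

#' Engine adapter registry
#'
#' Adapters mirror the wrapper architecture used for production simulators:
#' each one translates a simulation experiment into engine-specific
#' operations and returns a standardized [result_set()], capturing failures
#' in the status rather than raising. Two configurations of the built-in
#' reference engine (`reference-lsoda`, `reference-bdf`) are pre-registered.
#'
#' @param engine_id unique engine identifier.
#' @param execute function `(entry, settings) -> result_set` where `entry`
#'   is an [omex_archive()] or a `list(doc =, model =)`.
#' @param capabilities character vector of feature flags.
#' @return `register_engine` returns the adapter invisibly; `get_engine` the
#'   adapter; `list_engines` the registered ids.
#' @export
register_engine <- function(engine_id, execute,
                            capabilities = character(0)) {
  adapter <- structure(list(engine_id = engine_id, execute = execute,
                            capabilities = capabilities),
                       class = "engine_adapter")
  assign(engine_id, adapter, envir = the_engines)
  invisible(adapter)
}

#' @rdname register_engine
#' @export
get_engine <- function(engine_id) {
  if (!exists(engine_id, envir = the_engines)) {
    vk_stop("unknown-engine", paste("no engine registered as", engine_id))
  }
  get(engine_id, envir = the_engines)
}

#' @rdname register_engine
#' @export
list_engines <- function() sort(ls(the_engines))

#' Execute a simulation experiment on an engine
#'
#' Full pipeline: load the archive's SED-ML and models, apply model changes
#' (after promoting local parameters so they are addressable), compile,
#' integrate each task, and evaluate the data generators into reports.
#' Failures of any stage are captured in the returned status; this function
#' does not raise for entry-level problems.
#'
#' @param entry an [omex_archive()], or `list(doc = sed_document, model =
#'   sbml_handle)` for a pre-parsed experiment.
#' @param engine_id a registered engine (default `"reference-lsoda"`).
#' @param settings optional [solver_settings()] override.
#' @return a [result_set()].
#' @export
execute <- function(entry, engine_id = "reference-lsoda", settings = NULL) {
  adapter <- get_engine(engine_id)
  adapter$execute(entry, settings)
}

reference_execute <- function(entry, settings = NULL, method = "lsoda",
                              engine_id = paste0("reference-", method)) {
  if (is.null(settings)) settings <- solver_settings(method = method)
  settings$method <- method
  fail <- function(code, msg) {
    result_set(engine_id, "failure",
               message = paste0(code, ": ", msg))
  }
  tryCatch({
    if (inherits(entry, "omex_archive")) {
      sed_locs <- archive_locations_of(entry, "sedml")
      if (length(sed_locs) == 0) {
        return(fail("no-sedml", "archive contains no SED-ML"))
      }
      doc <- parse_sedml(entry$payload[[sort(sed_locs)[1]]])
      get_model <- function(m) {
        if (!(m$source %in% names(entry$payload))) {
          vk_stop("missing-model-source", m$source)
        }
        read_sbml(entry$payload[[m$source]])
      }
    } else if (is.list(entry) && !is.null(entry$doc)) {
      doc <- entry$doc
      get_model <- function(m) entry$model
    } else {
      return(fail("bad-entry", "expected omex_archive or doc+model"))
    }

    models_by_id <- stats::setNames(doc$models,
                                    vapply(doc$models, `[[`, "", "id"))
    sims_by_id <- stats::setNames(doc$simulations,
                                  vapply(doc$simulations, `[[`, "", "id"))
    used_tasks <- unique(unlist(lapply(doc$data_generators, function(d) {
      vapply(d$variables, `[[`, "", "task_ref")
    })))
    trajectories <- list()
    last_model <- NULL
    for (t in doc$tasks) {
      if (!(t$id %in% used_tasks)) next
      m <- models_by_id[[t$model_ref]]
      s <- sims_by_id[[t$simulation_ref]]
      if (is.null(m) || is.null(s)) {
        vk_stop("invalid-document", paste("task", t$id, "has dangling refs"))
      }
      if (!identical(s$type, "uniformTimeCourse")) {
        vk_stop("unsupported-feature", paste("simulation type", s$type))
      }
      h <- get_model(m)
      h <- promote_local_parameters(h)$model
      h <- apply_changes(h, m$changes)
      system <- compile_odes(h)
      traj <- run_timecourse(system, s, settings)
      trajectories[[t$id]] <- traj
      last_model <- h
    }
    if (length(trajectories) == 0) {
      return(fail("nothing-to-run", "no task is referenced by any output"))
    }
    rs <- evaluate_data_generators(doc, trajectories, last_model, engine_id)
    rs$engine_id <- engine_id
    rs
  }, error = function(e) {
    code <- setdiff(class(e), c("verikit_error", "error", "condition",
                                "simpleError", "rlang_error"))
    code <- if (length(code) > 0) code[1] else "error"
    fail(code, conditionMessage(e))
  })
}

register_reference_engines <- function() {
  register_engine("reference-lsoda",
                  function(entry, settings = NULL)
                    reference_execute(entry, settings, "lsoda",
                                      "reference-lsoda"),
                  capabilities = c("sbml-core", "uniform-timecourse",
                                   "atol-vector"))
  register_engine("reference-bdf",
                  function(entry, settings = NULL)
                    reference_execute(entry, settings, "vode",
                                      "reference-bdf"),
                  capabilities = c("sbml-core", "uniform-timecourse",
                                   "atol-vector"))
}

.onLoad <- function(libname, pkgname) {
  register_reference_engines()
}

#' Export a result set to disk
#'
#' One CSV per report (time grid and labeled columns) plus a JSON metadata
#' file carrying engine id, status, and report shapes.
#'
#' @param rs a [result_set()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, defaults to the engine id.
#' @return invisibly, the paths written.
#' @export
write_resultset <- function(rs, dir, prefix = rs$engine_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(rs$reports)) {
    r <- rs$reports[[id]]
    df <- as.data.frame(r$values)
    names(df) <- r$labels
    p <- file.path(dir, paste0(prefix, "_", id, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(engine_id = rs$engine_id, status = rs$status,
               message = rs$message,
               reports = lapply(rs$reports, function(r) {
                 list(labels = r$labels, rows = nrow(r$values))
               }))
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
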