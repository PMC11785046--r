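# Deterministic, replayable SED-ML repairs. Every fix is recorded as a
# RepairAction row (code, location, before, after); replaying the log on the
# original document reproduces the repaired one.

#' Repair log constructor
#'
#' @param code action code, one of `rewrite-source`, `prune-unused`,
#'   `dedupe-id`, `fix-target`, `cap-points`.
#' @param location document path of the element acted on.
#' @param before,after textual representation of the change.
#' @return data frame of class `repair_log`.
#' @export
repair_log <- function(code = character(), location = character(),
                       before = character(), after = character()) {
  allowed <- c("rewrite-source", "prune-unused", "dedupe-id", "fix-target",
               "cap-points")
  stopifnot(all(code %in% allowed))
  structure(data.frame(code = as.character(code),
                       location = as.character(location),
                       before = as.character(before),
                       after = as.character(after),
                       stringsAsFactors = FALSE),
            class = c("repair_log", "data.frame"))
}

bind_logs <- function(...) {
  logs <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, list(...))
  if (length(logs) == 0) return(repair_log())
  structure(do.call(rbind, lapply(logs, as.data.frame)),
            class = c("repair_log", "data.frame"))
}

#' Serialize a repair log as JSON lines
#' @param log a [repair_log()].
#' @param path file to write; one JSON object per line.
#' @export
write_repair_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, , drop = FALSE]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# normalized filename similarity in [0, 1] via Levenshtein distance
filename_similarity <- function(a, b) {
  a <- tolower(basename(a)); b <- tolower(basename(b))
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b), 1)
}

# fraction of the document's model-element targets resolvable in a candidate
target_resolution_fraction <- function(doc, handle) {
  targets <- character(0)
  for (m in doc$models) {
    targets <- c(targets, vapply(m$changes, `[[`, "", "target"))
  }
  for (d in doc$data_generators) {
    for (v in d$variables) {
      if (is.na(v$symbol %||% NA) && !is.na(v$target %||% NA)) {
        targets <- c(targets, v$target)
      }
    }
  }
  if (length(targets) == 0) return(0)
  ids <- sbml_all_ids(handle)
  hits <- vapply(targets, function(t) {
    pt <- parse_target(t)
    pt$valid && pt$id %in% ids
  }, logical(1))
  mean(hits)
}

#' Rewrite dangling model sources to actual archive files
#'
#' Legacy experiment files routinely point at a fictitious `model.xml`. Every
#' model whose source is absent from the archive is rewritten: with a single
#' SBML payload the choice is forced; with several, candidates are scored by
#' `0.5 * filename similarity + 0.5 * fraction of the document's targets
#' resolvable in the candidate`, ties broken by lexicographically smallest
#' location. Deterministic by construction.
#'
#' @param doc a [sed_document()].
#' @param archive an [omex_archive()] with at least one SBML payload.
#' @param weights length-2 numeric: filename-similarity and target-resolution
#'   weights.
#' @return list with `doc` and `log` ([repair_log()]).
#' @section Errors: `"no-candidate"` when the archive holds no SBML at all.
#' @export
resolve_model_sources <- function(doc, archive, weights = c(0.5, 0.5)) {
  log <- repair_log()
  sbml_locs <- archive_locations_of(archive, "sbml")
  for (i in seq_along(doc$models)) {
    m <- doc$models[[i]]
    if (m$source %in% names(archive$payload)) next
    if (length(sbml_locs) == 0) {
      vk_stop("no-candidate",
              paste("no SBML payload to resolve source", m$source))
    }
    chosen <- if (length(sbml_locs) == 1) {
      sbml_locs
    } else {
      scores <- vapply(sbml_locs, function(loc) {
        h <- tryCatch(read_sbml(archive$payload[[loc]]),
                      error = function(e) NULL)
        frac <- if (is.null(h)) 0 else target_resolution_fraction(doc, h)
        weights[1] * filename_similarity(m$source, loc) + weights[2] * frac
      }, 0)
      best <- sbml_locs[scores == max(scores)]
      sort(best)[1]
    }
    log <- bind_logs(log, repair_log("rewrite-source",
                                     paste0("model:", m$id),
                                     m$source, chosen))
    doc$models[[i]]$source <- chosen
  }
  list(doc = doc, log = log)
}

# ids reachable from outputs, walking output -> datagen -> task -> model/sim
reachable_ids <- function(doc) {
  dg_ids <- unique(unlist(lapply(doc$outputs, function(o) {
    if (o$kind == "report") vapply(o$items, `[[`, "", "ref")
    else unlist(lapply(o$items, function(it) c(it$x, it$y)))
  }))) %||% character(0)
  dgs <- Filter(function(d) d$id %in% dg_ids, doc$data_generators)
  task_ids <- unique(unlist(lapply(dgs, function(d) {
    vapply(d$variables, `[[`, "", "task_ref")
  }))) %||% character(0)
  tasks <- Filter(function(t) t$id %in% task_ids, doc$tasks)
  list(
    data_generators = dg_ids,
    tasks = task_ids,
    simulations = unique(vapply(tasks, `[[`, "", "simulation_ref")),
    models = unique(vapply(tasks, `[[`, "", "model_ref"))
  )
}

#' Remove elements unreachable from any output
#'
#' Reachability is computed transitively from the outputs (reports and
#' plots): data generators they reference, tasks those use, and the models
#' and simulations those tasks bind. Everything else is removed and logged.
#'
#' @param doc a [sed_document()].
#' @return list with `doc` and `log`.
#' @export
prune_unused <- function(doc) {
  reach <- reachable_ids(doc)
  log <- repair_log()
  drop_from <- function(elements, keep_ids, what) {
    kept <- list()
    for (e in elements) {
      if (e$id %in% keep_ids) kept[[length(kept) + 1]] <- e
      else log <<- bind_logs(log, repair_log("prune-unused",
                                             paste0(what, ":", e$id),
                                             e$id, ""))
    }
    kept
  }
  doc$data_generators <- drop_from(doc$data_generators,
                                   reach$data_generators, "dataGenerator")
  doc$tasks <- drop_from(doc$tasks, reach$tasks, "task")
  doc$simulations <- drop_from(doc$simulations, reach$simulations,
                               "simulation")
  doc$models <- drop_from(doc$models, reach$models, "model")
  list(doc = doc, log = log)
}

# structural identity ignores nothing: whole record equality
element_identical <- function(a, b) identical(a, b)

#' Collapse or rename duplicated ids
#'
#' Structurally identical duplicates collapse to the first occurrence;
#' same-id-different-content elements keep their content but get a fresh id
#' with a numeric suffix (`_2`, `_3`, ...). References continue to resolve to
#' the first occurrence, which preserves the semantics of every reference
#' that was previously ambiguous-but-resolvable.
#'
#' @param doc a [sed_document()].
#' @return list with `doc` and `log`.
#' @export
dedupe_ids <- function(doc) {
  log <- repair_log()
  taken <- sed_all_ids(doc)
  seen <- list()
  dedupe_coll <- function(elements, what) {
    kept <- list()
    for (e in elements) {
      prev <- seen[[e$id]]
      if (is.null(prev)) {
        seen[[e$id]] <<- e
        kept[[length(kept) + 1]] <- e
      } else if (element_identical(prev, e)) {
        log <<- bind_logs(log, repair_log("dedupe-id",
                                          paste0(what, ":", e$id),
                                          e$id, "collapsed into first"))
      } else {
        new_id <- e$id; k <- 2
        repeat {
          new_id <- paste0(e$id, "_", k)
          if (!(new_id %in% taken)) break
          k <- k + 1
        }
        taken <<- c(taken, new_id)
        log <<- bind_logs(log, repair_log("dedupe-id",
                                          paste0(what, ":", e$id),
                                          e$id, new_id))
        e$id <- new_id
        seen[[new_id]] <<- e
        kept[[length(kept) + 1]] <- e
      }
    }
    kept
  }
  doc$models <- dedupe_coll(doc$models, "model")
  doc$simulations <- dedupe_coll(doc$simulations, "simulation")
  doc$tasks <- dedupe_coll(doc$tasks, "task")
  doc$data_generators <- dedupe_coll(doc$data_generators, "dataGenerator")
  doc$outputs <- dedupe_coll(doc$outputs, "output")
  list(doc = doc, log = log)
}

#' Canonicalize incorrectly formatted element pointers
#'
#' A pointer that does not resolve but addresses an id that exists in the
#' model (bare id, unprefixed XPath, differently-quoted selector) is
#' rewritten to the canonical prefixed id-selector form
#' `/sbml:sbml/sbml:model/sbml:listOfX/sbml:x[@id='...']`. Pointers whose id
#' cannot be found are left untouched and reported via `issues`.
#'
#' @param doc a [sed_document()].
#' @param model an `sbml_handle` the pointers should resolve in.
#' @return list with `doc`, `log`, and `issues`.
#' @export
repair_targets <- function(doc, model) {
  log <- repair_log()
  issues <- vk_no_issues()
  ids <- sbml_all_ids(model)
  fix <- function(target, where) {
    pt <- parse_target(target)
    if (pt$canonical && pt$id %in% ids) return(target)
    if (pt$valid && pt$id %in% ids) {
      canon <- canonical_target_for(model, pt$id)
      if (!is.na(canon) && !identical(canon, target)) {
        log <<- bind_logs(log, repair_log("fix-target", where, target, canon))
        return(canon)
      }
      return(target)
    }
    issues <<- rbind_issues(issues, vk_issues(
      if (pt$valid) "dangling-target" else "malformed-target", where,
      target %||% ""))
    target
  }
  for (i in seq_along(doc$models)) {
    for (j in seq_along(doc$models[[i]]$changes)) {
      tgt <- doc$models[[i]]$changes[[j]]$target
      doc$models[[i]]$changes[[j]]$target <-
        fix(tgt, paste0("model:", doc$models[[i]]$id, "/change", j))
    }
  }
  for (i in seq_along(doc$data_generators)) {
    d <- doc$data_generators[[i]]
    for (j in seq_along(d$variables)) {
      v <- d$variables[[j]]
      if (!is.na(v$symbol %||% NA)) next
      doc$data_generators[[i]]$variables[[j]]$target <-
        fix(v$target, paste0("dataGenerator:", d$id, "/", v$id))
    }
  }
  list(doc = doc, log = log, issues = issues)
}

#' Cap requested output points
#'
#' Time courses requesting more than `cap` output intervals (legacy files ask
#' for millions, which bogs simulators down) are clamped to `cap`.
#'
#' @param doc a [sed_document()].
#' @param cap maximum number of output intervals (default 100000).
#' @return list with `doc` and `log`.
#' @export
cap_points <- function(doc, cap = 100000L) {
  stopifnot(cap >= 1)
  log <- repair_log()
  for (i in seq_along(doc$simulations)) {
    s <- doc$simulations[[i]]
    if (!identical(s$type, "uniformTimeCourse")) next
    if (s$number_of_steps > cap) {
      log <- bind_logs(log, repair_log("cap-points",
                                       paste0("simulation:", s$id),
                                       as.character(s$number_of_steps),
                                       as.character(cap)))
      doc$simulations[[i]]$number_of_steps <- as.integer(cap)
    }
  }
  list(doc = doc, log = log)
}

#' Apply the full repair catalogue
#'
#' Runs [resolve_model_sources()], [dedupe_ids()], [repair_targets()],
#' [prune_unused()], [cap_points()] in that order (sources must resolve
#' before targets can be checked; pruning comes late so nothing reachable is
#' lost mid-repair) and combines the logs. Idempotent: repairing a repaired
#' document is the identity with an empty log.
#'
#' @param doc a [sed_document()].
#' @param archive an [omex_archive()] with the model payloads.
#' @param model optional `sbml_handle` for target canonicalization; defaults
#'   to the first resolvable model source in the archive.
#' @param cap output-interval cap passed to [cap_points()].
#' @return list with `doc`, `log`, and `issues`.
#' @export
repair_all <- function(doc, archive, model = NULL, cap = 100000L) {
  r1 <- resolve_model_sources(doc, archive)
  r2 <- dedupe_ids(r1$doc)
  if (is.null(model)) {
    src <- if (length(r2$doc$models) > 0) r2$doc$models[[1]]$source else NULL
    if (!is.null(src) && src %in% names(archive$payload)) {
      model <- tryCatch(read_sbml(archive$payload[[src]]),
                        error = function(e) NULL)
    }
  }
  if (!is.null(model)) {
    r3 <- repair_targets(r2$doc, model)
  } else {
    r3 <- list(doc = r2$doc, log = repair_log(), issues = vk_no_issues())
  }
  r4 <- prune_unused(r3$doc)
  r5 <- cap_points(r4$doc, cap)
  list(doc = r5$doc,
       log = bind_logs(r1$log, r2$log, r3$log, r4$log, r5$log),
       issues = r3$issues)
}
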