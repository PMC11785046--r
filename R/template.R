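#' Generate a template time-course experiment for a model
#'
#' For models lacking a curated experiment, builds the generic experiment
#' used repository-wide: load the model, run a deterministic ODE time course
#' for ten time units, and export the levels of all dynamic variables both as
#' a table of values per time point (report) and as a plot of each variable
#' against time. Such a template does not reproduce any publication figure,
#' but two engines agreeing on it shows the model is robust to
#' interpretation.
#'
#' @param model an `sbml_handle`.
#' @param model_location archive-relative path the document's model source
#'   should point at.
#' @param number_of_steps output intervals (default 100, i.e. 101 points; the
#'   duration of ten time units is the fixed part, the grid density a
#'   plot-friendly default).
#' @param algorithm KiSAO id; defaults to CVODE-style deterministic ODE
#'   integration (`KISAO:0000019`).
#' @return a [sed_document()] (L1V4) with one model, one uniform time course
#'   (`output_end_time = 10`), one task, data generators for time and each
#'   dynamic variable, one report and one 2D plot.
#' @section Errors: `"nothing-to-plot"` when the model has no dynamic
#'   variable.
#' @export
build_template <- function(model, model_location,
                           number_of_steps = 100L,
                           algorithm = KISAO$cvode) {
  vars <- list_dynamic_variables(model)
  if (length(vars) == 0) {
    vk_stop("nothing-to-plot", "model has no dynamic variables")
  }
  mod <- sed_model("model", model_location)
  sim <- sed_uniform_timecourse("sim", 0, 0, 10, number_of_steps, algorithm)
  task <- sed_task("task", "model", "sim")
  dgs <- list(sed_data_generator(
    "dg_time",
    list(list(id = "var_time", task_ref = "task", target = NA_character_,
              symbol = TIME_SYMBOL)),
    as.name("var_time")))
  for (v in vars) {
    dgs[[length(dgs) + 1]] <- sed_data_generator(
      paste0("dg_", v),
      list(list(id = paste0("var_", v), task_ref = "task",
                target = canonical_target_for(model, v),
                symbol = NA_character_)),
      as.name(paste0("var_", v)))
  }
  report <- sed_output("report", "report", c(
    list(list(label = "time", ref = "dg_time")),
    lapply(vars, function(v) list(label = v, ref = paste0("dg_", v)))))
  plot <- sed_output("plot2d", "plot", lapply(vars, function(v) {
    list(x = "dg_time", y = paste0("dg_", v))
  }))
  sed_document(models = list(mod), simulations = list(sim),
               tasks = list(task), data_generators = dgs,
               outputs = list(report, plot), level = 1L, version = 4L)
}
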