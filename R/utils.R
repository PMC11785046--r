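#' @keywords internal
"_PACKAGE"

# Signal a classed error whose condition class carries the machine-readable
# code, so callers can dispatch on e.g. class "manifest-absent".
vk_stop <- function(code, message) {
  stop(structure(
    class = c(code, "verikit_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = sys.call(-1))
  ))
}

# Diagnostic issues are plain data frames: one row per finding.
vk_issues <- function(code = character(), location = character(),
                      detail = character()) {
  data.frame(code = as.character(code), location = as.character(location),
             detail = as.character(detail), stringsAsFactors = FALSE)
}

vk_no_issues <- function() vk_issues()

rbind_issues <- function(...) {
  do.call(rbind, Filter(function(x) is.data.frame(x) && nrow(x) > 0, list(...))) %||%
    vk_no_issues()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn topological sort over a dependency map: deps[[id]] lists the ids that
# must come before id. Errors with `cycle_code` on a cycle.
topo_sort <- function(ids, deps, cycle_code = "cyclic-dependencies") {
  ordered <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(id) {
      all(!(deps[[id]] %in% remaining))
    }, logical(1))]
    if (length(ready) == 0) {
      vk_stop(cycle_code, paste("dependency cycle among:",
                                paste(remaining, collapse = ", ")))
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

# Numeric attribute parsing tolerant of SBML spellings of non-finite values.
parse_sbml_number <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NA_real_)
  low <- tolower(trimws(s))
  if (low %in% c("inf", "+inf", "infinity")) return(Inf)
  if (low %in% c("-inf", "-infinity")) return(-Inf)
  if (low == "nan") return(NaN)
  suppressWarnings(as.numeric(s))
}

format_sbml_number <- function(x) {
  if (is.nan(x)) return("NaN")
  if (is.infinite(x)) return(if (x > 0) "INF" else "-INF")
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}
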