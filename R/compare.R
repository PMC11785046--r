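# The replication criterion: two trajectories for the same labeled output
# agree when every point satisfies an additive relative-plus-absolute bound,
# with the absolute part scaled by the range of that variable's output
# values. The relative default of 1e-4 is the repository-wide replication
# tolerance; the range scaling keeps the criterion meaningful for variables
# living at any magnitude.

#' Comparison policy
#'
#' @param relative_tolerance per-point relative tolerance (default `1e-4`,
#'   the corpus replication criterion).
#' @param range_atol_factor the absolute tolerance is this factor times the
#'   pooled range of the two trajectories; defaults to the relative
#'   tolerance.
#' @param absolute_floor lower bound on the absolute tolerance so that
#'   constant (zero-range) columns can still match (default `1e-12`).
#' @param nan_policy `"fail-on-any-nan"` (default: a non-finite output is
#'   evidence of failure) or `"fail-unless-both-nan"` (pointwise-matching
#'   NaNs count as agreement).
#' @return list of class `comparison_policy`.
#' @export
comparison_policy <- function(relative_tolerance = 1e-4,
                              range_atol_factor = relative_tolerance,
                              absolute_floor = 1e-12,
                              nan_policy = c("fail-on-any-nan",
                                             "fail-unless-both-nan")) {
  stopifnot(relative_tolerance >= 0, range_atol_factor >= 0,
            absolute_floor >= 0)
  structure(list(relative_tolerance = relative_tolerance,
                 range_atol_factor = range_atol_factor,
                 absolute_floor = absolute_floor,
                 nan_policy = match.arg(nan_policy)),
            class = "comparison_policy")
}

#' Compare one output variable between two engines
#'
#' Verdict is pass iff for every point
#' `|a_i - b_i| <= rtol * max(|a_i|, |b_i|) + atol_v`, where
#' `atol_v = max(range_atol_factor * range(a, b), absolute_floor)`. The
#' `max(|a|, |b|)` normalization makes the verdict symmetric in its
#' arguments: no engine is privileged as the reference.
#'
#' @param a,b equal-length numeric trajectories on identical output grids.
#' @param policy a [comparison_policy()].
#' @param label variable label carried into the verdict.
#' @return list of class `variable_verdict`: `label`, `max_abs_dev`,
#'   `max_rel_dev`, `passed`.
#' @section Errors: `"shape-mismatch"` on unequal lengths.
#' @export
compare_variables <- function(a, b, policy = comparison_policy(),
                              label = "") {
  if (length(a) != length(b)) {
    vk_stop("shape-mismatch", sprintf("lengths %d vs %d",
                                      length(a), length(b)))
  }
  a <- as.numeric(a); b <- as.numeric(b)
  both_nan <- is.nan(a) & is.nan(b)
  nonfinite <- !is.finite(a) | !is.finite(b)
  if (policy$nan_policy == "fail-unless-both-nan") {
    nonfinite <- nonfinite & !both_nan
  }
  nan_fail <- any(nonfinite)
  keep <- is.finite(a) & is.finite(b)
  if (!any(keep)) {
    return(structure(list(label = label, max_abs_dev = Inf,
                          max_rel_dev = Inf, passed = !nan_fail),
                     class = "variable_verdict"))
  }
  af <- a[keep]; bf <- b[keep]
  rng <- max(c(af, bf)) - min(c(af, bf))
  atol_v <- max(policy$range_atol_factor * rng, policy$absolute_floor)
  absdev <- abs(af - bf)
  scale <- pmax(abs(af), abs(bf))
  ok <- absdev <= policy$relative_tolerance * scale + atol_v
  reldev <- ifelse(scale > 0, absdev / scale, 0)
  structure(list(label = label,
                 max_abs_dev = max(absdev),
                 max_rel_dev = max(reldev),
                 passed = all(ok) && !nan_fail),
            class = "variable_verdict")
}

#' Compare two result sets
#'
#' Reports are matched by report id and columns by label; the comparison
#' passes iff the shared label set is non-empty and every shared labeled
#' column passes under the policy. Shape or output-grid mismatches are a
#' fail verdict with a reason, not an exception: a grid mismatch signals a
#' divergent interpretation of the experiment, which is exactly what
#' verification must surface. No interpolation is done.
#'
#' @param A,B successful [result_set()]s.
#' @param policy a [comparison_policy()].
#' @return list of class `comparison_report`: `passed`, `reason`,
#'   `verdicts` (data frame: report, label, max_abs_dev, max_rel_dev,
#'   passed).
#' @export
compare_resultsets <- function(A, B, policy = comparison_policy()) {
  fail <- function(reason) {
    structure(list(passed = FALSE, reason = reason,
                   verdicts = data.frame()),
              class = "comparison_report")
  }
  if (!identical(A$status, "success") || !identical(B$status, "success")) {
    return(fail("not-both-successful"))
  }
  shared_reports <- intersect(names(A$reports), names(B$reports))
  if (length(shared_reports) == 0) return(fail("no-shared-outputs"))
  verdicts <- data.frame()
  any_shared_label <- FALSE
  for (rid in shared_reports) {
    ra <- A$reports[[rid]]; rb <- B$reports[[rid]]
    shared <- intersect(ra$labels, rb$labels)
    if (length(shared) == 0) next
    if (nrow(ra$values) != nrow(rb$values)) {
      return(fail(paste0("shape-mismatch:", rid)))
    }
    if (!isTRUE(all(ra$time == rb$time))) {
      return(fail(paste0("grid-mismatch:", rid)))
    }
    any_shared_label <- TRUE
    for (lab in shared) {
      v <- compare_variables(ra$values[, match(lab, ra$labels)],
                             rb$values[, match(lab, rb$labels)],
                             policy, label = lab)
      verdicts <- rbind(verdicts, data.frame(
        report = rid, label = lab, max_abs_dev = v$max_abs_dev,
        max_rel_dev = v$max_rel_dev, passed = v$passed,
        stringsAsFactors = FALSE))
    }
  }
  if (!any_shared_label) return(fail("no-shared-outputs"))
  structure(list(passed = all(verdicts$passed), reason = "",
                 verdicts = verdicts),
            class = "comparison_report")
}

#' Aggregate cross-engine runs into a verification matrix
#'
#' Pairwise comparisons among all successful runs of one entry. Replication
#' is achieved iff at least one pair of engines passes the comparator; with
#' fewer than two successful runs there is nothing to compare and the entry
#' cannot be replicated.
#'
#' @param entry_id identifier of the entry.
#' @param runs named list, engine id -> [result_set()].
#' @param policy a [comparison_policy()].
#' @return list of class `verification_matrix`: `entry_id`,
#'   `engine_statuses` (named character), `pairwise` (data frame: engine_a,
#'   engine_b, passed, reason), `ran_count`, `replicated`.
#' @export
build_verification_matrix <- function(entry_id, runs,
                                      policy = comparison_policy()) {
  stopifnot(length(runs) >= 1, !is.null(names(runs)))
  statuses <- vapply(runs, function(r) r$status, "")
  successes <- names(statuses)[statuses == "success"]
  pairwise <- data.frame(engine_a = character(), engine_b = character(),
                         passed = logical(), reason = character(),
                         stringsAsFactors = FALSE)
  if (length(successes) >= 2) {
    pairs <- utils::combn(sort(successes), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      rep <- compare_resultsets(runs[[a]], runs[[b]], policy)
      pairwise <- rbind(pairwise, data.frame(
        engine_a = a, engine_b = b, passed = rep$passed,
        reason = rep$reason, stringsAsFactors = FALSE))
    }
  }
  structure(list(entry_id = entry_id, engine_statuses = statuses,
                 pairwise = pairwise,
                 ran_count = length(successes),
                 replicated = any(pairwise$passed)),
            class = "verification_matrix")
}

#' @export
print.verification_matrix <- function(x, ...) {
  cat(sprintf("<verification_matrix %s> ran=%d replicated=%s\n",
              x$entry_id, x$ran_count, x$replicated))
  for (e in names(x$engine_statuses)) {
    cat("  ", e, ": ", x$engine_statuses[[e]], "\n", sep = "")
  }
  if (nrow(x$pairwise) > 0) {
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s ~ %s : %s\n", x$pairwise$engine_a[i],
                  x$pairwise$engine_b[i],
                  if (x$pairwise$passed[i]) "match" else
                    paste("mismatch", x$pairwise$reason[i])))
    }
  }
  invisible(x)
}

verification_matrix_to_list <- function(m) {
  list(entry_id = m$entry_id,
       engine_statuses = as.list(m$engine_statuses),
       pairwise = m$pairwise,
       ran_count = m$ran_count,
       replicated = m$replicated)
}
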