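test_that("the replication criterion accepts and rejects as specified", {
  b <- 0:10
  expect_true(compare_variables(b, b)$passed)
  expect_identical(compare_variables(b, b)$max_abs_dev, 0)

  # uniform 5e-5 down-scaling stays inside the 1e-4 relative tolerance
  a <- b * (1 - 5e-5)
  expect_true(compare_variables(a, b)$passed)

  # a 10%-of-range shift fails
  a2 <- b + 0.1 * diff(range(b))
  expect_false(compare_variables(a2, b)$passed)

  # constant equal columns (zero range) pass via the absolute floor
  expect_true(compare_variables(rep(3, 5), rep(3, 5))$passed)

  expect_vk_error(compare_variables(1:3, 1:4), "shape-mismatch")
})

test_that("the verdict is symmetric and monotone in the tolerances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- stats::rnorm(n, sd = 10^stats::runif(1, -6, 2))
    b <- a + stats::rnorm(n, sd = 10^stats::runif(1, -10, -2))
    pol <- comparison_policy(
      relative_tolerance = 10^stats::runif(1, -6, -2),
      range_atol_factor = 10^stats::runif(1, -6, -2))
    va <- compare_variables(a, b, pol)
    vb <- compare_variables(b, a, pol)
    expect_identical(va$passed, vb$passed)
    expect_identical(va$max_abs_dev, vb$max_abs_dev)
    # loosening either tolerance never flips pass -> fail
    looser1 <- comparison_policy(pol$relative_tolerance * 10,
                                 pol$range_atol_factor)
    looser2 <- comparison_policy(pol$relative_tolerance,
                                 pol$range_atol_factor * 10)
    if (va$passed) {
      expect_true(compare_variables(a, b, looser1)$passed)
      expect_true(compare_variables(a, b, looser2)$passed)
    }
  }
})

test_that("with absolute terms disabled the pass boundary sits at rtol", {
  pol <- comparison_policy(relative_tolerance = 1e-4,
                           range_atol_factor = 0, absolute_floor = 0)
  b <- as.numeric(1:101)
  # the criterion |a-b| <= rtol*max(|a|,|b|) on a = b*(1-delta) reduces to
  # delta <= rtol exactly
  expect_true(compare_variables(b * (1 - 0.99e-4), b, pol)$passed)
  expect_false(compare_variables(b * (1 - 1.01e-4), b, pol)$passed)
})

test_that("NaN outputs fail by default, matched NaNs pass when allowed", {
  a <- c(1, NaN, 3); b <- c(1, NaN, 3)
  expect_false(compare_variables(a, b)$passed)
  lax <- comparison_policy(nan_policy = "fail-unless-both-nan")
  expect_true(compare_variables(a, b, lax)$passed)
  expect_false(compare_variables(c(1, NaN, 3), c(1, 2, 3), lax)$passed)
})

test_that("result-set comparison matches by report id and label", {
  mk <- function(values, labels, engine = "e", time = NULL) {
    if (is.null(time)) time <- seq_len(nrow(values))
    result_set(engine, "success", reports = list(
      report = list(labels = labels, values = values, time = time)))
  }
  v <- cbind(1:10, (1:10) * 2)
  A <- mk(v, c("x", "y"))
  expect_true(compare_resultsets(A, A)$passed)

  # one column shifted by 10% of its range: fail, offender named
  v2 <- v; v2[, 2] <- v2[, 2] + 0.1 * diff(range(v2[, 2]))
  B <- mk(v2, c("x", "y"))
  r <- compare_resultsets(A, B)
  expect_false(r$passed)
  expect_identical(r$verdicts$label[!r$verdicts$passed], "y")

  # disjoint label sets
  C <- mk(v, c("p", "q"))
  r2 <- compare_resultsets(A, C)
  expect_false(r2$passed)
  expect_identical(r2$reason, "no-shared-outputs")

  # grid mismatch is a verdict, not an exception
  D <- mk(v, c("x", "y"), time = seq_len(nrow(v)) + 0.5)
  r3 <- compare_resultsets(A, D)
  expect_false(r3$passed)
  expect_match(r3$reason, "grid-mismatch")

  # failed runs cannot pass
  E <- result_set("e", "failure", message = "boom")
  expect_false(compare_resultsets(A, E)$passed)
})

test_that("verification matrices agree with exhaustive pair enumeration", {
  mk_run <- function(ok, shift = 0) {
    if (!ok) return(result_set("x", "failure", message = "err"))
    v <- cbind(1:20, sin(1:20) + shift)
    result_set("x", "success", reports = list(
      report = list(labels = c("t", "y"), values = v, time = 1:20)))
  }
  set.seed(99)
  for (trial in 1:15) {
    n <- sample(2:5, 1)
    ok <- stats::runif(n) < 0.7
    shift <- ifelse(stats::runif(n) < 0.5, 0, 1)  # two result families
    runs <- lapply(seq_len(n), function(i) mk_run(ok[i], shift[i]))
    names(runs) <- paste0("engine", seq_len(n))
    m <- build_verification_matrix("entry", runs)
    expect_identical(m$ran_count, sum(ok))
    # brute force: enumerate every pair of successes
    brute <- FALSE
    succ <- which(ok)
    if (length(succ) >= 2) {
      for (i in succ) for (j in succ) {
        if (i < j && shift[i] == shift[j]) brute <- TRUE
      }
    }
    expect_identical(m$replicated, brute)
    # pairwise keys only among successes
    expect_true(all(c(m$pairwise$engine_a, m$pairwise$engine_b) %in%
                      paste0("engine", succ)))
  }

  # single success: nothing to compare against
  m1 <- build_verification_matrix("e", list(a = mk_run(TRUE),
                                            b = mk_run(FALSE)))
  expect_identical(m1$ran_count, 1L)
  expect_false(m1$replicated)
  expect_identical(nrow(m1$pairwise), 0L)

  # three successes with one divergent engine: replicated, and the outlier
  # is identifiable from the pairwise map
  runs3 <- list(a = mk_run(TRUE, 0), b = mk_run(TRUE, 0),
                c = mk_run(TRUE, 1))
  m3 <- build_verification_matrix("e", runs3)
  expect_true(m3$replicated)
  bad <- m3$pairwise[!m3$pairwise$passed, ]
  expect_setequal(unique(c(bad$engine_a, bad$engine_b))[
    !(unique(c(bad$engine_a, bad$engine_b)) %in%
        c(m3$pairwise$engine_a[m3$pairwise$passed],
          m3$pairwise$engine_b[m3$pairwise$passed]))], "c")
})
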