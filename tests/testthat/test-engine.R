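test_that("compiled right-hand side matches hand stoichiometry", {
  sys <- compile_odes(read_sbml(make_chain_model(2, 1, c(1, 0))))
  expect_identical(sys$state_ids, c("S1", "S2"))
  expect_equal(sys$rhs(0, c(1, 0)), c(-1, 1))
  expect_equal(sys$rhs(0, c(0.25, 0)), c(-0.25, 0.25))

  # events are outside the declared subset
  with_event <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="false"/></listOfSpecies>',
    '<listOfEvents><event id="e1" useValuesFromTriggerTime="true">',
    '<trigger initialValue="true" persistent="true">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><true/></math>',
    "</trigger></event></listOfEvents>"))
  err <- tryCatch(compile_odes(read_sbml(with_event)), condition = identity)
  expect_s3_class(err, "unsupported-model-feature")
  expect_match(conditionMessage(err), "event")
})

test_that("assignment-rule observables track their expression pointwise", {
  b <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="false"/></listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="k1" value="0.5" constant="true"/>',
    '<parameter id="y" value="0" constant="false"/>',
    "</listOfParameters>",
    '<listOfRules><assignmentRule variable="y">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><cn>2</cn><ci>S1</ci></apply></math>",
    "</assignmentRule></listOfRules>",
    '<listOfReactions><reaction id="J1" reversible="false">',
    '<listOfReactants><speciesReference species="S1" stoichiometry="1"',
    ' constant="true"/></listOfReactants><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><ci>k1</ci><ci>S1</ci></apply></math>",
    "</kineticLaw></reaction></listOfReactions>"))
  h <- read_sbml(b)
  expect_identical(list_dynamic_variables(h), c("S1", "y"))
  sys <- compile_odes(h)
  traj <- run_timecourse(sys, sed_uniform_timecourse("s", 0, 0, 4, 50))
  expect_equal(unname(traj[, "y"]), unname(2 * traj[, "S1"]),
               tolerance = 1e-12)
})

test_that("model changes rescale the compiled dynamics", {
  h <- read_sbml(chain3_bytes())
  ch <- list(list(
    target = "/sbml:sbml/sbml:model/sbml:listOfParameters/sbml:parameter[@id='k1']",
    new_value = "2"))
  h2 <- apply_changes(h, ch)
  s1 <- compile_odes(h)
  s2 <- compile_odes(h2)
  expect_equal(s2$rhs(0, c(1, 0, 0))[1], 2 * s1$rhs(0, c(1, 0, 0))[1])

  expect_identical(as.character(apply_changes(h, list())$doc),
                   as.character(h$doc))

  # promoted local parameters become changeable
  hl <- read_sbml(chain3_bytes(local_params = TRUE))
  hp <- promote_local_parameters(hl)$model
  hp2 <- apply_changes(hp, list(list(target = "J1_k", new_value = "3")))
  par <- sbml_parameters(hp2)
  expect_equal(par$value[par$id == "J1_k"], 3)

  expect_vk_error(apply_changes(h, list(list(target = "ghost",
                                             new_value = "1"))),
                  "dangling-target")
  expect_vk_error(apply_changes(h, list(list(
    target = "/sbml:sbml/sbml:model/sbml:listOfParameters/sbml:parameter[@id='k1']",
    new_value = "fast"))), "bad-value")
})

test_that("the absolute-tolerance vector follows the initial-value scaling", {
  s <- solver_settings(atol_adjustment_factor = 1e-12)
  expect_equal(make_atol_vector(s, c(1, 1e-6)), c(1e-12, 1e-18))
  # unset factor: uniform base value
  expect_equal(make_atol_vector(solver_settings(), c(1, 1e-6, 5)),
               rep(1e-12, 3))
  # zero initial values floor at the base tolerance
  expect_equal(make_atol_vector(s, c(2, 0)), c(2e-12, 1e-12))
  # homogeneity on the nonzero entries
  x0 <- c(1, 3e-4, 7e2)
  expect_equal(make_atol_vector(s, 10 * x0), 10 * make_atol_vector(s, x0))
})

test_that("reference engine matches the Bateman oracle on chains up to n=5", {
  set.seed(7)
  for (n in 2:5) {
    k <- sort(stats::runif(n - 1, 0.2, 2), decreasing = TRUE)
    x0 <- c(1, rep(0, n - 1))
    sys <- compile_odes(read_sbml(make_chain_model(n, k, x0)))
    sim <- sed_uniform_timecourse("s", 0, 0, 10, 100)
    traj <- run_timecourse(sys, sim)
    cf <- chain_closed_form(k, x0, traj[, "time"])
    expect_lt(max(abs(traj[, colnames(cf)] - cf)), 1e-8)
    # mass conservation on the closed chain
    totals <- rowSums(traj[, colnames(cf), drop = FALSE])
    expect_lt(max(abs(totals - sum(x0))),
              10 * solver_settings()$relative_tolerance * sum(x0))
  }
})

test_that("tightening the relative tolerance does not worsen the error", {
  k <- c(1, 0.5)
  x0 <- c(1, 0, 0)
  sys <- compile_odes(read_sbml(make_chain_model(3, k, x0)))
  sim <- sed_uniform_timecourse("s", 0, 0, 10, 100)
  errs <- vapply(c(1e-4, 1e-5, 1e-6, 1e-7), function(rtol) {
    traj <- run_timecourse(sys, sim, solver_settings(
      relative_tolerance = rtol, base_absolute_tolerance = 1e-14))
    cf <- chain_closed_form(k, x0, traj[, "time"])
    max(abs(traj[, colnames(cf)] - cf))
  }, 0)
  expect_true(all(diff(errs) <= 0))
})

test_that("zero-duration runs return the initial observables", {
  sys <- compile_odes(read_sbml(chain3_bytes()))
  traj <- run_timecourse(sys, sed_uniform_timecourse("s", 0, 0, 0, 1))
  expect_identical(nrow(traj), 1L)
  expect_equal(unname(traj[1, ]), c(0, 1, 0, 0))
})

test_that("data generators compute identity, conservation, and constants", {
  entry <- chain3_entry()
  doc <- parse_sedml(entry$payload[["simulation.sedml"]])
  model <- read_sbml(entry$payload[["biomodel.xml"]])
  sys <- compile_odes(model)
  traj <- run_timecourse(sys, doc$simulations[[1]])
  trajectories <- list(task = traj)

  # identity math: column equals the trajectory
  rs <- evaluate_data_generators(doc, trajectories, model)
  expect_equal(unname(rs$reports$report$values[, "S1"]),
               unname(traj[, "S1"]))

  # conservation: S1+S2+S3 is constant on the closed chain
  d <- doc
  d$data_generators[[5]] <- sed_data_generator(
    "dg_total",
    list(list(id = "a", task_ref = "task",
              target = "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S1']",
              symbol = NA_character_),
         list(id = "b", task_ref = "task",
              target = "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S2']",
              symbol = NA_character_),
         list(id = "cc", task_ref = "task",
              target = "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S3']",
              symbol = NA_character_)),
    quote(a + b + cc))
  d$outputs[[1]]$items[[5]] <- list(label = "total", ref = "dg_total")
  rs2 <- evaluate_data_generators(d, trajectories, model)
  total <- rs2$reports$report$values[, "total"]
  expect_lt(max(abs(total - 1)), 1e-7)

  # constant parameter requested as output: materialized constant column
  d2 <- doc
  d2$data_generators[[5]] <- sed_data_generator(
    "dg_k1",
    list(list(id = "kv", task_ref = "task",
              target = "/sbml:sbml/sbml:model/sbml:listOfParameters/sbml:parameter[@id='k1']",
              symbol = NA_character_)),
    quote(kv))
  d2$outputs[[1]]$items[[5]] <- list(label = "k1", ref = "dg_k1")
  rs3 <- evaluate_data_generators(d2, trajectories, model)
  expect_equal(unname(rs3$reports$report$values[, "k1"]), rep(1, 101))

  # undeclared symbol in math
  d3 <- doc
  d3$data_generators[[2]]$math <- quote(var_S1 + ghost)
  expect_vk_error(evaluate_data_generators(d3, trajectories, model),
                  "bad-datagen")
})

test_that("execute captures failures in status instead of raising", {
  entry <- chain3_entry()
  de <- make_defective_entry(entry, "dangling-target", 1)
  rs <- execute(de, "reference-lsoda")
  expect_identical(rs$status, "failure")
  expect_match(rs$message, "dangling-target")

  # repeated runs are bit-identical
  r1 <- execute(entry, "reference-lsoda")
  r2 <- execute(entry, "reference-lsoda")
  expect_identical(r1, r2)
})

test_that("engine registry resolves adapters and rejects unknown ids", {
  expect_true(all(c("reference-lsoda", "reference-bdf") %in% list_engines()))
  expect_identical(get_engine("reference-bdf")$engine_id, "reference-bdf")
  expect_vk_error(get_engine("copasi"), "unknown-engine")
})

test_that("result sets export as CSV with a JSON sidecar", {
  rs <- execute(chain3_entry(), "reference-lsoda")
  dir <- tempfile("rsout")
  paths <- write_resultset(rs, dir)
  csv <- utils::read.csv(file.path(dir, "reference-lsoda_report.csv"),
                         check.names = FALSE)
  expect_identical(names(csv), c("time", "S1", "S2", "S3"))
  expect_identical(nrow(csv), 101L)
  meta <- jsonlite::read_json(file.path(dir, "reference-lsoda_meta.json"))
  expect_identical(meta$status, "success")
  unlink(dir, recursive = TRUE)
})
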