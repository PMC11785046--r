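test_that("dangling model sources resolve to the right SBML candidate", {
  entry <- chain3_entry()
  doc <- parse_sedml(entry$payload[["simulation.sedml"]])

  # single candidate: forced choice
  d <- doc; d$models[[1]]$source <- "model.xml"
  r <- resolve_model_sources(d, entry)
  expect_identical(r$doc$models[[1]]$source, "biomodel.xml")
  expect_identical(r$log$code, "rewrite-source")

  # two candidates: targets resolve only in the real model
  two <- entry
  decoy <- make_chain_model(2, 0.9, c(1, 0), model_id = "decoy")
  decoy_h <- read_sbml(decoy)
  # rename decoy species so template targets don't resolve there
  for (n in xml2::xml_find_all(decoy_h$doc, ".//*[@id]")) {
    id <- xml2::xml_attr(n, "id")
    if (grepl("^S", id)) xml2::xml_set_attr(n, "id", paste0("X", id))
  }
  two$payload[["aaa_decoy.xml"]] <- write_sbml(decoy_h)
  two$entries <- rbind(two$entries, data.frame(
    location = "aaa_decoy.xml", format = omex_format_uri("sbml"),
    master = FALSE))
  d2 <- doc; d2$models[[1]]$source <- "model.xml"
  r2 <- resolve_model_sources(d2, two)
  expect_identical(r2$doc$models[[1]]$source, "biomodel.xml")

  # content score dominates: brute-force check of resolvable-target counts
  frac_real <- verikit:::target_resolution_fraction(
    d2, read_sbml(two$payload[["biomodel.xml"]]))
  frac_decoy <- verikit:::target_resolution_fraction(
    d2, read_sbml(two$payload[["aaa_decoy.xml"]]))
  expect_gt(frac_real, frac_decoy)

  # source already present: identity
  r3 <- resolve_model_sources(doc, entry)
  expect_identical(nrow(r3$log), 0L)
  expect_identical(r3$doc, doc)

  # no SBML at all
  none <- omex_archive(
    data.frame(location = "a.txt", format = "text/plain", master = TRUE),
    list(a.txt = charToRaw("x")))
  d4 <- doc; d4$models[[1]]$source <- "model.xml"
  expect_vk_error(resolve_model_sources(d4, none), "no-candidate")
})

test_that("pruning removes exactly what no output reaches", {
  entry <- chain3_entry()
  doc <- parse_sedml(entry$payload[["simulation.sedml"]])

  d <- doc
  d$simulations[[2]] <- sed_uniform_timecourse("orphan")
  r <- prune_unused(d)
  expect_identical(r$log$location, "simulation:orphan")
  expect_identical(r$doc$simulations, doc$simulations)

  # fully connected document is untouched
  r2 <- prune_unused(doc)
  expect_identical(nrow(r2$log), 0L)

  # a datagen used only by the plot is retained
  d3 <- doc
  d3$outputs <- Filter(function(o) o$kind == "plot2d", d3$outputs)
  r3 <- prune_unused(d3)
  # dg_time is x-axis of every curve; all species datagens are y refs
  expect_identical(length(r3$doc$data_generators),
                   length(doc$data_generators))
})

test_that("duplicate ids collapse or rename depending on content", {
  entry <- chain3_entry()
  doc <- parse_sedml(entry$payload[["simulation.sedml"]])

  d <- doc
  d$simulations[[2]] <- d$simulations[[1]]  # identical duplicate
  r <- dedupe_ids(d)
  expect_identical(length(r$doc$simulations), 1L)
  expect_identical(r$log$code, "dedupe-id")

  d2 <- doc
  other <- d2$simulations[[1]]
  other$output_end_time <- 20
  d2$simulations[[2]] <- other  # same id, different content
  r2 <- dedupe_ids(d2)
  expect_identical(length(r2$doc$simulations), 2L)
  expect_identical(r2$doc$simulations[[2]]$id, "sim_2")

  r3 <- dedupe_ids(doc)
  expect_identical(nrow(r3$log), 0L)
  expect_identical(r3$doc, doc)
})

test_that("pointers are canonicalized but never invented", {
  entry <- chain3_entry()
  model <- read_sbml(entry$payload[["biomodel.xml"]])
  doc <- parse_sedml(entry$payload[["simulation.sedml"]])

  d <- doc
  d$data_generators[[2]]$variables[[1]]$target <-
    "/sbml/model/listOfSpecies/species[@id='S1']"
  r <- repair_targets(d, model)
  expect_identical(
    r$doc$data_generators[[2]]$variables[[1]]$target,
    "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S1']")
  expect_identical(r$log$code, "fix-target")

  # bare id shorthand is expanded too
  d1 <- doc
  d1$data_generators[[2]]$variables[[1]]$target <- "S1"
  r1 <- repair_targets(d1, model)
  expect_identical(
    r1$doc$data_generators[[2]]$variables[[1]]$target,
    "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S1']")

  # unknown id: untouched plus an issue
  d2 <- doc
  bad <- "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='nope']"
  d2$data_generators[[2]]$variables[[1]]$target <- bad
  r2 <- repair_targets(d2, model)
  expect_identical(r2$doc$data_generators[[2]]$variables[[1]]$target, bad)
  expect_identical(r2$issues$code, "dangling-target")

  # already canonical: identity
  r3 <- repair_targets(doc, model)
  expect_identical(nrow(r3$log), 0L)
  expect_identical(r3$doc, doc)
})

test_that("point caps clamp only above the cap", {
  doc <- parse_sedml(chain3_entry()$payload[["simulation.sedml"]])
  d <- doc
  d$simulations[[1]]$number_of_steps <- 5000000L
  r <- cap_points(d, 100000L)
  expect_identical(r$doc$simulations[[1]]$number_of_steps, 100000L)
  expect_identical(r$log$code, "cap-points")

  expect_identical(nrow(cap_points(doc, 100000L)$log), 0L)
  d2 <- doc
  d2$simulations[[1]]$number_of_steps <- 100000L
  expect_identical(nrow(cap_points(d2, 100000L)$log), 0L)  # boundary
})

test_that("repair_all fixes every injected defect kind and is idempotent", {
  entry <- chain3_entry()
  expected_actions <- list(
    "model-xml-source" = "rewrite-source",
    "unused-simulation" = "prune-unused",
    "duplicate-id" = "dedupe-id",
    "malformed-target" = "fix-target",
    "excessive-points" = "cap-points")
  for (defect in names(expected_actions)) {
    de <- make_defective_entry(entry, defect, seed = 5)
    doc <- parse_sedml(de$payload[["simulation.sedml"]])
    r <- repair_all(doc, de)
    expect_true(expected_actions[[defect]] %in% r$log$code, label = defect)
    # repaired document is clean
    expect_identical(nrow(validate_semantics(r$doc, de)), 0L)
    # idempotence
    r2 <- repair_all(r$doc, de)
    expect_identical(nrow(r2$log), 0L)
    expect_identical(r2$doc, r$doc)
  }
  # dangling-target cannot be repaired (targets are never invented): it is
  # surfaced as an issue instead
  de <- make_defective_entry(entry, "dangling-target", seed = 5)
  doc <- parse_sedml(de$payload[["simulation.sedml"]])
  r <- repair_all(doc, de)
  expect_true("dangling-target" %in% r$issues$code)
})

test_that("clean entries pass through repair bit-exactly", {
  entry <- chain3_entry()
  sed_bytes <- entry$payload[["simulation.sedml"]]
  doc <- parse_sedml(sed_bytes)
  r <- repair_all(doc, entry)
  expect_identical(nrow(r$log), 0L)
  expect_identical(write_sedml(r$doc), sed_bytes)
  # and the executed results are bit-identical pre/post repair
  pre <- execute(entry, "reference-lsoda")
  entry2 <- entry
  entry2$payload[["simulation.sedml"]] <- write_sedml(r$doc)
  post <- execute(entry2, "reference-lsoda")
  expect_identical(pre$reports, post$reports)
})

test_that("repair logs serialize as JSON lines", {
  de <- make_defective_entry(chain3_entry(), "model-xml-source", 1)
  doc <- parse_sedml(de$payload[["simulation.sedml"]])
  r <- repair_all(doc, de)
  p <- tempfile(fileext = ".jsonl")
  write_repair_log(r$log, p)
  lines <- readLines(p)
  expect_identical(length(lines), nrow(r$log))
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$code, "rewrite-source")
  unlink(p)
})
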