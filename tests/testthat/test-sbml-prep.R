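test_that("local parameters are promoted to prefixed globals", {
  h <- read_sbml(chain3_bytes(local_params = TRUE))
  r <- promote_local_parameters(h)
  par <- sbml_parameters(r$model)
  expect_setequal(par$id, c("J1_k", "J2_k"))
  expect_equal(par$value, c(1, 0.5))
  rx <- sbml_reactions(r$model)
  expect_identical(nrow(rx[[1]]$local_parameters), 0L)
  # math rewritten to the new ids
  expect_true("J1_k" %in% all.vars(rx[[1]]$kinetic_math))
  expect_identical(r$renames$old, c("k", "k"))

  # no locals -> identity with empty map
  h2 <- read_sbml(chain3_bytes(local_params = FALSE))
  r2 <- promote_local_parameters(h2)
  expect_identical(nrow(r2$renames), 0L)
  expect_identical(as.character(r2$model$doc), as.character(h2$doc))

  # name collision with an existing global gets a numeric suffix
  b <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="false"/></listOfSpecies>',
    '<listOfParameters><parameter id="J1_k" value="9" constant="true"/>',
    "</listOfParameters>",
    '<listOfReactions><reaction id="J1" reversible="false">',
    '<listOfReactants><speciesReference species="S1" stoichiometry="1"',
    ' constant="true"/></listOfReactants><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><ci>k</ci><ci>S1</ci></apply></math>",
    '<listOfLocalParameters><localParameter id="k" value="2"/>',
    "</listOfLocalParameters></kineticLaw></reaction></listOfReactions>"))
  r3 <- promote_local_parameters(read_sbml(b))
  expect_identical(r3$renames$new, "J1_k_2")
})

test_that("promotion preserves simulated trajectories", {
  local_entry <- make_entry(chain3_bytes(local_params = TRUE),
                            write_sedml(build_template(
                              read_sbml(chain3_bytes()), "biomodel.xml")))
  global_entry <- chain3_entry()
  a <- execute(local_entry, "reference-lsoda")
  b <- execute(global_entry, "reference-lsoda")
  expect_identical(a$status, "success")
  expect_true(compare_resultsets(a, b)$passed)
})

test_that("initial assignments are inlined in dependency order", {
  b <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="0"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="false"/></listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="k" value="3" constant="true"/>',
    '<parameter id="a" value="0" constant="false"/>',
    '<parameter id="b" value="0" constant="false"/>',
    "</listOfParameters>",
    "<listOfInitialAssignments>",
    '<initialAssignment symbol="S1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><cn>2</cn><ci>k</ci></apply></math>",
    "</initialAssignment>",
    '<initialAssignment symbol="a">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><plus/><ci>b</ci><cn>1</cn></apply></math>",
    "</initialAssignment>",
    '<initialAssignment symbol="b">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<cn>2</cn></math>",
    "</initialAssignment>",
    "</listOfInitialAssignments>"))
  h <- inline_initial_assignments(read_sbml(b))
  expect_identical(length(sbml_initial_assignments(h)), 0L)
  expect_equal(sbml_species(h)$initial_amount, 6)       # 2 * k
  par <- sbml_parameters(h)
  expect_equal(par$value[par$id == "a"], 3)             # b inlined first
  expect_equal(par$value[par$id == "b"], 2)

  # idempotent / identity on assignment-free models
  h2 <- inline_initial_assignments(h)
  expect_identical(as.character(h2$doc), as.character(h$doc))

  # cycle detection
  bc <- sbml_snippet(paste0(
    '<listOfParameters><parameter id="a" value="0"/>',
    '<parameter id="b" value="0"/></listOfParameters>',
    "<listOfInitialAssignments>",
    '<initialAssignment symbol="a">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>b</ci></math>',
    "</initialAssignment>",
    '<initialAssignment symbol="b">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>a</ci></math>',
    "</initialAssignment></listOfInitialAssignments>"))
  expect_vk_error(inline_initial_assignments(read_sbml(bc)),
                  "cyclic-initial-assignments")

  bu <- sbml_snippet(paste0(
    '<listOfParameters><parameter id="a" value="0"/></listOfParameters>',
    "<listOfInitialAssignments>",
    '<initialAssignment symbol="a">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>ghost</ci></math>',
    "</initialAssignment></listOfInitialAssignments>"))
  expect_vk_error(inline_initial_assignments(read_sbml(bu)),
                  "unresolved-symbol")
})

test_that("inlining initial assignments preserves trajectories", {
  # chain whose k1 is set by an initial assignment to the same value
  b <- chain3_bytes()
  h <- read_sbml(b)
  doc <- h$doc
  mn <- xml2::xml_find_first(doc, "./*[local-name()='model']")
  loi <- xml2::xml_add_child(mn, "listOfInitialAssignments")
  ia <- xml2::xml_add_child(loi, "initialAssignment", symbol = "S1")
  math <- xml2::xml_add_child(ia, "math",
                              xmlns = "http://www.w3.org/1998/Math/MathML")
  ap <- xml2::xml_add_child(math, "apply")
  xml2::xml_add_child(ap, "plus")
  cn1 <- xml2::xml_add_child(ap, "cn"); xml2::xml_set_text(cn1, "0.25")
  cn2 <- xml2::xml_add_child(ap, "cn"); xml2::xml_set_text(cn2, "0.75")
  withia <- charToRaw(as.character(doc))
  tpl <- write_sedml(build_template(read_sbml(withia), "biomodel.xml"))
  pre <- execute(make_entry(withia, tpl), "reference-lsoda")
  inlined <- write_sbml(inline_initial_assignments(read_sbml(withia)))
  post <- execute(make_entry(inlined, tpl), "reference-lsoda")
  expect_identical(pre$status, "success")
  expect_true(compare_resultsets(pre, post)$passed)
})

test_that("non-finite parameters: unused are reset, used are fatal", {
  b <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="false"/></listOfSpecies>',
    "<listOfParameters>",
    '<parameter id="dead" value="NaN" constant="true"/>',
    '<parameter id="alive" value="INF" constant="true"/>',
    "</listOfParameters>",
    '<listOfReactions><reaction id="J1" reversible="false">',
    '<listOfReactants><speciesReference species="S1" stoichiometry="1"',
    ' constant="true"/></listOfReactants><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><ci>alive</ci><ci>S1</ci></apply></math>",
    "</kineticLaw></reaction></listOfReactions>"))
  r <- scrub_nonfinite_parameters(read_sbml(b))
  expect_identical(r$log$location, "dead")
  par <- sbml_parameters(r$model)
  expect_identical(par$value[par$id == "dead"], 0)
  expect_true(is.infinite(par$value[par$id == "alive"]))
  expect_identical(r$issues$code, "nonfinite-used-parameter")

  # all-finite model: identity, empty log
  h <- read_sbml(chain3_bytes())
  r2 <- scrub_nonfinite_parameters(h)
  expect_identical(nrow(r2$log), 0L)
  expect_identical(nrow(r2$issues), 0L)
  expect_identical(as.character(r2$model$doc), as.character(h$doc))
})

test_that("invalid layout payloads are stripped, valid ones retained", {
  entry <- chain3_entry()
  de <- make_defective_entry(entry, "invalid-package-payload", 1)
  h <- read_sbml(de$payload[["biomodel.xml"]])
  r <- strip_invalid_package_payloads(h)
  expect_identical(nrow(r$log), 1L)
  # core model simulates identically after stripping
  e2 <- de
  e2$payload[["biomodel.xml"]] <- write_sbml(r$model)
  a <- execute(de, "reference-lsoda")
  b <- execute(e2, "reference-lsoda")
  expect_true(compare_resultsets(a, b)$passed)

  # a valid layout (with dimensions) is retained
  doc <- read_sbml(chain3_bytes())
  mn <- xml2::xml_find_first(doc$doc, "./*[local-name()='model']")
  good <- xml2::read_xml(paste0(
    '<layout:listOfLayouts xmlns:layout=',
    '"http://www.sbml.org/sbml/level3/version1/layout/version1">',
    '<layout:layout layout:id="l1">',
    '<layout:dimensions layout:width="100" layout:height="100"/>',
    "</layout:layout></layout:listOfLayouts>"))
  xml2::xml_add_child(mn, xml2::xml_root(good))
  r2 <- strip_invalid_package_payloads(doc)
  expect_identical(nrow(r2$log), 0L)
  expect_true(grepl("listOfLayouts", as.character(r2$model$doc)))
})

test_that("annotation URI checks are purely syntactic", {
  mk <- function(uri) read_sbml(sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"',
    ' metaid="c0"><annotation>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '<rdf:Description rdf:about="#c0"><bqbiol:is><rdf:Bag>',
    '<rdf:li rdf:resource="', uri, '"/>',
    "</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF>",
    "</annotation></compartment></listOfCompartments>")))
  expect_identical(nrow(check_annotation_uris(
    mk("https://identifiers.org/GO:0008152"))), 0L)
  expect_identical(check_annotation_uris(
    mk("https://identifiers.org/GOO:0008152"))$code, "unknown-prefix")
  expect_identical(check_annotation_uris(
    mk("https://identifiers.org/GO"))$code, "malformed-reference")
  expect_identical(check_annotation_uris(
    mk("https://identifiers.org/GO:81"))$code, "malformed-reference")
})

test_that("dynamic-variable listing follows rules and boundary conditions", {
  # 3 plain species are dynamic, a constant one is not
  b <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    "<listOfSpecies>",
    '<species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    '<species id="S2" compartment="c" initialAmount="0"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    '<species id="Sfixed" compartment="c" initialAmount="5"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false" constant="true"/>',
    '<species id="Sbound" compartment="c" initialAmount="2"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="true" constant="false"/>',
    "</listOfSpecies>",
    '<listOfParameters><parameter id="p" value="0" constant="false"/>',
    "</listOfParameters>",
    "<listOfRules>",
    '<rateRule variable="p">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>1</cn></math>',
    "</rateRule></listOfRules>"))
  vars <- list_dynamic_variables(read_sbml(b))
  expect_identical(vars, c("S1", "S2", "p"))

  # all-constant model -> empty
  bc <- sbml_snippet(paste0(
    '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="S1" compartment="c" initialAmount="1"',
    ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
    ' constant="true"/></listOfSpecies>'))
  expect_identical(list_dynamic_variables(read_sbml(bc)), character(0))
})
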