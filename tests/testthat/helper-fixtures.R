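# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

chain3_bytes <- function(local_params = FALSE) {
  make_chain_model(3, c(1, 0.5), c(1, 0, 0), local_params = local_params)
}

chain3_entry <- function() {
  h <- read_sbml(chain3_bytes())
  make_entry(chain3_bytes(), write_sedml(build_template(h, "biomodel.xml")))
}

multiscale_entry <- function(scales = c(0, -6, -12)) {
  mb <- make_multiscale_model(scales)
  h <- read_sbml(mb)
  make_entry(mb, write_sedml(build_template(h, "biomodel.xml")))
}

run_both_engines <- function(entry, settings = NULL) {
  list(
    "reference-lsoda" = execute(entry, "reference-lsoda", settings),
    "reference-bdf" = execute(entry, "reference-bdf", settings)
  )
}

# condition-code helper: the code is the first condition class
expect_vk_error <- function(expr, code) {
  expect_error(expr, class = code)
}

# a tiny SBML model written by hand, for features the chain generator does
# not produce (assignment rules, initial assignments, function definitions,
# boundary species, events, ...)
sbml_snippet <- function(body, level = "3", version = "2") {
  ns <- if (level == "3") {
    sprintf("http://www.sbml.org/sbml/level3/version%s/core", version)
  } else {
    sprintf("http://www.sbml.org/sbml/level%s/version%s", level, version)
  }
  charToRaw(paste0(
    '<sbml xmlns="', ns, '" level="', level, '" version="', version, '">',
    "<model id=\"m\">", body, "</model></sbml>"
  ))
}
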