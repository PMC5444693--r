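test_that("SBML round trip is structural identity for every fixture motif", {
  for (m in all_motifs()) {
    net <- make_fixture(m)$network
    p <- withr::local_tempfile(fileext = ".xml")
    write_sbml(net, p)
    expect_networks_equal(load_sbml(p), net)
  }
})

test_that("round trip preserves randomized (jittered) fixture kinetics", {
  for (s in 1:5) {
    net <- make_fixture("receptor_inhibitor", jitter = TRUE, seed = s)$network
    p <- withr::local_tempfile(fileext = ".xml")
    write_sbml(net, p)
    reloaded <- load_sbml(p)
    expect_networks_equal(reloaded, net)
    expect_silent(validate_network(reloaded))
  }
})

test_that("parsing is deterministic: two loads compare equal", {
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml(make_fixture("crosstalk_shared_phosphatase")$network, p)
  expect_networks_equal(load_sbml(p), load_sbml(p))
})

test_that("reaction referencing an undeclared species is an integrity error", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="bad"><listOfSpecies>',
    '<species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '</listOfSpecies><listOfParameters><parameter id="k" value="1" constant="true"/></listOfParameters>',
    '<listOfReactions><reaction id="r1" reversible="false" fast="false">',
    '<listOfReactants><speciesReference species="X" stoichiometry="1" constant="true"/></listOfReactants>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k</ci><ci>X</ci></apply></math></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), p)
  expect_error(load_sbml(p), "undeclared species.*X")
})

test_that("malformed XML raises a format error and events are unsupported", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", p)
  expect_error(load_sbml(p), "format error")
  expect_error(load_sbml(withr::local_tempfile()), "not found")

  q <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="ev"><listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>',
    '<listOfEvents><event id="e1"/></listOfEvents></model></sbml>'), q)
  expect_error(load_sbml(q), "unsupported.*listOfEvents")
})

test_that("piecewise math is rejected naming the construct", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="pw"><listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<piecewise><piece><cn>1</cn><apply><lt/><ci>A</ci><cn>2</cn></apply></piece></piecewise>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>'), p)
  expect_error(load_sbml(p), "unsupported.*piecewise")
})

test_that("L2 amounts convert to concentrations and local parameters are namespaced", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="l2"><listOfCompartments><compartment id="cell" size="2"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cell" initialAmount="10"/>',
    '<species id="B" compartment="cell" initialConcentration="3"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="r1">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>k</ci><ci>A</ci></apply></math>',
    '<listOfParameters><parameter id="k" value="0.25"/></listOfParameters>',
    '</kineticLaw></reaction></listOfReactions></model></sbml>'), p)
  net <- load_sbml(p)
  expect_equal(net$species$initial_concentration[net$species$id == "A"], 5)
  expect_equal(net$species$initial_concentration[net$species$id == "B"], 3)
  expect_named(net$parameters, "r1__k")
  expect_equal(unname(net$parameters), 0.25)
  expect_equal(deparse(net$reactions[[1]]$kinetic_law), "r1__k * A")
  # L2 default reversible is true
  expect_true(net$reactions[[1]]$reversible)
})

test_that("write_sbml refuses a network violating referential integrity", {
  net <- make_fixture("decay")$network
  net$reactions[[1]]$reactants <- c(ghost = 1)
  expect_error(write_sbml(net, withr::local_tempfile(fileext = ".xml")),
               "undeclared species")
})

test_that("drug catalogue parses, binds and validates", {
  net <- reaction_network(
    rbind(species("drug_2C4"), species("HER2", initial_concentration = 10)),
    list(reaction("r1", c(drug_2C4 = 1, HER2 = 1), numeric(),
                  kinetic_law = quote(k * drug_2C4 * HER2))),
    c(k = 0.1))
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,dosage_nM,target_species",
               "pertuzumab,30,drug_2C4"), p)
  ctl <- load_drug_catalogue(p, net)
  expect_s3_class(ctl, "drug_catalogue")
  expect_equal(nrow(ctl), 1L)
  expect_equal(ctl$dosage_nM, 30)
  expect_equal(ctl$target, "drug_2C4")

  # headerless tab-separated variant parses identically
  q <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pertuzumab\t30\tdrug_2C4", q)
  expect_equal(load_drug_catalogue(q, net)$dosage_nM, 30)

  # empty file -> empty catalogue
  e <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), e)
  expect_equal(nrow(load_drug_catalogue(e, net)), 0L)

  # missing target species and negative dosage are rejected
  b <- withr::local_tempfile(fileext = ".csv")
  writeLines("drugX,10,nosuch", b)
  expect_error(load_drug_catalogue(b, net), "absent")
  writeLines("drugX,-5,drug_2C4", b)
  expect_error(load_drug_catalogue(b, net), "non-negative")
})
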