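# Model container, validation, GPR rules and model I/O.

test_that("exchange reactions are auto-detected as single-metabolite reactions", {
  m <- tiny_chain_model()
  expect_setequal(m$exchanges, c("EX_a", "EX_bm"))
  m6 <- fx$model
  expect_true(all(startsWith(sort(m6$exchanges), "EX_")))
  expect_length(grep("^EX_(glu|ser|asn|asp|ala|leu)$", m6$exchanges), 6L)
})

test_that("validation errors name the offending element", {
  expect_error(
    metabolic_model(list(reaction("R1", c(a_c = -1, b_c = 1), lb = 2, ub = 1),
                         reaction("BIO", c(b_c = -1))),
                    biomass = "BIO"),
    "R1.*lower bound"
  )
  expect_error(
    metabolic_model(list(reaction("BIO", c(a_c = 1))), biomass = "BIO"),
    "no substrate"
  )
  expect_error(
    metabolic_model(list(reaction("R1", c(a_c = -1)),
                         reaction("BIO", c(a_c = -1))),
                    biomass = "nope"),
    "not found"
  )
  expect_error(
    metabolic_model(list(reaction("R1", c(a_c = -1), gpr = "gA and or gB"),
                         reaction("BIO", c(a_c = -1))),
                    biomass = "BIO"),
    "invalid GPR"
  )
})

test_that("GPR parsing extracts genes with and/or precedence and parentheses", {
  expect_setequal(gpr_genes("gA and gB"), c("gA", "gB"))
  expect_setequal(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_setequal(gpr_genes("g1 or g2 and g3"), c("g1", "g2", "g3"))
  expect_equal(gpr_genes(""), character(0))
  expect_equal(gpr_genes("  "), character(0))
  expect_error(gpr_genes("(gA and"), "unexpected end|unbalanced")
  expect_error(gpr_genes("gA gB"), "trailing token")
})

test_that("genes_for_reactions returns the deduplicated union and rejects unknown ids", {
  m <- metabolic_model(
    list(reaction("R1", c(a_c = -1, b_c = 1), gpr = "gA and gB"),
         reaction("R2", c(b_c = -1, c_c = 1), gpr = "gA or gC"),
         reaction("R3", c(c_c = -1, d_c = 1), gpr = ""),
         reaction("BIO", c(d_c = -1))),
    biomass = "BIO"
  )
  expect_setequal(genes_for_reactions(m, c("R1")), c("gA", "gB"))
  expect_setequal(genes_for_reactions(m, c("R1", "R2")), c("gA", "gB", "gC"))
  expect_equal(sum(genes_for_reactions(m, c("R1", "R2")) == "gA"), 1L)
  expect_equal(genes_for_reactions(m, character(0)), character(0))
  expect_equal(genes_for_reactions(m, "R3"), character(0))
  expect_error(genes_for_reactions(m, "R99"), "unknown reaction")
})

test_that("JSON and SBML round-trips preserve stoichiometry, bounds, GPRs and subsystems", {
  m <- make_toy_model(4, seed = 3)
  for (dialect in c("tabular_json", "sbml")) {
    f <- tempfile(fileext = if (dialect == "sbml") ".xml" else ".json")
    write_model(m, f, dialect = dialect)
    m2 <- read_model(f, dialect = dialect)
    expect_identical(names(m2$reactions), names(m$reactions))
    expect_identical(m2$biomass, m$biomass)
    for (r in names(m$reactions)) {
      a <- m$reactions[[r]]
      b <- m2$reactions[[r]]
      expect_identical(sort(names(a$stoich)), sort(names(b$stoich)))
      expect_equal(unname(a$stoich[names(b$stoich)]), unname(b$stoich))
      expect_equal(a$lb, b$lb)
      expect_equal(a$ub, b$ub)
      expect_identical(a$subsystem, b$subsystem)
      expect_setequal(gpr_genes(a$gpr), gpr_genes(b$gpr))
    }
  }
})

test_that("a legacy SBML reversible flag is honoured when fbc bounds are absent", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="legacy"><listOfSpecies>',
    '<species id="M_a_c" compartment="c"/>',
    '<species id="M_b_c" compartment="c"/>',
    "</listOfSpecies><listOfReactions>",
    '<reaction id="R_conv" reversible="true">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="1"/></listOfProducts>',
    "</reaction>",
    '<reaction id="R_biomass" reversible="false">',
    '<listOfReactants><speciesReference species="M_b_c" stoichiometry="1"/></listOfReactants>',
    "</reaction>",
    "</listOfReactions></model></sbml>"
  ), f)
  m <- read_model(f, dialect = "sbml") # the R_ prefix convention is stripped
  expect_equal(m$reactions$conv$lb, -1000)
  expect_equal(m$reactions$conv$ub, 1000)
  expect_equal(m$reactions$biomass$lb, 0)
  expect_identical(m$biomass, "biomass")
})

test_that("malformed model files raise parse errors naming the problem", {
  f <- tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(read_model(f), "malformed")
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(reactions = list()), f2, auto_unbox = TRUE)
  expect_error(read_model(f2), "biomass")
  expect_error(read_model(tempfile()), "not found")
})

test_that("flipping a reaction's direction leaves the FBA optimum unchanged", {
  m <- fx$model
  flipped <- m$reactions
  for (rid in c("DEG_glu", "TCA_IDH", "EX_ser")) {
    r <- flipped[[rid]]
    flipped[[rid]] <- reaction(r$id, -r$stoich, lb = -r$ub, ub = -r$lb,
                               gpr = r$gpr, subsystem = r$subsystem)
  }
  m_flip <- metabolic_model(flipped, biomass = m$biomass, id = m$id)
  f1 <- run_phase_fba(m, fx$pp)
  f2 <- run_phase_fba(m_flip, fx$pp)
  expect_equal(attr(f1, "mu"), attr(f2, "mu"), tolerance = 1e-7)
})
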