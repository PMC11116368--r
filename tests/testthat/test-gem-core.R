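test_that("model construction enforces structural invariants", {
  expect_error(
    gem_model("bad", metabolites = metabolite("A@c"),
              reactions = list(reaction("R1", c("A@c" = -1, "Z@c" = 1)))),
    "undeclared metabolite")
  expect_error(reaction("R", c("A@c" = 1), lb = 5, ub = 1),
               "lower bound exceeds upper")
  expect_error(
    gem_model("bad2", metabolites = rbind(metabolite("A@c"), metabolite("B@c")),
              reactions = list(reaction("EX_x", c("A@c" = -1, "B@c" = 1),
                                        kind = "exchange"))),
    "exactly one metabolite")
  # zero coefficients are pruned at construction
  r <- reaction("R", c("A@c" = -1, "B@c" = 0, "C@c" = 1))
  expect_named(r$stoich, c("A@c", "C@c"))
})

test_that("GPR rules parse, compare, and combine correctly", {
  tree <- gpr_parse("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_true(gpr_equivalent("g1 and g2", "g2 and g1"))
  expect_true(gpr_equivalent("(g1 or g2) and g3", "(g3 and g1) or (g3 and g2)"))
  expect_false(gpr_equivalent("g1 and g2", "g1 or g2"))
  expect_null(gpr_parse(""))
  expect_error(gpr_parse("g1 and (g2"), "parse error")
  expect_error(gpr_parse("g1 g2"), "parse error")
  # OR-combination is absorbing for empty rules and idempotent
  expect_equal(gpr_or("", "g1"), "g1")
  expect_equal(gpr_or("g1 and g2", "g1 and g2"), "g1 and g2")
  expect_true(gpr_equivalent(gpr_or("g1", "g2 and g3"), "g1 or (g2 and g3)"))
})

test_that("reaction kind inference follows id-prefix and structure rules", {
  m <- chain_model(with_biomass = TRUE)
  kinds <- vapply(m$reactions, `[[`, character(1), "kind")
  expect_equal(unname(kinds[c("EX_A@e", "T_A", "R1", "bio")]),
               c("exchange", "transport", "internal", "biomass"))
})

test_that("dead-end detection matches producer/consumer analysis", {
  m <- chain_model()
  expect_equal(find_dead_end_metabolites(m), "C@c")
  # fully reversible isolated pair: each side can be produced and consumed
  # through the two directions, so neither is a dead end
  iso <- gem_model("iso", metabolites = rbind(metabolite("A@c"), metabolite("B@c")),
                   reactions = list(reaction("R", c("A@c" = -1, "B@c" = 1),
                                             lb = -1000, ub = 1000)))
  expect_equal(find_dead_end_metabolites(iso), character())
  # the same pair irreversible: A has no producer, B no consumer
  iso$reactions$R$lb <- 0
  expect_equal(find_dead_end_metabolites(iso), c("A@c", "B@c"))
  empty <- gem_model("empty")
  expect_equal(find_dead_end_metabolites(empty), character())
})

test_that("adding reactions never creates dead ends among existing metabolites", {
  for (seed in 1:5) {
    tn <- generate_truth_network(3, 2, seed = seed)
    m <- tn$model
    m$reactions[["Rb1_1"]] <- NULL   # knock a hole in a branch
    before <- find_dead_end_metabolites(m)
    m2 <- set_reaction(m, tn$model$reactions[["Rb1_1"]])
    after <- find_dead_end_metabolites(m2)
    expect_true(all(intersect(after, m$metabolites$id) %in% before))
  }
})

test_that("mass and charge balance verdicts are exact", {
  mets <- rbind(metabolite("h2o@c", formula = "H2O", charge = 0L),
                metabolite("h2@c", formula = "H2", charge = 0L),
                metabolite("o2@c", formula = "O2", charge = 0L),
                metabolite("ch4@c", formula = "CH4", charge = 0L),
                metabolite("ch3@c", formula = "CH3", charge = -1L),
                metabolite("blank@c", formula = ""))
  r1 <- reaction("split", c("h2o@c" = -2, "h2@c" = 2, "o2@c" = 1), kind = "internal")
  b1 <- check_mass_charge_balance(r1, mets)
  expect_equal(b1$verdict, "balanced")
  r2 <- reaction("demeth", c("ch4@c" = -1, "ch3@c" = 1), kind = "internal")
  b2 <- check_mass_charge_balance(r2, mets)
  expect_equal(b2$verdict, "unbalanced")
  expect_equal(unname(b2$element_imbalance["H"]), -1)
  expect_equal(b2$charge_imbalance, -1)
  r3 <- reaction("mystery", c("blank@c" = -1, "h2@c" = 1), kind = "internal")
  expect_equal(check_mass_charge_balance(r3, mets)$verdict, "undetermined")
  r4 <- reaction("EX_h2o@c", c("h2o@c" = -1), kind = "exchange")
  expect_equal(check_mass_charge_balance(r4, mets)$verdict, "exempt")
})

test_that("balance checker agrees with independent element arithmetic", {
  elements <- c("C", "H", "N", "O")
  set.seed(11)
  for (i in 1:10) {
    counts <- matrix(sample(0:4, 3 * length(elements), replace = TRUE), nrow = 3)
    formulas <- apply(counts, 1, function(cc)
      paste0(elements[cc > 0], ifelse(cc[cc > 0] > 1, cc[cc > 0], ""), collapse = ""))
    formulas[formulas == ""] <- "C1"
    counts[rowSums(counts) == 0, 1] <- 1
    mets <- do.call(rbind, lapply(1:3, function(j)
      metabolite(paste0("x", j, "@c"), formula = formulas[j], charge = 0L)))
    coefs <- sample(c(-3:-1, 1:3), 3, replace = TRUE)
    rxn <- reaction("R", setNames(coefs, paste0("x", 1:3, "@c")), kind = "internal")
    rep <- check_mass_charge_balance(rxn, mets)
    expected <- as.numeric(t(counts) %*% coefs)   # independent: matrix arithmetic
    names(expected) <- elements
    expected <- expected[expected != 0]
    got <- rep$element_imbalance[order(names(rep$element_imbalance))]
    expect_equal(got, expected[order(names(expected))],
                 tolerance = 1e-9, ignore_attr = FALSE)
    expect_equal(rep$verdict, if (length(expected)) "unbalanced" else "balanced")
  }
})

test_that("formula parser handles counts and parenthesized groups", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("Ca(OH)2"), c(Ca = 1, O = 2, H = 2))
  expect_null(parse_formula(""))
  expect_null(parse_formula("???"))
})

test_that("model statistics count the documented quantities", {
  m <- chain_model()
  s <- model_stats(m)
  expect_equal(s$n_metabolites, 4)
  expect_equal(s$n_reactions, 4)
  expect_equal(s$n_dead_ends, 1)
  # 3 GPR-eligible reactions (transport + 2 internal), all with GPR
  expect_equal(s$frac_reactions_without_gpr, 0)
  m$reactions$R1$gpr <- ""
  expect_equal(model_stats(m)$frac_reactions_without_gpr, 1 / 3)
  e <- model_stats(gem_model("empty"))
  expect_equal(unlist(e), c(n_reactions = 0, n_metabolites = 0, n_genes = 0,
                            n_dead_ends = 0, frac_reactions_without_gpr = 0))
})

test_that("SBML and TSV round-trips preserve the structural digest", {
  models <- list(chain_model(with_biomass = TRUE),
                 generate_truth_network(2, 2, seed = 3)$model,
                 gem_model("empty"))
  for (m in models) {
    sb <- tempfile(fileext = ".sbml")
    write_model(m, sb, dialect = "sbml-fbc")
    back <- read_model(sb, dialect = "sbml-fbc")
    expect_identical(model_digest(back), model_digest(m))
    expect_identical(back$objective, m$objective)
    td <- tempfile()
    write_model(m, td, dialect = "tsv-triplet")
    back2 <- read_model(td, dialect = "tsv-triplet")
    expect_identical(model_digest(back2), model_digest(m))
    unlink(sb); unlink(td, recursive = TRUE)
  }
})

test_that("SBML round-trip preserves GPR semantics, EC numbers and attributes", {
  m <- generate_truth_network(3, 2, seed = 9)$model
  sb <- tempfile(fileext = ".sbml")
  write_model(m, sb)
  back <- read_model(sb)
  for (id in reaction_ids(m)) {
    expect_true(gpr_equivalent(m$reactions[[id]]$gpr, back$reactions[[id]]$gpr))
    expect_equal(sort(back$reactions[[id]]$ec), sort(m$reactions[[id]]$ec))
    expect_equal(back$reactions[[id]]$kind, m$reactions[[id]]$kind)
  }
  expect_equal(back$metabolites[order(back$metabolites$id), ]$formula,
               m$metabolites[order(m$metabolites$id), ]$formula)
  expect_equal(back$genes, m$genes)
  # empty GPRs emit no gene association elements
  m2 <- chain_model()
  m2$reactions$R1$gpr <- ""
  write_model(m2, sb)
  expect_false(any(grepl("geneProductAssociation",
                         grep("R1", readLines(sb), value = TRUE))))
  unlink(sb)
})

test_that("reading malformed input gives structured errors", {
  f <- tempfile(fileext = ".sbml")
  writeLines("this is not xml <", f)
  expect_error(read_model(f), "parse failure")
  expect_error(read_model(tempfile(fileext = ".sbml")), "no such file")
  unlink(f)
})
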