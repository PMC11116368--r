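test_that("universal biomass insertion replaces and extends as specified", {
  m <- chain_model()
  spec <- c("B@c" = -1, "atp@c" = -0.5)
  m2 <- add_universal_biomass(m, spec)
  expect_equal(m2$objective, "bio_universal")
  expect_true("atp@c" %in% m2$metabolites$id)
  # a pre-existing biomass reaction is replaced, with a message
  m3 <- chain_model(with_biomass = TRUE)
  expect_message(m4 <- add_universal_biomass(m3, spec), "replaced")
  kinds <- vapply(m4$reactions, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "biomass"), 1L)
  expect_error(add_universal_biomass(m, numeric()), "empty")
})

test_that("gap-filling finds the unique feasible singleton", {
  inst <- random_gapfill_instance(101)
  # drop exactly one known reaction for a controlled singleton case
  m <- chain_model()
  m <- add_universal_biomass(m, c("B@c" = -1))
  m$reactions[["R1"]] <- NULL
  db <- gem_model("db", metabolites = rbind(m$metabolites, metabolite("Z1@c"),
                                            metabolite("Z2@c")),
                  reactions = list(
                    reaction("R1", c("A@c" = -1, "B@c" = 1), lb = 0),
                    reaction("junk", c("Z1@c" = -1, "Z2@c" = 1), lb = 0)))
  res <- gapfill_model(m, db, medium(c("A@e" = 10)))
  expect_equal(res$added_reactions, "R1")
  expect_gte(res$growth, 0.05)
  expect_equal(res$model$reactions[["R1"]]$gpr, "")
})

test_that("gap-filling prefers the shorter of two alternative routes", {
  cf <- crossfeeding_fixture(3)
  dep <- cf$community$members$dependent
  # no alanine in the medium: must synthesize via the 3-step database route
  res <- gapfill_model(dep, cf$universal_db, cf$media$rich)
  expect_setequal(res$added_reactions, c("Raltala1", "Raltala2", "Raltala3"))
  # independent check: exhaustive enumeration over all candidate subsets
  expect_equal(length(res$added_reactions),
               brute_gapfill_min_weight(dep, cf$universal_db, cf$media$rich))
})

test_that("MILP solutions match exhaustive enumeration on random instances", {
  for (seed in 1:10) {
    inst <- random_gapfill_instance(seed)
    m <- inst$model
    oracle <- brute_gapfill_min_weight(m, inst$db, inst$medium)
    res <- gapfill_model(m, inst$db, inst$medium)
    expect_equal(sum(rep(1, length(res$added_reactions))), oracle,
                 info = paste("seed", seed))
  }
})

test_that("equal-weight ties break to the lexicographically smallest id set", {
  # two parallel single-reaction routes, identical weight
  mets <- rbind(metabolite("S@e"), metabolite("S@c"), metabolite("P@c"))
  m <- gem_model("tie", metabolites = mets, reactions = list(
    reaction("EX_S@e", c("S@e" = -1), lb = -10, kind = "exchange"),
    reaction("T_S", c("S@e" = -1, "S@c" = 1), lb = 0),
    reaction("bio", c("P@c" = -1), lb = 0, kind = "biomass")),
    objective = "bio")
  db <- gem_model("db", metabolites = mets, reactions = list(
    reaction("zzz_route", c("S@c" = -1, "P@c" = 1), lb = 0),
    reaction("aaa_route", c("S@c" = -1.5, "P@c" = 1.5), lb = 0)))
  res <- gapfill_model(m, db, medium(c("S@e" = 10)))
  expect_equal(res$added_reactions, "aaa_route")
})

test_that("infeasible gap-filling names the blocked biomass precursors", {
  m <- chain_model()
  m <- add_universal_biomass(m, c("B@c" = -1, "unobtainium@c" = -1))
  db <- gem_model("db", metabolites = m$metabolites, reactions = list())
  err <- tryCatch(gapfill_model(m, db, medium(c("A@e" = 10))),
                  commgem_gapfill_infeasible = function(e) e)
  expect_s3_class(err, "commgem_gapfill_infeasible")
  expect_true("unobtainium@c" %in% err$blocked_precursors)
  expect_false("B@c" %in% err$blocked_precursors)
})

test_that("permeable metabolite prediction respects coupling and the threshold", {
  # biomass obligatorily co-produces D@e: D is permeable
  mets <- rbind(metabolite("S@e"), metabolite("S@c"), metabolite("D@e"),
                metabolite("U@e"))
  m <- gem_model("perm", metabolites = mets, reactions = list(
    reaction("EX_S@e", c("S@e" = -1), lb = -5, kind = "exchange"),
    reaction("T_S", c("S@e" = -1, "S@c" = 1), lb = 0),
    reaction("bio", c("S@c" = -1, "D@e" = 0.5), lb = 0, kind = "biomass"),
    reaction("SK_D@e", c("D@e" = -1), lb = 0, kind = "sink")),
    objective = "bio")
  perm <- predict_permeable_metabolites(m, medium(c("S@e" = 5)))
  expect_true("D@e" %in% perm)
  # U@e has no path from any substrate: not permeable
  expect_false("U@e" %in% perm)
  # threshold above the attainable secretion excludes the metabolite:
  # max D secretion is 0.5 * 5 = 2.5 by the uptake bottleneck
  perm2 <- predict_permeable_metabolites(m, medium(c("S@e" = 5)), tol = 2.6)
  expect_false("D@e" %in% perm2)
  perm3 <- predict_permeable_metabolites(m, medium(c("S@e" = 5)), tol = 2.4)
  expect_true("D@e" %in% perm3)
  # a non-growing model is an error
  m$reactions$EX_S <- NULL
  m2 <- m; m2$reactions[["EX_S@e"]]$lb <- 0
  expect_error(predict_permeable_metabolites(m2, NULL), "does not reach")
})

test_that("iterative gap-filling routes metabolites between members by order", {
  cf <- crossfeeding_fixture(1)
  res_d <- iterative_community_gapfill(cf$community, cf$media$rich,
                                       cf$media$minimal, cf$universal_db)
  # descending: the donor feeds alanine into the pool; the dependent member
  # needs only an uptake reaction
  expect_equal(res_d$results$dependent$added_reactions, "EX_ala@e")
  expect_equal(length(res_d$results$donor$added_reactions), 0)
  # ascending: the dependent member goes first and must synthesize
  comm_a <- cf$community; comm_a$order <- "ascending"
  res_a <- iterative_community_gapfill(comm_a, cf$media$rich,
                                       cf$media$minimal, cf$universal_db)
  expect_equal(sort(res_a$results$dependent$added_reactions),
               c("Raltala1", "Raltala2", "Raltala3"))
  expect_gt(length(res_a$results$dependent$added_reactions),
            length(res_d$results$dependent$added_reactions))
  # every added reaction lacks genetic support
  for (r in res_d$results)
    for (id in r$added_reactions)
      expect_equal(r$model$reactions[[id]]$gpr, "")
  # medium monotonicity: the final medium contains the base medium
  expect_true(all(names(cf$media$minimal$uptake) %in%
                    names(res_d$final_medium$uptake)))
  # the routed metabolite shows up as community-exchanged
  exch <- community_exchanged(lapply(res_d$results, `[[`, "model"))
  expect_true("ala@e" %in% exch)
})

test_that("a single-member community reduces to plain gap-filling", {
  cf <- crossfeeding_fixture(2)
  donor <- cf$community$members$donor
  solo <- community(list(donor = donor), c(donor = 1), order = "descending")
  res <- iterative_community_gapfill(solo, cf$media$rich, cf$media$minimal,
                                     cf$universal_db)
  direct <- gapfill_model(donor, cf$universal_db, cf$media$rich)
  expect_equal(res$results$donor$added_reactions, direct$added_reactions)
})

test_that("abundance correlation matches the closed-form Pearson formula", {
  mk <- function(mag, n_added) structure(
    list(mag_id = mag, added_reactions = paste0("r", seq_len(n_added)),
         imported = character(), exported = character(), growth = 1,
         status = "ok"), class = "gapfill_result")
  counts <- c(2, 5, 4, 8, 11)
  ab <- c(m1 = 1, m2 = 3, m3 = 4, m4 = 7, m5 = 10)
  results <- setNames(lapply(seq_along(counts),
                             function(i) mk(names(ab)[i], counts[i])), names(ab))
  out <- correlate_abundance_with_gapfill(results, ab, "added")
  # independent arithmetic: covariance over product of standard deviations
  x <- unname(ab); y <- counts
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  # exact proportionality gives r = 1
  results2 <- setNames(lapply(seq_along(ab),
                              function(i) mk(names(ab)[i], 2 * unname(ab)[i])),
                       names(ab))
  expect_equal(correlate_abundance_with_gapfill(results2, ab, "added")$r, 1,
               tolerance = 1e-9)
  # constant counts: undefined correlation
  results3 <- setNames(lapply(names(ab), function(m) mk(m, 3)), names(ab))
  expect_error(correlate_abundance_with_gapfill(results3, ab, "added"),
               "zero variance")
})
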