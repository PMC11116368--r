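test_that("truth networks are deterministic, growth-capable and dead-end free", {
  a <- generate_truth_network(2, 3, seed = 7)
  b <- generate_truth_network(2, 3, seed = 7)
  expect_identical(model_digest(a$model), model_digest(b$model))
  f1 <- tempfile(fileext = ".sbml"); f2 <- tempfile(fileext = ".sbml")
  write_model(a$model, f1); write_model(b$model, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical files
  unlink(c(f1, f2))
  expect_gt(fba(a$model, a$media$rich)$objective, 0)
  expect_gt(fba(a$model, a$media$minimal)$objective, 0)
  expect_length(find_dead_end_metabolites(a$model), 0)
  expect_error(generate_truth_network(0, 2), ">= 1")
})

test_that("every generated member is gap-fillable with the universal database", {
  for (seed in c(1, 5, 9)) {
    fx <- generate_community(n_members = 2, seed = seed)
    for (mag in names(fx$members)) {
      truth <- fx$members[[mag]]$truth
      res <- gapfill_model(truth, fx$universal_db, fx$media$rich)
      expect_gte(res$growth, 0.05)
    }
  }
})

test_that("a no-degradation profile gives a view identical up to renaming", {
  tn <- generate_truth_network(3, 2, seed = 11)
  clean <- tool_profile("clean", "cl")
  v <- derive_tool_view(tn$model, clean, seed = 1)
  map <- load_reference_tables(
    { f <- tempfile(); write.table(v$met_table, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE); f },
    { f <- tempfile(); write.table(v$rxn_table, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE); f })
  back <- translate_model(v$model, map)$model
  expect_equal(jaccard(reaction_ids(back), reaction_ids(tn$model)), 1)
  expect_equal(jaccard(back$metabolites$id, tn$model$metabolites$id), 1)
})

test_that("full dropout of non-core reactions leaves only the protected core", {
  tn <- generate_truth_network(3, 2, seed = 11)
  allgone <- tool_profile("bare", "br", reaction_dropout_prob = 1)
  v <- derive_tool_view(tn$model, allgone, seed = 1)
  core <- attr(tn$model, "core_ids")
  kinds <- vapply(v$model$reactions, `[[`, character(1), "kind")
  n_core_like <- sum(!(kinds %in% c("exchange", "sink", "biomass")))
  expect_equal(n_core_like,
               sum(!(vapply(tn$model$reactions[core], `[[`, character(1), "kind")
                     %in% c("exchange", "sink", "biomass"))))
})

test_that("dead-end appendages raise the dead-end count by at least their number", {
  tn <- generate_truth_network(2, 2, seed = 3)
  base_profile <- tool_profile("plain", "pl")
  dx_profile <- tool_profile("dx", "dx", extra_deadend_reactions = 3L)
  v0 <- derive_tool_view(tn$model, base_profile, seed = 5)
  v3 <- derive_tool_view(tn$model, dx_profile, seed = 5)
  expect_gte(length(find_dead_end_metabolites(v3$model)),
             length(find_dead_end_metabolites(v0$model)) + 3)
})

test_that("community fixtures are reproducible with positive finite abundances", {
  f1 <- generate_community(n_members = 4, seed = 21)
  f2 <- generate_community(n_members = 4, seed = 21)
  expect_identical(f1$abundance, f2$abundance)
  expect_true(all(is.finite(f1$abundance) & f1$abundance > 0))
  expect_identical(model_digest(f1$members$mag03$views$gapseq),
                   model_digest(f2$members$mag03$views$gapseq))
  # different seed, different content
  f3 <- generate_community(n_members = 4, seed = 22)
  expect_false(identical(f1$abundance, f3$abundance))
})

test_that("tool profiles reproduce the qualitative structural signatures", {
  # aggregated over seeds: gapseq-like views have the most reactions and
  # dead ends, carveme-like views the most genes
  n_rxn <- n_dead <- n_gene <- matrix(0, 20, 3,
                                      dimnames = list(NULL, c("carveme", "gapseq", "kbase")))
  pf <- tool_profiles()
  for (s in 1:20) {
    tn <- generate_truth_network(3, 2, seed = 300 + s)
    for (tool in colnames(n_rxn)) {
      v <- derive_tool_view(tn$model, pf[[tool]], seed = 600 + s)$model
      st <- model_stats(v)
      n_rxn[s, tool] <- st$n_reactions
      n_dead[s, tool] <- st$n_dead_ends
      n_gene[s, tool] <- st$n_genes
    }
  }
  means <- function(M) colMeans(M)
  expect_gt(means(n_rxn)["gapseq"], means(n_rxn)["kbase"])
  expect_gt(means(n_dead)["gapseq"], means(n_dead)["kbase"])
  expect_gt(means(n_dead)["gapseq"], means(n_dead)["carveme"])
  expect_equal(names(which.max(means(n_gene))), "carveme")
})

test_that("complementary dropout makes the consensus strictly richer in connectivity", {
  wins <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    tr <- make_translated_triple(700 + s, complementary = TRUE)
    cons <- merge_models(tr$views)$model
    nd_cons <- length(find_dead_end_metabolites(cons))
    nd_views <- vapply(tr$views, function(v)
      length(find_dead_end_metabolites(v)), numeric(1))
    if (all(nd_cons < nd_views)) wins <- wins + 1
  }
  expect_gte(wins / n_seeds, 0.9)
})
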