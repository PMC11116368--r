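test_that("stripping removes exactly the boundary and biomass reactions", {
  m <- chain_model(with_biomass = TRUE)
  m$reactions[["SK_C@c"]] <- reaction("SK_C@c", c("C@c" = -1), lb = 0, kind = "sink")
  s <- strip_boundary_and_biomass(m)
  expect_setequal(reaction_ids(s), c("T_A", "R1", "R2"))
  expect_true(is.na(s$objective))
  expect_identical(model_digest(strip_boundary_and_biomass(s)), model_digest(s))
  e <- gem_model("empty")
  expect_length(strip_boundary_and_biomass(e)$reactions, 0)
})

test_that("reaction equivalence classifies composition, reversal, and scaling", {
  rA <- reaction("x1", c("A@c" = -1, "B@c" = -1, "C@c" = 1), lb = 0)
  rB <- reaction("x2", c("A@c" = -1, "B@c" = -1, "C@c" = 1), lb = 0)
  expect_equal(reactions_equivalent(rA, rB), "duplicate")
  rC <- reaction("x3", c("A@c" = 1, "B@c" = 1, "C@c" = -1), lb = 0)
  expect_equal(reactions_equivalent(rA, rC), "duplicate_reversed")
  rD <- reaction("x4", c("A@c" = -1, "D@c" = 1), lb = 0)
  expect_equal(reactions_equivalent(rA, rD), "distinct")
  # scalar multiples are the same conversion
  rE <- reaction("x5", c("A@c" = -2, "B@c" = -2, "C@c" = 2), lb = 0)
  expect_equal(reactions_equivalent(rA, rE), "duplicate")
  # same id always wins
  rF <- reaction("x1", c("Z@c" = -1, "Q@c" = 1), lb = 0)
  expect_equal(reactions_equivalent(rA, rF), "duplicate")
})

test_that("merging a model with itself is the identity on the digest", {
  tr <- make_translated_triple(5)
  v <- tr$views[[1]]
  merged <- merge_models(list(v, v))$model
  expect_identical(merged$genes, v$genes)
  expect_identical(sort(reaction_ids(merged)), sort(reaction_ids(v)))
  expect_identical(model_digest(merged)$reactions, model_digest(v)$reactions)
})

test_that("merging disjoint views sums reactions; duplicates widen bounds and OR GPRs", {
  mets1 <- rbind(metabolite("A@c"), metabolite("B@c"))
  v1 <- gem_model("m", tool = "carveme", metabolites = mets1,
                  reactions = list(reaction("R1", c("A@c" = -1, "B@c" = 1),
                                            lb = 0, gpr = "g1",
                                            source_tools = "carveme")))
  mets2 <- rbind(metabolite("C@c"), metabolite("D@c"))
  v2 <- gem_model("m", tool = "gapseq", metabolites = mets2,
                  reactions = list(reaction("R2", c("C@c" = -1, "D@c" = 1),
                                            lb = 0, gpr = "g2",
                                            source_tools = "gapseq")))
  disjoint <- merge_models(list(v1, v2))$model
  expect_equal(length(disjoint$reactions), 2)
  expect_setequal(disjoint$genes, c("g1", "g2"))

  # same conversion: irreversible + reversible -> reversible, GPR ORed
  v3 <- gem_model("m", tool = "gapseq", metabolites = mets1,
                  reactions = list(reaction("Rx", c("A@c" = -1, "B@c" = 1),
                                            lb = -1000, ub = 1000, gpr = "g2",
                                            source_tools = "gapseq")))
  mm <- merge_models(list(v1, v3))
  expect_equal(length(mm$model$reactions), 1)
  kept <- mm$model$reactions[["R1"]]
  expect_equal(kept$lb, -1000)
  expect_equal(kept$ub, 1000)
  expect_true(gpr_equivalent(kept$gpr, "g1 or g2"))
  expect_setequal(kept$source_tools, c("carveme", "gapseq"))
  expect_equal(mm$report$per_view$merged, c(0, 1))
})

test_that("reversed duplicates are merged after negation", {
  mets <- rbind(metabolite("A@c"), metabolite("B@c"))
  fwd <- gem_model("m", tool = "carveme", metabolites = mets,
                   reactions = list(reaction("F", c("A@c" = -1, "B@c" = 1),
                                             lb = 0, gpr = "g1")))
  bwd <- gem_model("m", tool = "kbase", metabolites = mets,
                   reactions = list(reaction("Bk", c("A@c" = 1, "B@c" = -1),
                                             lb = 0, gpr = "g2")))
  merged <- merge_models(list(fwd, bwd))$model
  expect_equal(length(merged$reactions), 1)
  kept <- merged$reactions[["F"]]
  # the backward-only partner contributes the reverse direction
  expect_equal(kept$lb, -1000)
  expect_equal(kept$ub, 1000)
})

test_that("merge keeps the balanced variant's formula annotations", {
  mets_bad <- rbind(metabolite("A@c", formula = "C2H4"),
                    metabolite("B@c", formula = "C2H3"))   # unbalanced as annotated
  mets_good <- rbind(metabolite("A@c", formula = "C2H4"),
                     metabolite("B@c", formula = "C2H4"))
  v1 <- gem_model("m", tool = "carveme", metabolites = mets_bad,
                  reactions = list(reaction("R", c("A@c" = -1, "B@c" = 1), lb = 0)))
  v2 <- gem_model("m", tool = "gapseq", metabolites = mets_good,
                  reactions = list(reaction("R2", c("A@c" = -1, "B@c" = 1), lb = 0)))
  mm <- merge_models(list(v1, v2))
  f <- mm$model$metabolites$formula[mm$model$metabolites$id == "B@c"]
  expect_equal(f, "C2H4")
  expect_true(any(grepl("balanced", mm$report$conflicts)))
})

test_that("merge content is order-insensitive at the stoichiometry-digest level", {
  for (seed in c(2, 9)) {
    tr <- make_translated_triple(seed)
    d1 <- model_digest(merge_models(tr$views)$model)
    d2 <- model_digest(merge_models(rev(tr$views))$model)
    expect_identical(d1$reactions, d2$reactions)
    expect_identical(d1$genes, d2$genes)
    expect_identical(d1$metabolites, d2$metabolites)
  }
})

test_that("consensus audit passes on generated triples and detects violations", {
  tr <- make_translated_triple(4)
  mm <- merge_models(tr$views)
  aud <- consensus_dead_end_audit(tr$views, mm$model)
  expect_true(aud$ok)
  # hand-built: view1's dead-end C is consumed in view2, so the consensus
  # resolves it
  mets <- rbind(metabolite("A@c"), metabolite("C@c"), metabolite("D@c"))
  v1 <- gem_model("m", tool = "carveme", metabolites = mets[1:2, ],
                  reactions = list(reaction("P", c("A@c" = -1, "C@c" = 1), lb = 0)))
  v2 <- gem_model("m", tool = "gapseq", metabolites = mets[2:3, ],
                  reactions = list(reaction("Q", c("C@c" = -1, "D@c" = 1), lb = 0)))
  expect_true("C@c" %in% find_dead_end_metabolites(v1))
  cons <- merge_models(list(v1, v2))$model
  expect_false("C@c" %in% find_dead_end_metabolites(cons))
  expect_true(consensus_dead_end_audit(list(v1, v2), cons)$ok)
  # a deliberately broken consensus fails the gene-union check
  broken <- cons
  broken$genes <- c(broken$genes, "ghost")
  expect_false(consensus_dead_end_audit(list(v1, v2), broken)$gene_union_ok)
})

test_that("merging never exceeds the summed reaction count and unions genes exactly", {
  for (seed in c(3, 8, 13)) {
    tr <- make_translated_triple(seed)
    mm <- merge_models(tr$views)
    expect_lte(length(mm$model$reactions),
               sum(vapply(tr$views, function(v) length(v$reactions), numeric(1))))
    expect_identical(mm$model$genes,
                     sort(unique(unlist(lapply(tr$views, `[[`, "genes")))))
  }
})
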