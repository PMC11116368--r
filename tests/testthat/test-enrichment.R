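test_that("Jaccard similarity covers the boundary cases", {
  expect_equal(jaccard(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(), character()), 1)
  expect_equal(jaccard(c("a", "a", "b"), c("b")), 1 / 2)   # set semantics
})

test_that("one minus Jaccard satisfies the triangle inequality", {
  set.seed(5)
  pool <- letters
  for (i in 1:100) {
    a <- sample(pool, sample(0:10, 1))
    b <- sample(pool, sample(0:10, 1))
    cc <- sample(pool, sample(0:10, 1))
    dab <- 1 - jaccard(a, b); dbc <- 1 - jaccard(b, cc); dac <- 1 - jaccard(a, cc)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("pairwise similarity matrices match direct set arithmetic", {
  tr <- make_translated_triple(6)
  M <- pairwise_similarity(tr$views, "reactions")
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(M, t(M))
  expect_equal(M["carveme", "gapseq"],
               jaccard(reaction_ids(tr$views$carveme),
                       reaction_ids(tr$views$gapseq)))
  # structurally identical views score 1 off-diagonal
  same <- list(a = tr$views[[1]], b = tr$views[[1]])
  expect_equal(unname(pairwise_similarity(same, "metabolites")[1, 2]), 1)
  expect_error(pairwise_similarity(tr$views, "colour"), "'arg' should be one of")
})

test_that("EC subclass extraction keeps the first two numeric fields", {
  expect_equal(ec_subclass("2.3.1.12"), "2.3")
  expect_equal(ec_subclass("4.2.99.18"), "4.2")
  expect_true(is.na(ec_subclass("3.-.-.-")))
  expect_true(is.na(ec_subclass("oxidoreductase")))
  expect_equal(ec_subclass(c("1.1.1.1", "7.2.4.1")), c("1.1", "7.2"))
})

test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  # worked case: only one way to draw all 4 from the 5 successes
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 3, 12, 12), 1)   # K = N: certain
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "violate")
  expect_error(hypergeom_upper_tail(2, 4, 5, 3), "violate")
})

test_that("hypergeometric tail matches draw enumeration on small populations", {
  for (N in c(5, 8, 11)) for (n in c(2, min(5, N - 1))) for (K in c(1, N %/% 2)) {
    for (k in 0:min(n, K)) {
      expect_equal(hypergeom_upper_tail(k, n, K, N), hyper_enum_upper(k, n, K, N),
                   tolerance = 1e-12,
                   info = sprintf("N=%d n=%d K=%d k=%d", N, n, K, k))
    }
  }
})

mk_rxn <- function(id, ec) reaction(id, setNames(-1, "x@c"), kind = "sink", ec = ec)

test_that("EC-subclass enrichment counts and tests as documented", {
  # single-subclass toy reproducing the worked hypergeometric counts:
  # background 10 annotated reactions, 5 in subclass 2.3; target = 4 of them
  bg <- c(lapply(1:5, function(i) mk_rxn(paste0("s", i), "2.3.1.1")),
          lapply(1:5, function(i) mk_rxn(paste0("o", i), "1.1.1.1")))
  tgt <- bg[1:4]
  et <- enrich_ec_subclasses(tgt, bg, alpha = 0.05)
  row <- et[et$subclass == "2.3", ]
  expect_equal(row$k, 4); expect_equal(row$n, 4)
  expect_equal(row$K, 5); expect_equal(row$N, 10)
  expect_equal(row$p_value, 5 / 210, tolerance = 1e-12)
  # target = background: every subclass has p = 1
  et2 <- enrich_ec_subclasses(bg, bg)
  expect_true(all(et2$p_value == 1))
  # a reaction with ECs in two subclasses counts once per subclass
  multi <- c(bg, list(reaction("m1", c("x@c" = -1), kind = "sink",
                               ec = c("2.3.9.9", "1.1.5.5"))))
  et3 <- enrich_ec_subclasses(list(multi[[11]]), multi)
  expect_equal(et3$k[et3$subclass == "2.3"], 1)
  expect_equal(et3$k[et3$subclass == "1.1"], 1)
  expect_equal(unique(et3$n), 1)
  expect_error(enrich_ec_subclasses(list(mk_rxn("nope", "5.5.5.5")), bg),
               "not contained")
})

test_that("BH adjustment preserves the order of raw p-values", {
  set.seed(9)
  bg <- lapply(1:40, function(i)
    mk_rxn(paste0("r", i), paste0(sample(c("1.1", "2.3", "2.7", "4.2"), 1), ".1.1")))
  tgt <- bg[sample(40, 15)]
  et <- enrich_ec_subclasses(tgt, bg)
  ord <- order(et$p_value)
  expect_true(all(diff(et$adjusted_p[ord]) >= -1e-12))
  expect_true(all(et$adjusted_p >= et$p_value - 1e-12))
})

test_that("enrichment is invariant to reaction relabeling", {
  set.seed(2)
  bg <- lapply(1:30, function(i)
    mk_rxn(paste0("r", i), paste0(sample(c("1.1", "2.3", "3.1"), 1), ".4.4")))
  tgt_idx <- sample(30, 10)
  et1 <- enrich_ec_subclasses(bg[tgt_idx], bg)
  bg2 <- lapply(seq_along(bg), function(i) {
    r <- bg[[i]]; r$id <- paste0("zz", i); r
  })
  et2 <- enrich_ec_subclasses(bg2[tgt_idx], bg2)
  expect_equal(et1[, c("subclass", "k", "n", "K", "N", "p_value")],
               et2[, c("subclass", "k", "n", "K", "N", "p_value")])
})

test_that("group tests dispatch correctly and behave at the extremes", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  kt <- group_tests(same)
  expect_equal(kt$method, "kruskal")
  expect_equal(kt$statistic, 0, tolerance = 1e-9)
  # completely separated ranks: rank-sum statistic at its extremum n1*n2
  wt <- group_tests(list(lo = c(1, 2, 3), hi = c(10, 11, 12)))
  expect_equal(wt$method, "wilcoxon")
  expect_equal(wt$statistic, 0)
  wt2 <- group_tests(list(hi = c(10, 11, 12), lo = c(1, 2, 3)))
  expect_equal(wt2$statistic, 9)   # n1 * n2
  pr <- group_tests(list(x = c(1, 2, 3, 5), y = c(2, 4, 6, 10)), method = "pearson")
  expect_equal(pr$estimate, 1, tolerance = 1e-12)
  expect_error(group_tests(list(a = 1, b = c(1, 2))), "n >= 2")
})
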