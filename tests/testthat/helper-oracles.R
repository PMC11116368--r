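# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately avoid the package's LP/MILP code paths: they use
# exhaustive enumeration and plain linear algebra only.

# --- toy model builders ----------------------------------------------------

# EX_A <-> A@e, T: A@e -> A@c, R1: A@c -> B@c, R2: B@c -> C@c; C has no
# consumer. Biomass optional (consumes B).
chain_model <- function(with_biomass = FALSE, uptake = 10) {
  mets <- rbind(metabolite("A@e", formula = "C2H4"),
                metabolite("A@c", formula = "C2H4"),
                metabolite("B@c", formula = "C2H4"),
                metabolite("C@c", formula = "C2H4"))
  rxns <- list(
    reaction("EX_A@e", c("A@e" = -1), lb = -uptake, ub = 1000, kind = "exchange"),
    reaction("T_A", c("A@e" = -1, "A@c" = 1), lb = 0, gpr = "gT"),
    reaction("R1", c("A@c" = -1, "B@c" = 1), lb = 0, gpr = "g1", ec = "1.1.1.1"),
    reaction("R2", c("B@c" = -1, "C@c" = 1), lb = 0, gpr = "g2", ec = "2.3.1.5"))
  obj <- NA_character_
  if (with_biomass) {
    rxns <- c(rxns, list(reaction("bio", c("B@c" = -1), lb = 0, kind = "biomass")))
    obj <- "bio"
  }
  gem_model("chain", tool = "synthetic", metabolites = mets, reactions = rxns,
            objective = obj)
}

# two parallel paths with capacities 4 and 6 feeding biomass
two_path_model <- function() {
  mets <- rbind(metabolite("S@e"), metabolite("S@c"), metabolite("P1@c"),
                metabolite("P2@c"), metabolite("Q@c"))
  rxns <- list(
    reaction("EX_S@e", c("S@e" = -1), lb = -10, ub = 1000, kind = "exchange"),
    reaction("T_S", c("S@e" = -1, "S@c" = 1), lb = 0),
    reaction("Ra", c("S@c" = -1, "P1@c" = 1), lb = 0, ub = 4),
    reaction("Rb", c("S@c" = -1, "P2@c" = 1), lb = 0, ub = 6),
    reaction("Ca", c("P1@c" = -1, "Q@c" = 1), lb = 0),
    reaction("Cb", c("P2@c" = -1, "Q@c" = 1), lb = 0),
    reaction("bio", c("Q@c" = -1), lb = 0, kind = "biomass"))
  gem_model("twopath", tool = "synthetic", metabolites = mets, reactions = rxns,
            objective = "bio")
}

# --- brute-force flux-space oracle -----------------------------------------

# All vertices (basic feasible solutions) of {v : S v = 0, lb <= v <= ub},
# found by fixing n - rank(S) variables at a bound and solving for the rest.
enumerate_flux_vertices <- function(model, tol = 1e-8) {
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb", USE.NAMES = FALSE)
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub", USE.NAMES = FALSE)
  n <- ncol(S)
  r <- if (nrow(S)) qr(S)$rank else 0
  nfree <- n - r
  verts <- list()
  try_point <- function(v) {
    if (all(v >= lb - 1e-6) && all(v <= ub + 1e-6) &&
        (nrow(S) == 0 || max(abs(S %*% v)) < 1e-6))
      verts[[length(verts) + 1L]] <<- v
  }
  if (nfree == 0) {
    v <- rep(0, n)
    try_point(v)
  } else {
    for (F in utils::combn(n, nfree, simplify = FALSE)) {
      B <- setdiff(seq_len(n), F)
      SB <- S[, B, drop = FALSE]
      if (qr(SB)$rank < length(B)) next
      for (mask in 0:(2^nfree - 1L)) {
        at_ub <- bitwAnd(mask, bitwShiftL(1L, seq_len(nfree) - 1L)) != 0L
        vF <- ifelse(at_ub, ub[F], lb[F])
        rhs <- -S[, F, drop = FALSE] %*% vF
        vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
        if (is.null(vB)) next
        v <- numeric(n)
        v[F] <- vF; v[B] <- vB
        try_point(v)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n, dimnames = list(NULL, colnames(S))))
  out <- do.call(rbind, verts)
  colnames(out) <- colnames(S)
  out
}

# blocked set by vertex enumeration: a reaction is blocked iff its flux is
# (numerically) zero at every vertex of the flux polytope
brute_blocked <- function(model, med = NULL, tol = 1e-6) {
  model <- apply_medium(model, med)
  V <- enumerate_flux_vertices(model)
  rids <- reaction_ids(model)
  if (nrow(V) == 0) return(sort(rids))
  sort(rids[apply(abs(V), 2, max) < tol])
}

# --- brute-force gap-fill oracle -------------------------------------------

# minimum total weight over all 2^k candidate subsets that reach biomass
# flux >= epsilon (Inf if none); feasibility via FBA on the assembled model
brute_gapfill_min_weight <- function(model, universal_db, med, epsilon = 0.05,
                                     weights = NULL) {
  op <- commgem:::open_medium_exchanges(model, med)
  model <- op$model
  cands <- commgem:::gapfill_candidates(model, universal_db)
  ids <- names(cands)
  if (is.null(weights)) weights <- setNames(rep(1, length(ids)), ids)
  best <- Inf
  for (mask in 0:(2^length(ids) - 1L)) {
    pick <- ids[bitwAnd(mask, bitwShiftL(1L, seq_along(ids) - 1L)) != 0L]
    w <- sum(weights[pick])
    if (w >= best) next
    m2 <- commgem:::combined_gapfill_model(model, cands[pick], universal_db)
    g <- tryCatch(fba(m2)$objective, error = function(e) -Inf)
    if (g >= epsilon - 1e-6) best <- w
  }
  best
}

# random small gap-fill instance: a linear pathway with some reactions
# removed into the database, plus decoys and a 2-step shortcut
random_gapfill_instance <- function(seed) {
  set.seed(seed)
  L <- 4
  mets <- rbind(metabolite("n@e", formula = "C6H12O6"),
                metabolite("n@c", formula = "C6H12O6"),
                do.call(rbind, lapply(seq_len(L), function(k)
                  metabolite(paste0("m", k, "@c")))))
  path_ids <- paste0("P", seq_len(L))
  rxns <- list(
    reaction("EX_n@e", c("n@e" = -1), lb = -10, ub = 1000, kind = "exchange"),
    reaction("T_n", c("n@e" = -1, "n@c" = 1), lb = 0))
  prev <- "n@c"
  for (k in seq_len(L)) {
    rxns[[length(rxns) + 1L]] <- reaction(path_ids[k],
                                          setNames(c(-1, 1), c(prev, paste0("m", k, "@c"))),
                                          lb = 0)
    prev <- paste0("m", k, "@c")
  }
  rxns[[length(rxns) + 1L]] <- reaction("bio", setNames(-1, paste0("m", L, "@c")),
                                        lb = 0, kind = "biomass")
  full <- gem_model("inst", tool = "synthetic", metabolites = mets,
                    reactions = rxns, objective = "bio")
  n_drop <- sample(1:3, 1)
  dropped <- sample(path_ids, n_drop)
  model <- full
  model$reactions <- model$reactions[setdiff(names(model$reactions), dropped)]
  db_mets <- rbind(mets, metabolite("s1@c"), metabolite("d1@c"), metabolite("d2@c"))
  db_rxns <- full$reactions[dropped]
  # 2-step shortcut from n to m2 (an alternative to P1+P2)
  db_rxns[["Sh1"]] <- reaction("Sh1", c("n@c" = -1, "s1@c" = 1), lb = 0)
  db_rxns[["Sh2"]] <- reaction("Sh2", c("s1@c" = -1, "m2@c" = 1), lb = 0)
  db_rxns[["D1"]] <- reaction("D1", c("d1@c" = -1, "d2@c" = 1), lb = 0)
  if (runif(1) < 0.5)
    db_rxns[["D2"]] <- reaction("D2", c("d2@c" = -1, "d1@c" = 1), lb = 0)
  db <- gem_model("db", tool = "synthetic", metabolites = db_mets,
                  reactions = db_rxns)
  list(model = model, db = db, medium = medium(c("n@e" = 10)))
}

# --- hypergeometric enumeration oracle -------------------------------------

# exact P[X >= k] by enumerating all C(N, n) draws from a population where
# items 1..K are the successes
hyper_enum_upper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# --- consensus triple builder ----------------------------------------------

# translated + stripped tool views of one truth network, ready to merge
make_translated_triple <- function(seed, complementary = FALSE) {
  fx <- generate_community(n_members = 1, seed = seed,
                           complementary_dropout = complementary,
                           auxotroph_members = integer())
  mem <- fx$members[[1]]
  views <- lapply(names(mem$views), function(tool) {
    tb <- mem$tables[[tool]]
    mf <- tempfile(fileext = ".tsv"); rf <- tempfile(fileext = ".tsv")
    write.table(tb$met, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tb$rxn, rf, sep = "\t", quote = FALSE, row.names = FALSE)
    map <- load_reference_tables(mf, rf)
    unlink(c(mf, rf))
    strip_boundary_and_biomass(translate_model(mem$views[[tool]], map)$model)
  })
  names(views) <- names(mem$views)
  list(views = views, truth = mem$truth)
}
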