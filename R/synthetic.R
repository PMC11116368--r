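# Synthetic ground-truth networks and tool-view degradations.
#
# The generator builds small but fully functional metabolic networks --
# nutrient uptake, a linear carbon core, amino-acid synthesis, secretable
# byproduct branches, and a biomass reaction -- and then derives per-tool
# "views" that emulate the structural signatures automated reconstruction
# tools leave on draft models: namespace relabeling, reaction and GPR
# dropout, gene pooling, and tool-specific dead-end appendages.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

EC_SUBCLASS_ALPHABET <- c("1.1", "2.3", "2.7", "4.2", "3.1")
EC_SUBCLASS_WEIGHTS <- c(0.20, 0.30, 0.20, 0.15, 0.15)

sample_ec <- function() {
  sub <- sample(EC_SUBCLASS_ALPHABET, 1, prob = EC_SUBCLASS_WEIGHTS)
  paste0(sub, ".", sample.int(20, 1), ".", sample.int(50, 1))
}

#' Generate a ground-truth toy metabolic network
#'
#' Builds a connected, growth-capable network: exchanges and transporters
#' for glucose, ammonium and magnesium; a linear carbon core
#' (glc -> cA -> cB -> accoa); alanine synthesis (cA + nh4 -> ala); a
#' universal biomass reaction consuming acetyl-CoA, alanine and magnesium;
#' and `n_branch_pathways` side branches of `branch_length` reactions each,
#' ending in a secretable extracellular byproduct with its own sink. Every
#' internal and transport reaction carries a synthetic GPR, and internal
#' reactions carry EC numbers drawn from a fixed subclass alphabet. The
#' truth network has no dead-end metabolites and positive growth on its own
#' media by construction.
#'
#' The universal gap-filling database contains the truth's internal and
#' transport reactions (GPR-stripped), an alternative three-step alanine
#' route, an alanine importer, and blocked decoy reactions over
#' database-only metabolites. The organism-specific alanine synthesis
#' reaction itself is deliberately absent from the database, so alanine
#' auxotrophs must either use the longer database route or import alanine.
#'
#' @param n_branch_pathways Number of byproduct branches (>= 1).
#' @param branch_length Reactions per branch (>= 1).
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param tag Short label baked into gene ids (keeps gene sets
#'   member-specific in community fixtures).
#' @return List with `model`, `biomass_spec`, `universal_db`, `media`
#'   (list `rich`, `minimal`), and `core_ids` (protected reaction ids).
#' @export
generate_truth_network <- function(n_branch_pathways = 3, branch_length = 2,
                                   seed = 1, tag = "t1") {
  if (n_branch_pathways < 1 || branch_length < 1)
    stop("n_branch_pathways and branch_length must be >= 1", call. = FALSE)
  with_seed(seed, {
    gene_i <- 0L
    new_gene <- function() {
      gene_i <<- gene_i + 1L
      paste0("g_", tag, "_", sprintf("%03d", gene_i))
    }
    rand_gpr <- function() {
      if (runif(1) < 0.3) {
        op <- if (runif(1) < 0.5) "and" else "or"
        paste0("(", new_gene(), " ", op, " ", new_gene(), ")")
      } else new_gene()
    }
    formulas <- c(glc = "C6H12O6", cA = "C6H10O5", cB = "C4H6O4",
                  accoa = "C23H38N7O17P3S", ala = "C3H7NO2", nh4 = "H4N",
                  mg = "Mg")
    mets <- empty_metabolites()
    add_met <- function(base, comp, formula = "") {
      id <- paste0(base, "@", comp)
      if (!(id %in% mets$id))
        mets <<- rbind(mets, metabolite(id, name = base, formula = formula,
                                        compartment = comp))
      id
    }
    for (b in c("glc", "nh4", "mg")) {
      add_met(b, "e", formulas[[b]]); add_met(b, "c", formulas[[b]])
    }
    for (b in c("cA", "cB", "accoa", "ala")) add_met(b, "c", formulas[[b]])

    rxns <- list()
    add_rxn <- function(id, stoich, lb = 0, ub = DEFAULT_BOUND, gpr = "",
                        ec = character(), kind = NA_character_) {
      rxns[[id]] <<- reaction(id, stoich, lb = lb, ub = ub, gpr = gpr, ec = ec,
                              kind = kind, source_tools = "truth")
    }
    for (b in c("glc", "nh4", "mg")) {
      add_rxn(paste0("EX_", b, "@e"), setNames(-1, paste0(b, "@e")),
              lb = -10, kind = "exchange")
      add_rxn(paste0("T", b), setNames(c(-1, 1), paste0(b, c("@e", "@c"))),
              gpr = rand_gpr(), kind = "transport")
    }
    add_rxn("Rcore1", c("glc@c" = -1, "cA@c" = 1), gpr = rand_gpr(), ec = sample_ec())
    add_rxn("Rcore2", c("cA@c" = -1, "cB@c" = 1), gpr = rand_gpr(), ec = sample_ec())
    add_rxn("Rcore3", c("cB@c" = -1, "accoa@c" = 1), lb = -DEFAULT_BOUND,
            gpr = rand_gpr(), ec = sample_ec())
    add_rxn("Rala", c("cA@c" = -1, "nh4@c" = -1, "ala@c" = 1),
            gpr = rand_gpr(), ec = sample_ec())

    starts <- c("glc@c", "cA@c", "cB@c")
    byproducts <- character()
    for (j in seq_len(n_branch_pathways)) {
      prev <- starts[((j - 1) %% length(starts)) + 1]
      for (k in seq_len(branch_length)) {
        nxt <- if (k == branch_length) add_met(paste0("byp", j), "c")
               else add_met(paste0("b", j, "m", k), "c")
        add_rxn(paste0("Rb", j, "_", k), setNames(c(-1, 1), c(prev, nxt)),
                gpr = rand_gpr(), ec = sample_ec())
        prev <- nxt
      }
      bype <- add_met(paste0("byp", j), "e")
      byproducts <- c(byproducts, bype)
      add_rxn(paste0("Tbyp", j), setNames(c(-1, 1), c(paste0("byp", j, "@c"), bype)),
              gpr = rand_gpr(), kind = "transport")
      add_rxn(paste0("SK_", bype), setNames(-1, bype), kind = "sink")
    }
    biomass_spec <- c("accoa@c" = -1, "ala@c" = -1, "mg@c" = -0.1)
    add_rxn("bio_universal", biomass_spec, kind = "biomass")

    model <- gem_model(paste0("mag_", tag), tool = "synthetic",
                       metabolites = mets, reactions = rxns,
                       objective = "bio_universal")
    core_ids <- c("Rcore1", "Rcore2", "Rcore3", "Rala",
                  paste0("T", c("glc", "nh4", "mg")),
                  paste0("EX_", c("glc", "nh4", "mg"), "@e"), "bio_universal")
    attr(model, "core_ids") <- core_ids

    # universal database: truth content without genetic support, an
    # alternative alanine route, an alanine importer, and blocked decoys
    db_mets <- mets
    db_rxns <- list()
    for (r in rxns) {
      if (r$kind %in% c("exchange", "sink", "biomass")) next
      if (r$id == "Rala") next
      r$gpr <- ""; r$source_tools <- "universal"
      db_rxns[[r$id]] <- r
    }
    db_mets <- rbind(db_mets, metabolite("ala@e", name = "ala",
                                         formula = formulas[["ala"]]),
                     metabolite("axA@c"), metabolite("axB@c"),
                     metabolite("dbx1@c"), metabolite("dbx2@c"),
                     metabolite("dbx3@c"))
    db_add <- function(id, stoich, lb = 0) {
      db_rxns[[id]] <<- reaction(id, stoich, lb = lb, ub = DEFAULT_BOUND,
                                 source_tools = "universal")
    }
    db_add("Raltala1", c("cB@c" = -1, "axA@c" = 1))
    db_add("Raltala2", c("axA@c" = -1, "axB@c" = 1))
    db_add("Raltala3", c("axB@c" = -1, "nh4@c" = -1, "ala@c" = 1))
    db_add("Tala_in", c("ala@e" = -1, "ala@c" = 1))
    db_add("Rdecoy1", c("dbx1@c" = -1, "dbx2@c" = 1))
    db_add("Rdecoy2", c("dbx2@c" = -1, "dbx3@c" = 1))
    db_add("Rdecoy3", c("dbx1@c" = -1, "dbx3@c" = 1), lb = -DEFAULT_BOUND)
    universal_db <- gem_model("universal", tool = "synthetic",
                              metabolites = db_mets, reactions = db_rxns)

    media <- list(
      rich = medium(c("glc@e" = 20, "nh4@e" = 20, "mg@e" = 20)),
      minimal = medium(c("glc@e" = 10, "nh4@e" = 10, "mg@e" = 10)))
    list(model = model, biomass_spec = biomass_spec,
         universal_db = universal_db, media = media, core_ids = core_ids,
         byproducts = byproducts)
  })
}

#' Reconstruction-tool degradation profile
#'
#' Parameters controlling how [derive_tool_view()] degrades a truth network
#' into a tool-like draft model.
#'
#' @param tool Tool label (`"carveme"`, `"gapseq"`, `"kbase"`, ...).
#' @param namespace_label Source-namespace label for relabeled identifiers.
#' @param reaction_dropout_prob Probability of dropping each non-core
#'   internal/transport reaction.
#' @param gene_dropout_prob Probability that a reaction loses its GPR.
#' @param extra_deadend_reactions Number of appended tool-specific reactions
#'   each producing a dead-end metabolite.
#' @param gpr_rewire_prob Probability that a reaction's GPR is replaced by a
#'   namespace-local gene.
#' @param gene_pool_size Size of the shared gene pool used for rewiring
#'   (`NA` = a fresh gene per rewire); a small pool emulates tools that map
#'   few genes to many reactions.
#' @return A `tool_profile` list.
#' @export
tool_profile <- function(tool, namespace_label = tool,
                         reaction_dropout_prob = 0, gene_dropout_prob = 0,
                         extra_deadend_reactions = 0L, gpr_rewire_prob = 0,
                         gene_pool_size = NA_integer_) {
  probs <- c(reaction_dropout_prob, gene_dropout_prob, gpr_rewire_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (extra_deadend_reactions < 0) stop("extra_deadend_reactions must be >= 0", call. = FALSE)
  structure(list(tool = tool, namespace_label = namespace_label,
                 reaction_dropout_prob = reaction_dropout_prob,
                 gene_dropout_prob = gene_dropout_prob,
                 extra_deadend_reactions = as.integer(extra_deadend_reactions),
                 gpr_rewire_prob = gpr_rewire_prob,
                 gene_pool_size = gene_pool_size),
            class = "tool_profile")
}

#' Standard tool profiles
#'
#' Default degradation profiles chosen so that, statistically over seeds,
#' the gapseq-like views carry the most reactions and dead-end metabolites,
#' the carveme-like views the most genes, and the kbase-like views the
#' fewest reactions — the qualitative ordering reported for draft
#' reconstructions of the same genomes.
#'
#' @return Named list of `tool_profile` objects.
#' @export
tool_profiles <- function() {
  list(
    carveme = tool_profile("carveme", "bigg", reaction_dropout_prob = 0.15,
                           gene_dropout_prob = 0.03, extra_deadend_reactions = 2L,
                           gpr_rewire_prob = 0.02),
    gapseq = tool_profile("gapseq", "gsseed", reaction_dropout_prob = 0.03,
                          gene_dropout_prob = 0.05, extra_deadend_reactions = 6L,
                          gpr_rewire_prob = 0.90, gene_pool_size = 6L),
    kbase = tool_profile("kbase", "kbseed", reaction_dropout_prob = 0.30,
                         gene_dropout_prob = 0.35, extra_deadend_reactions = 1L,
                         gpr_rewire_prob = 0.05))
}

relabel_model <- function(m, ns, mapped_from_truth) {
  bases <- sort(unique(met_base(m$metabolites$id)))
  met_map <- setNames(paste0(ns, "_m", sprintf("%03d", seq_along(bases))), bases)
  rename_met <- function(ids) paste0(met_map[met_base(ids)], "@", met_compartment(ids))
  m$metabolites$id <- rename_met(m$metabolites$id)
  rxn_rows <- list()
  new_rxns <- list()
  ri <- 0L
  for (r in m$reactions) {
    old_id <- r$id
    names(r$stoich) <- rename_met(names(r$stoich))
    new_id <- switch(r$kind,
                     exchange = paste0("EX_", names(r$stoich)),
                     sink = paste0("SK_", names(r$stoich)),
                     biomass = paste0("bio_", ns),
                     { ri <- ri + 1L; paste0(ns, "_r", sprintf("%03d", ri)) })
    r$id <- new_id
    new_rxns[[new_id]] <- r
    if (old_id %in% mapped_from_truth$rxns)
      rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
        source_namespace = ns, source_id = new_id, common_id = old_id)
    if (identical(m$objective, old_id)) m$objective <- new_id
  }
  m$reactions <- new_rxns
  met_rows <- data.frame(source_namespace = ns,
                         source_id = unname(met_map[intersect(bases, mapped_from_truth$mets)]),
                         common_id = intersect(bases, mapped_from_truth$mets))
  list(model = m,
       met_table = met_rows,
       rxn_table = if (length(rxn_rows)) do.call(rbind, rxn_rows) else
         data.frame(source_namespace = character(), source_id = character(),
                    common_id = character()))
}

#' Derive a tool-like view from a truth network
#'
#' Applies a [tool_profile()] to a truth model: drops non-core reactions
#' independently with the profile's dropout probability (the core biomass
#' path is protected), deletes or rewires GPR rules, appends tool-specific
#' reactions that create dead-end metabolites, prunes metabolites no longer
#' referenced, and relabels all identifiers into the profile's source
#' namespace. The cross-reference tables needed to translate the view back
#' to the common namespace are emitted alongside; the appended dead-end
#' content has no common-namespace counterpart and stays unmapped.
#'
#' @param truth Truth `gem_model` from [generate_truth_network()].
#' @param profile A `tool_profile`.
#' @param seed RNG seed.
#' @param drop_exact Optional character vector of reaction ids to drop
#'   instead of random dropout (used for complementary-dropout fixtures).
#' @return List with `model` (the view), `met_table`, `rxn_table`.
#' @export
derive_tool_view <- function(truth, profile, seed, drop_exact = NULL) {
  core <- attr(truth, "core_ids")
  with_seed(seed, {
    m <- truth
    m$tool <- profile$tool
    kinds <- vapply(m$reactions, `[[`, character(1), "kind")
    droppable <- names(m$reactions)[kinds %in% c("internal", "transport") &
                                      !(names(m$reactions) %in% core)]
    drop <- if (!is.null(drop_exact)) intersect(drop_exact, names(m$reactions))
            else droppable[runif(length(droppable)) < profile$reaction_dropout_prob]
    m$reactions <- m$reactions[!(names(m$reactions) %in% drop)]

    ns <- profile$namespace_label
    pool <- if (!is.na(profile$gene_pool_size))
      paste0("g_", ns, "_p", sprintf("%02d", seq_len(profile$gene_pool_size)))
    else NULL
    rw <- 0L
    for (id in names(m$reactions)) {
      if (m$reactions[[id]]$kind %in% c("exchange", "sink", "biomass")) next
      u <- runif(2)
      if (u[1] < profile$gene_dropout_prob) {
        m$reactions[[id]]$gpr <- ""
      } else if (u[2] < profile$gpr_rewire_prob) {
        m$reactions[[id]]$gpr <- if (!is.null(pool)) sample(pool, 1) else {
          rw <- rw + 1L
          paste0("g_", ns, "_rw", rw)
        }
      }
    }
    cyto <- m$metabolites$id[m$metabolites$compartment == "c"]
    cyto <- intersect(cyto, unique(unlist(lapply(m$reactions, function(r) names(r$stoich)))))
    for (i in seq_len(profile$extra_deadend_reactions)) {
      src <- sample(cyto, 1)
      dx <- paste0("dx_", ns, "_", i, "@c")
      m$metabolites <- rbind(m$metabolites, metabolite(dx))
      m$reactions[[paste0("DEX_", ns, "_", i)]] <-
        reaction(paste0("DEX_", ns, "_", i), setNames(c(-1, 1), c(src, dx)),
                 lb = 0, gpr = paste0("g_", ns, "_dx", i), ec = sample_ec(),
                 source_tools = profile$tool)
    }
    used <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
    m$metabolites <- m$metabolites[m$metabolites$id %in% used, , drop = FALSE]
    m$genes <- sort(unique(unlist(lapply(m$reactions, function(r) gpr_genes(r$gpr)))))
    mapped <- list(mets = met_base(truth$metabolites$id),
                   rxns = reaction_ids(truth))
    out <- relabel_model(m, ns, mapped)
    out$model <- gem_model(out$model$id, tool = profile$tool,
                           metabolites = out$model$metabolites,
                           reactions = out$model$reactions,
                           genes = out$model$genes,
                           objective = out$model$objective)
    out
  })
}

#' Generate a full synthetic community fixture
#'
#' Per member: a truth network (sharing the structural metabolite universe
#' across members so cross-feeding is possible, with member-specific gene
#' ids) and three tool views with namespace tables. One member (by default
#' the second, when present) is made an alanine auxotroph by deleting the
#' alanine-synthesis reaction and giving it an alanine importer; all other
#' members receive alanine export machinery, so the iterative gap-filler can
#' route alanine between members. Abundances are log-normal.
#'
#' @param n_members Number of community members (>= 1).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters
#'   (defaults 0 and 1, a typical MAG coverage shape).
#' @param profiles Named list of `tool_profile` (default [tool_profiles()]).
#' @param seed RNG seed.
#' @param n_branch_pathways,branch_length Passed to
#'   [generate_truth_network()].
#' @param complementary_dropout If `TRUE`, the three views of each member
#'   drop disjoint thirds of the droppable reactions and add no extra
#'   dead-end appendages, so the consensus restores the full truth content.
#' @param auxotroph_members Indices of members made alanine auxotrophs
#'   (default: member 2 when `n_members >= 2`).
#' @return List with `members` (per member: `truth`, `views`, namespace
#'   tables), `abundance`, `biomass_spec`, `universal_db`, `media`, `seed`.
#' @export
generate_community <- function(n_members = 4, abundance_meanlog = 0,
                               abundance_sdlog = 1, profiles = tool_profiles(),
                               seed = 1, n_branch_pathways = 3,
                               branch_length = 2, complementary_dropout = FALSE,
                               auxotroph_members = NULL) {
  if (n_members < 1) stop("n_members must be >= 1", call. = FALSE)
  if (is.null(auxotroph_members))
    auxotroph_members <- if (n_members >= 2) 2L else integer()
  mags <- sprintf("mag%02d", seq_len(n_members))
  abundance <- with_seed(seed, setNames(rlnorm(n_members, abundance_meanlog,
                                               abundance_sdlog), mags))
  members <- list()
  biomass_spec <- NULL; universal_db <- NULL; media <- NULL
  for (j in seq_len(n_members)) {
    ms <- (seed %% 100000L) * 211L + j * 13L
    tn <- generate_truth_network(n_branch_pathways, branch_length, seed = ms,
                                 tag = mags[j])
    truth <- tn$model
    truth$id <- mags[j]
    if (j %in% auxotroph_members) {
      truth$reactions[["Rala"]] <- NULL
      truth <- ensure_metabolites(truth, "ala@e")
      truth$metabolites$formula[truth$metabolites$id == "ala@e"] <- "C3H7NO2"
      truth <- set_reaction(truth, reaction("Tala_in", c("ala@e" = -1, "ala@c" = 1),
                                            lb = 0, gpr = paste0("g_", mags[j], "_tai"),
                                            kind = "transport"))
      attr(truth, "core_ids") <- setdiff(c(attr(tn$model, "core_ids"), "Tala_in"), "Rala")
    } else {
      truth <- ensure_metabolites(truth, "ala@e")
      truth$metabolites$formula[truth$metabolites$id == "ala@e"] <- "C3H7NO2"
      truth <- set_reaction(truth, reaction("Tala_out", c("ala@c" = -1, "ala@e" = 1),
                                            lb = 0, gpr = paste0("g_", mags[j], "_tao"),
                                            kind = "transport"))
      truth <- set_reaction(truth, reaction("SK_ala@e", c("ala@e" = -1), lb = 0,
                                            kind = "sink"))
      attr(truth, "core_ids") <- c(attr(tn$model, "core_ids"), "Tala_out")
    }
    drop_sets <- NULL
    if (complementary_dropout) {
      # internal reactions only: dropping one always severs a branch chain
      # and creates a fresh dead end that the merged consensus repairs,
      # while dropping a transport can instead delete the extracellular
      # metabolite from the view altogether
      kinds <- vapply(truth$reactions, `[[`, character(1), "kind")
      droppable <- names(truth$reactions)[kinds == "internal" &
                                            !(names(truth$reactions) %in% attr(truth, "core_ids"))]
      idx <- with_seed(ms + 7L, sample(rep_len(seq_along(profiles), length(droppable))))
      drop_sets <- split(droppable, idx)
    }
    views <- list()
    tables <- list()
    for (pi in seq_along(profiles)) {
      pf <- profiles[[pi]]
      if (complementary_dropout) {
        pf$extra_deadend_reactions <- 0L
        de <- if (pi <= length(drop_sets)) drop_sets[[pi]] else character()
      } else de <- NULL
      v <- derive_tool_view(truth, pf, seed = ms + 1000L * pi, drop_exact = de)
      views[[pf$tool]] <- v$model
      tables[[pf$tool]] <- list(met = v$met_table, rxn = v$rxn_table)
    }
    members[[mags[j]]] <- list(truth = truth, views = views, tables = tables)
    if (j == 1) {
      biomass_spec <- tn$biomass_spec
      universal_db <- tn$universal_db
      media <- tn$media
    }
  }
  list(members = members, abundance = abundance, biomass_spec = biomass_spec,
       universal_db = universal_db, media = media, seed = seed)
}

#' Designed two-member cross-feeding fixture
#'
#' A donor (high abundance) that can synthesize and export alanine, and a
#' dependent member (low abundance) that lacks alanine synthesis but can
#' import alanine. Processed in descending abundance order, the donor grows
#' without additions, its permeable metabolites (including alanine) augment
#' the medium pool, and the dependent member is gap-filled with a single
#' uptake reaction; processed first (ascending order), the dependent member
#' must take the three-reaction alternative synthesis route from the
#' database instead.
#'
#' @param seed RNG seed.
#' @return List with `community` (a `gem_community`, descending order),
#'   `universal_db`, `media`, `biomass_spec`.
#' @export
crossfeeding_fixture <- function(seed = 1) {
  don <- generate_truth_network(2, 2, seed = (seed %% 100000L) * 31L + 1L, tag = "don")
  dep <- generate_truth_network(2, 2, seed = (seed %% 100000L) * 31L + 2L, tag = "dep")
  donor <- don$model; donor$id <- "donor"
  donor <- ensure_metabolites(donor, "ala@e")
  donor$metabolites$formula[donor$metabolites$id == "ala@e"] <- "C3H7NO2"
  donor <- set_reaction(donor, reaction("Tala_out", c("ala@c" = -1, "ala@e" = 1),
                                        lb = 0, gpr = "g_don_tao", kind = "transport"))
  donor <- set_reaction(donor, reaction("SK_ala@e", c("ala@e" = -1), lb = 0,
                                        kind = "sink"))
  dependent <- dep$model; dependent$id <- "dependent"
  dependent$reactions[["Rala"]] <- NULL
  dependent <- ensure_metabolites(dependent, "ala@e")
  dependent$metabolites$formula[dependent$metabolites$id == "ala@e"] <- "C3H7NO2"
  dependent <- set_reaction(dependent, reaction("Tala_in", c("ala@e" = -1, "ala@c" = 1),
                                                lb = 0, gpr = "g_dep_tai",
                                                kind = "transport"))
  comm <- community(list(donor = donor, dependent = dependent),
                    abundance = c(donor = 5, dependent = 1),
                    order = "descending")
  list(community = comm, universal_db = dep$universal_db, media = dep$media,
       biomass_spec = dep$biomass_spec)
}
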