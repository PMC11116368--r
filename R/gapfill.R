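#' Insert a universal biomass reaction
#'
#' Adds (or replaces) the biomass reaction and sets it as the model
#' objective. The same biomass stoichiometry — in practice adapted from the
#' E. coli biomass composition restricted to universal prokaryotic
#' components — is inserted into every draft model so that growth demands
#' are comparable across reconstruction tools. Metabolites referenced by the
#' spec but absent from the model are added (they may remain unproducible
#' until gap-filling).
#'
#' @param model A `gem_model`.
#' @param biomass_spec Named numeric vector: metabolite id -> coefficient
#'   (negative = consumed precursor).
#' @param id Reaction id for the biomass reaction.
#' @return Model with exactly one biomass reaction, set as objective.
#' @export
add_universal_biomass <- function(model, biomass_spec, id = "bio_universal") {
  biomass_spec <- unlist(biomass_spec)
  if (length(biomass_spec) == 0)
    stop("add_universal_biomass: empty biomass specification", call. = FALSE)
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  old <- names(model$reactions)[kinds == "biomass"]
  if (length(old)) {
    model$reactions <- model$reactions[!(names(model$reactions) %in% old)]
    message("replaced existing biomass reaction(s): ", paste(old, collapse = ", "))
  }
  model <- ensure_metabolites(model, names(biomass_spec))
  model$objective <- id
  rxn <- reaction(id, biomass_spec, lb = 0, ub = DEFAULT_BOUND, kind = "biomass")
  model$reactions[[id]] <- rxn
  errs <- validate_model(model)
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  model
}

open_medium_exchanges <- function(model, med) {
  # make sure every medium metabolite present in the model has an exchange
  # reaction; these are infrastructure, never counted as gap-fill additions
  opened <- character()
  if (is.null(med)) return(list(model = model, opened = opened))
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  ex_mets <- vapply(model$reactions[kinds == "exchange"],
                    function(r) names(r$stoich), character(1))
  for (m in names(med$uptake)) {
    if (!(m %in% model$metabolites$id) || m %in% ex_mets) next
    ex_id <- paste0("EX_", m)
    model$reactions[[ex_id]] <- reaction(ex_id, setNames(-1, m),
                                         lb = -med$uptake[[m]], ub = DEFAULT_BOUND,
                                         kind = "exchange")
    opened <- c(opened, ex_id)
  }
  list(model = apply_medium(model, med), opened = opened)
}

gapfill_candidates <- function(model, universal_db) {
  have_ids <- reaction_ids(model)
  have_keys <- vapply(model$reactions, function(r) canonical_stoich(r)$key,
                      character(1), USE.NAMES = FALSE)
  cands <- list()
  for (r in universal_db$reactions) {
    if (r$id %in% have_ids) next
    if (canonical_stoich(r)$key %in% have_keys) next
    r$gpr <- ""                      # gap-filled content has no genetic support
    r$source_tools <- "gapfill"
    cands[[r$id]] <- r
  }
  cands
}

combined_gapfill_model <- function(model, candidates, universal_db) {
  comb <- model
  for (r in candidates) {
    new_mets <- setdiff(names(r$stoich), comb$metabolites$id)
    if (length(new_mets)) {
      rows <- universal_db$metabolites[match(new_mets, universal_db$metabolites$id), , drop = FALSE]
      miss <- is.na(rows$id)
      if (any(miss)) rows[miss, ] <- do.call(rbind, lapply(new_mets[miss], metabolite))
      comb$metabolites <- rbind(comb$metabolites, rows)
    }
    comb$reactions[[r$id]] <- r
  }
  comb
}

gapfill_milp_parts <- function(comb, cand_ids, epsilon) {
  p <- model_lp_parts(comb)
  n_v <- length(p$rids)
  n_c <- length(cand_ids)
  cand_pos <- match(cand_ids, p$rids)
  n <- n_v + n_c
  pad <- function(M) cbind(M, matrix(0, nrow(M), n_c))
  A <- pad(p$S); dir <- rep("==", nrow(p$S)); rhs <- rep(0, nrow(p$S))
  # linking rows: lb_i * y_i <= v_i <= ub_i * y_i for each candidate
  for (k in seq_len(n_c)) {
    i <- cand_pos[k]
    row_hi <- numeric(n); row_hi[i] <- 1; row_hi[n_v + k] <- -p$ub[i]
    A <- rbind(A, row_hi); dir <- c(dir, "<="); rhs <- c(rhs, 0)
    row_lo <- numeric(n); row_lo[i] <- 1; row_lo[n_v + k] <- -p$lb[i]
    A <- rbind(A, row_lo); dir <- c(dir, ">="); rhs <- c(rhs, 0)
  }
  bio <- numeric(n); bio[match(comb$objective, p$rids)] <- 1
  A <- rbind(A, bio); dir <- c(dir, ">="); rhs <- c(rhs, epsilon)
  list(A = A, dir = dir, rhs = rhs,
       lb = c(p$lb, rep(0, n_c)), ub = c(p$ub, rep(1, n_c)),
       n_v = n_v, n_c = n_c, rids = p$rids)
}

diagnose_blocked_precursors <- function(comb, epsilon, tol = 1e-6) {
  bio <- comb$reactions[[comb$objective]]
  precursors <- names(bio$stoich)[bio$stoich < 0]
  blocked <- character()
  for (pmet in precursors) {
    probe <- comb
    probe$reactions[[comb$objective]] <- NULL
    probe$objective <- NA_character_
    sk <- paste0("SK_diag_", pmet)
    probe$reactions[[sk]] <- reaction(sk, setNames(-1, pmet), lb = 0,
                                      ub = DEFAULT_BOUND, kind = "sink")
    res <- tryCatch(fba(probe, objective = sk), error = function(e) NULL)
    required <- epsilon * abs(bio$stoich[[pmet]])
    if (is.null(res) || res$objective < required - tol)
      blocked <- c(blocked, pmet)
  }
  blocked
}

lexicographic_tiebreak <- function(parts, weights, w_star, cand_ids, tol = 1e-6) {
  # among minimum-weight solutions, pick the lexicographically smallest
  # sorted reaction-id set: scan candidates in id order and force each one
  # in whenever some minimum-weight solution still contains it
  n <- parts$n_v + parts$n_c
  ord <- order(cand_ids)
  A <- rbind(parts$A, c(rep(0, parts$n_v), weights))
  dir <- c(parts$dir, "<="); rhs <- c(parts$rhs, w_star + tol)
  lb <- parts$lb; ub <- parts$ub
  obj <- c(rep(0, parts$n_v), weights)
  chosen <- character()
  for (k in ord) {
    trial_lb <- lb; trial_lb[parts$n_v + k] <- 1
    res <- solve_milp(obj, A, dir, rhs, trial_lb, ub,
                      int_idx = parts$n_v + seq_len(parts$n_c), maximize = FALSE)
    if (res$status == "optimal" && res$objective <= w_star + tol) {
      lb <- trial_lb
      chosen <- c(chosen, cand_ids[k])
      if (sum(weights[match(chosen, cand_ids)]) >= w_star - tol) break
    } else {
      ub[parts$n_v + k] <- 0
    }
  }
  sort(chosen)
}

#' Gap-fill a model to growth
#'
#' Finds a minimum-weight set of reactions from a universal database whose
#' addition lets the model reach a biomass flux of at least `epsilon` on the
#' given medium. The selection is formulated as a mixed-integer program with
#' one binary indicator per candidate database reaction (objective: sum of
#' weights, default 1 per reaction) and solved exactly by branch-and-bound;
#' `relaxed = TRUE` switches to the LP relaxation (faster, minimality not
#' guaranteed). Ties between equal-weight solutions break deterministically
#' to the lexicographically smallest reaction-id set. Added reactions carry
#' no GPR (no genetic support). Exchange reactions for medium metabolites
#' are opened as infrastructure and never counted as additions.
#'
#' @param model A `gem_model` with a biomass objective.
#' @param universal_db A `gem_model` acting as the reaction database (in the
#'   same namespace).
#' @param med A `gem_medium`.
#' @param epsilon Minimum required biomass flux (default 0.05).
#' @param weights Named numeric vector of per-reaction weights (default 1).
#' @param relaxed Use the LP relaxation instead of the exact MILP.
#' @param tol Flux tolerance (default 1e-6).
#' @param tie_break Apply the lexicographic tie-break (default `TRUE`).
#' @return A `gapfill_result`: `mag_id`, `added_reactions`, `imported`,
#'   `exported`, `growth`, `status`, `opened_exchanges`, and the augmented
#'   `model`.
#' @export
gapfill_model <- function(model, universal_db, med, epsilon = 0.05,
                          weights = NULL, relaxed = FALSE, tol = 1e-6,
                          tie_break = TRUE) {
  if (is.na(model$objective))
    stop("gapfill_model: model has no biomass objective", call. = FALSE)
  op <- open_medium_exchanges(model, med)
  model <- op$model
  result <- function(added, growth, m, status = "ok") {
    structure(list(mag_id = m$id, added_reactions = added,
                   imported = imported_metabolites(m),
                   exported = exported_metabolites(m),
                   growth = growth, status = status,
                   opened_exchanges = op$opened, model = m),
              class = "gapfill_result")
  }
  base <- tryCatch(fba(model), error = function(e) NULL)
  if (!is.null(base) && base$objective >= epsilon - tol)
    return(result(character(), base$objective, model))

  cands <- gapfill_candidates(model, universal_db)
  comb <- combined_gapfill_model(model, cands, universal_db)
  full <- tryCatch(fba(comb), error = function(e) NULL)
  if (is.null(full) || full$objective < epsilon - tol) {
    blocked <- diagnose_blocked_precursors(comb, epsilon, tol)
    stop(structure(class = c("commgem_gapfill_infeasible", "error", "condition"),
                   list(message = paste0(
                     "gap-filling infeasible for model '", model$id,
                     "' even with the full database; blocked biomass precursor(s): ",
                     if (length(blocked)) paste(blocked, collapse = ", ") else "(none isolated)"),
                     call = NULL, blocked_precursors = blocked)))
  }
  cand_ids <- names(cands)
  if (is.null(weights)) weights <- setNames(rep(1, length(cand_ids)), cand_ids)
  w <- unname(weights[cand_ids]); w[is.na(w)] <- 1
  parts <- gapfill_milp_parts(comb, cand_ids, epsilon)
  obj <- c(rep(0, parts$n_v), w)
  if (relaxed) {
    sol <- solve_lp(obj, parts$A, parts$dir, parts$rhs, parts$lb, parts$ub,
                    maximize = FALSE)
    if (sol$status != "optimal")
      stop("gapfill_model: relaxed LP ", sol$status, call. = FALSE)
    added <- sort(cand_ids[sol$solution[parts$n_v + seq_len(parts$n_c)] > tol])
  } else {
    sol <- solve_milp(obj, parts$A, parts$dir, parts$rhs, parts$lb, parts$ub,
                      int_idx = parts$n_v + seq_len(parts$n_c), maximize = FALSE)
    if (sol$status != "optimal")
      stop("gapfill_model: MILP ", sol$status, call. = FALSE)
    added <- sort(cand_ids[sol$solution[parts$n_v + seq_len(parts$n_c)] > 0.5])
    if (tie_break && length(added))
      added <- lexicographic_tiebreak(parts, w, sol$objective, cand_ids)
  }
  aug <- combined_gapfill_model(model, cands[added], universal_db)
  growth <- fba(aug)$objective
  result(added, growth, aug)
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("<gapfill_result> %s [%s]: %d added, growth %.4g, %d imported, %d exported\n",
              x$mag_id, x$status, length(x$added_reactions), x$growth,
              length(x$imported), length(x$exported)))
  invisible(x)
}

#' Predict permeable (secretable) metabolites
#'
#' Extracellular metabolites whose secretion flux can exceed `tol` while the
#' model keeps a biomass flux of at least `epsilon`; each metabolite is
#' tested by maximizing its (temporary) sink flux under the growth
#' constraint. These are the metabolites used to augment the shared medium
#' during iterative community gap-filling.
#'
#' @inheritParams gapfill_model
#' @param tol Minimum secretion flux to call a metabolite permeable.
#' @return Sorted character vector of extracellular metabolite ids.
#' @export
predict_permeable_metabolites <- function(model, med = NULL, epsilon = 0.05,
                                          tol = 1e-6) {
  model <- apply_medium(model, med)
  growth <- tryCatch(fba(model)$objective, error = function(e) NA_real_)
  if (is.na(growth) || growth < epsilon - tol)
    stop("predict_permeable_metabolites: model does not reach biomass flux ",
         epsilon, " on the given medium", call. = FALSE)
  # candidates: extracellular metabolites the model cannot currently take
  # up (an importable metabolite routed straight back out through a sink is
  # a loop artifact, not secretion of a synthesized product)
  ex_mets <- setdiff(model$metabolites$id[model$metabolites$compartment == "e"],
                     imported_metabolites(model))
  if (!length(ex_mets)) return(character())
  p <- model_lp_parts(model)
  bio_row <- as.numeric(p$rids == model$objective)
  perm <- character()
  for (m in ex_mets) {
    probe <- model
    kinds <- vapply(probe$reactions, `[[`, character(1), "kind")
    sink_hit <- names(probe$reactions)[kinds == "sink" &
      vapply(probe$reactions, function(r) identical(names(r$stoich), m), logical(1))]
    sk <- if (length(sink_hit)) sink_hit[1] else {
      id <- paste0("SK_tmp_", m)
      probe$reactions[[id]] <- reaction(id, setNames(-1, m), lb = 0,
                                        ub = DEFAULT_BOUND, kind = "sink")
      id
    }
    pp <- model_lp_parts(probe)
    A <- rbind(pp$S, as.numeric(pp$rids == probe$objective))
    dir <- c(rep("==", nrow(pp$S)), ">=")
    rhs <- c(rep(0, nrow(pp$S)), epsilon)
    res <- solve_lp(as.numeric(pp$rids == sk), A, dir, rhs, pp$lb, pp$ub,
                    maximize = TRUE)
    if (res$status == "optimal" && res$objective > tol) perm <- c(perm, m)
  }
  sort(perm)
}

#' Community of per-genome models
#'
#' @param members Named list of `gem_model` (name = MAG id).
#' @param abundance Named positive numeric vector (MAG id -> abundance, e.g.
#'   sum of contig read coverages).
#' @param order `"descending"` (most abundant first) or `"ascending"`.
#' @return A `gem_community` object.
#' @export
community <- function(members, abundance, order = c("descending", "ascending")) {
  order <- match.arg(order)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("community members must be a named list", call. = FALSE)
  missing_ab <- setdiff(names(members), names(abundance))
  if (length(missing_ab))
    stop("abundance missing for member(s): ", paste(missing_ab, collapse = ", "),
         call. = FALSE)
  if (any(abundance[names(members)] <= 0))
    stop("abundances must be positive", call. = FALSE)
  structure(list(members = members, abundance = abundance[names(members)],
                 order = order), class = "gem_community")
}

#' @export
print.gem_community <- function(x, ...) {
  cat("<gem_community>", length(x$members), "members, order:", x$order, "\n")
  invisible(x)
}

#' Iterative abundance-ordered community gap-filling
#'
#' Processes community members in the order given by their abundance. The
#' first member is gap-filled on the initial (rich, LB-like) medium; every
#' subsequent member is gap-filled on the base (minimal, M9-like) medium,
#' with uptake reactions for all previously predicted permeable metabolites
#' added to the gap-filling database as weighted candidates. After each
#' successful gap-fill the member's permeable metabolites are predicted,
#' sink reactions are installed for them (defining the member's exported
#' set), and the shared pool grows monotonically. The final medium is the
#' base medium plus every exported metabolite.
#'
#' @param comm A `gem_community` (members must carry a biomass objective).
#' @param init_medium Initial `gem_medium` for the first member.
#' @param base_medium Base `gem_medium` for subsequent members.
#' @param universal_db Universal reaction database (`gem_model`).
#' @param epsilon,tol As in [gapfill_model()].
#' @param uptake_rate Uptake rate granted to pool-derived exchange
#'   candidates (default 10).
#' @param fail_fast Stop at the first infeasible member instead of recording
#'   and continuing.
#' @param relaxed Passed to [gapfill_model()].
#' @return List with `results` (list of `gapfill_result` in processing
#'   order) and `final_medium`.
#' @export
iterative_community_gapfill <- function(comm, init_medium, base_medium,
                                        universal_db, epsilon = 0.05,
                                        tol = 1e-6, uptake_rate = 10,
                                        fail_fast = FALSE, relaxed = FALSE) {
  ab <- comm$abundance
  ord <- order(if (comm$order == "descending") -ab else ab, names(ab))
  mags <- names(ab)[ord]
  pool <- character()
  results <- list()
  for (i in seq_along(mags)) {
    mag <- mags[i]
    m <- comm$members[[mag]]
    med <- if (i == 1) init_medium else base_medium
    db <- universal_db
    if (i > 1 && length(pool)) {
      db <- ensure_metabolites(db, pool)
      for (pm in setdiff(pool, names(base_medium$uptake))) {
        ex_id <- paste0("EX_", pm)
        if (!(ex_id %in% reaction_ids(db)))
          db$reactions[[ex_id]] <- reaction(ex_id, setNames(-1, pm),
                                            lb = -uptake_rate, ub = DEFAULT_BOUND,
                                            kind = "exchange")
      }
      m <- ensure_metabolites(m, intersect(pool, db$metabolites$id))
    }
    res <- tryCatch(
      gapfill_model(m, db, med, epsilon = epsilon, tol = tol, relaxed = relaxed),
      commgem_gapfill_infeasible = function(e) {
        structure(list(mag_id = mag, added_reactions = character(),
                       imported = character(), exported = character(),
                       growth = 0, status = "infeasible",
                       blocked_precursors = e$blocked_precursors,
                       opened_exchanges = character(), model = m),
                  class = "gapfill_result")
      })
    if (res$status == "ok") {
      perm <- predict_permeable_metabolites(res$model, epsilon = epsilon, tol = tol)
      for (pm in perm) {
        sk <- paste0("SK_", pm)
        if (!(sk %in% reaction_ids(res$model)))
          res$model$reactions[[sk]] <- reaction(sk, setNames(-1, pm), lb = 0,
                                                ub = DEFAULT_BOUND, kind = "sink")
      }
      res$exported <- exported_metabolites(res$model)
      pool <- sort(unique(c(pool, perm)))
    } else if (fail_fast) {
      stop("gap-filling infeasible for member '", mag, "'", call. = FALSE)
    }
    results[[mag]] <- res
  }
  extra <- setdiff(pool, names(base_medium$uptake))
  final_uptake <- c(base_medium$uptake, setNames(rep(uptake_rate, length(extra)), extra))
  list(results = results, final_medium = medium(final_uptake))
}

#' Correlate MAG abundance with gap-fill outcome counts
#'
#' Pearson correlation between member abundances and the per-member number
#' of added reactions, imported metabolites, or exported metabolites.
#'
#' @param results List of `gapfill_result` (named by MAG id).
#' @param abundance Named numeric abundance vector.
#' @param metric One of `"added"`, `"imported"`, `"exported"`.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_abundance_with_gapfill <- function(results, abundance,
                                             metric = c("added", "imported", "exported")) {
  metric <- match.arg(metric)
  mags <- names(results)
  counts <- vapply(results, function(r) switch(metric,
    added = length(r$added_reactions),
    imported = length(r$imported),
    exported = length(r$exported)), numeric(1))
  x <- abundance[mags]
  if (length(x) < 3) stop("need at least 3 members", call. = FALSE)
  if (sd(x) == 0 || sd(counts) == 0)
    stop("undefined correlation: zero variance in ",
         if (sd(x) == 0) "abundance" else metric, call. = FALSE)
  ct <- cor.test(x, counts, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
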