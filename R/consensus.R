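#' Remove boundary and biomass reactions
#'
#' Drops all exchange, sink, and biomass reactions (and clears the
#' objective); everything else is untouched. Draft models are stripped this
#' way before consensus merging so that each tool's boundary conventions and
#' biomass formulation do not contaminate the merged network.
#'
#' @param model A `gem_model`.
#' @return Stripped model.
#' @export
strip_boundary_and_biomass <- function(model) {
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  model$reactions <- model$reactions[!(kinds %in% c("exchange", "sink", "biomass"))]
  model$objective <- NA_character_
  model
}

canonical_stoich <- function(rxn, digits = 9) {
  st <- rxn$stoich
  if (length(st) == 0) return(list(key = paste0("empty:", rxn$id), orientation = 1))
  st <- st[order(names(st))]
  scale <- abs(st[[1]])
  v <- st / scale
  orientation <- sign(st[[1]])
  # orient so the lexicographically first metabolite has a negative sign;
  # the same physical conversion written in either direction gets one key
  if (orientation > 0) v <- -v
  list(key = paste(names(v), formatC(v, digits = digits, format = "g"),
                   sep = ":", collapse = "|"),
       orientation = orientation)
}

#' Classify two reactions as duplicates
#'
#' Reactions (in a common namespace) are `duplicate` if they share a reaction
#' id or have identical stoichiometry after canonical normalization (sorted
#' metabolite ids, coefficients rescaled to the first metabolite);
#' `duplicate_reversed` if their stoichiometries are exact negations;
#' `distinct` otherwise.
#'
#' @param r1,r2 `gem_reaction` objects.
#' @return `"duplicate"`, `"duplicate_reversed"`, or `"distinct"`.
#' @export
reactions_equivalent <- function(r1, r2) {
  if (identical(r1$id, r2$id)) return("duplicate")
  c1 <- canonical_stoich(r1); c2 <- canonical_stoich(r2)
  if (!identical(c1$key, c2$key)) return("distinct")
  if (c1$orientation == c2$orientation) "duplicate" else "duplicate_reversed"
}

merge_into <- function(kept, incoming, reversed, incoming_tool) {
  if (reversed) {
    # negate the later reaction: its forward direction is kept's backward
    lb_in <- -incoming$ub; ub_in <- -incoming$lb
  } else {
    lb_in <- incoming$lb; ub_in <- incoming$ub
  }
  kept$lb <- min(kept$lb, lb_in)
  kept$ub <- max(kept$ub, ub_in)
  kept$gpr <- gpr_or(kept$gpr, incoming$gpr)
  kept$ec <- sort(unique(c(kept$ec, incoming$ec)))
  src_in <- if (length(incoming$source_tools)) incoming$source_tools else incoming_tool
  kept$source_tools <- sort(unique(c(kept$source_tools, src_in)))
  kept
}

#' Merge tool views into a consensus model
#'
#' Iteratively folds an ordered list of per-genome models (already translated
#' to the common namespace and stripped of boundary/biomass reactions) into
#' one consensus model: the gene set becomes the exact union of the views'
#' gene sets, duplicate reactions are kept once with flux bounds widened to
#' the union of allowed directions and GPR rules combined by OR when they are
#' not logically equivalent, reversed duplicates are merged after negation,
#' and metabolite attribute conflicts resolve first-seen-wins (logged). When
#' candidate duplicates disagree on the mass-balance verdict, the balanced
#' variant's formula annotations are kept.
#'
#' @param views Ordered list of `gem_model` (first view seeds the consensus;
#'   the conventional order is carveme, gapseq, kbase).
#' @param id Consensus model id; defaults to the first view's id.
#' @return List with `model` (the consensus, `tool = "consensus"`) and
#'   `report` (per-view counts of added/merged reactions and conflict logs).
#' @export
merge_models <- function(views, id = NULL) {
  if (length(views) == 0) stop("merge_models: empty view list", call. = FALSE)
  if (is.null(id)) id <- views[[1]]$id
  consensus <- gem_model(id, tool = "consensus", validate = FALSE)
  key_index <- new.env(parent = emptyenv())   # canonical key -> kept rxn id
  report <- data.frame(view = character(), tool = character(),
                       n_reactions = integer(), added = integer(),
                       merged = integer(), stringsAsFactors = FALSE)
  conflicts <- character()

  for (vi in seq_along(views)) {
    view <- views[[vi]]
    added <- merged <- 0L
    kept_ids <- reaction_ids(consensus)
    for (r in view$reactions) {
      ck <- canonical_stoich(r)
      hit_id <- NULL
      if (r$id %in% kept_ids) {
        hit_id <- r$id
      } else if (!is.null(key_index[[ck$key]])) {
        hit_id <- key_index[[ck$key]]
      }
      if (is.null(hit_id)) {
        # new reaction: bring its metabolites along, first-seen attributes win
        new_mets <- setdiff(names(r$stoich), consensus$metabolites$id)
        if (length(new_mets)) {
          rows <- view$metabolites[match(new_mets, view$metabolites$id), , drop = FALSE]
          miss <- is.na(rows$id)
          if (any(miss)) rows[miss, ] <- do.call(rbind, lapply(new_mets[miss], metabolite))
          consensus$metabolites <- rbind(consensus$metabolites, rows)
        }
        old_mets <- intersect(names(r$stoich), consensus$metabolites$id)
        for (m in setdiff(old_mets, new_mets)) {
          i_c <- match(m, consensus$metabolites$id)
          i_v <- match(m, view$metabolites$id)
          if (!is.na(i_v)) {
            fc <- consensus$metabolites$formula[i_c]; fv <- view$metabolites$formula[i_v]
            if (nzchar(fc) && nzchar(fv) && fc != fv)
              conflicts <- c(conflicts, sprintf("metabolite %s: formula '%s' (kept) vs '%s' (%s)",
                                                m, fc, fv, view$tool))
          }
        }
        if (!length(r$source_tools)) r$source_tools <- view$tool
        consensus$reactions[[r$id]] <- r
        kept_ids <- c(kept_ids, r$id)
        key_index[[ck$key]] <- r$id
        added <- added + 1L
      } else {
        kept <- consensus$reactions[[hit_id]]
        reversed <- identical(reactions_equivalent(kept, r), "duplicate_reversed")
        # mass-balance criterion: if the kept variant is not balanced but the
        # incoming one is (in its own view's annotation context), adopt the
        # balanced variant's formula annotations for the touched metabolites
        bal_kept <- check_mass_charge_balance(kept, consensus$metabolites)$verdict
        bal_in <- tryCatch(check_mass_charge_balance(r, view$metabolites)$verdict,
                           error = function(e) "undetermined")
        if (!identical(bal_kept, "balanced") && identical(bal_in, "balanced")) {
          for (m in names(r$stoich)) {
            i_v <- match(m, view$metabolites$id)
            i_c <- match(m, consensus$metabolites$id)
            if (!is.na(i_v) && !is.na(i_c)) {
              consensus$metabolites$formula[i_c] <- view$metabolites$formula[i_v]
              consensus$metabolites$charge[i_c] <- view$metabolites$charge[i_v]
            }
          }
          conflicts <- c(conflicts, sprintf(
            "reaction %s: adopted balanced formula annotations from %s", hit_id, view$tool))
        }
        consensus$reactions[[hit_id]] <- merge_into(kept, r, reversed, view$tool)
        merged <- merged + 1L
      }
    }
    consensus$genes <- sort(unique(c(consensus$genes, view$genes)))
    report <- rbind(report, data.frame(
      view = view$id, tool = view$tool, n_reactions = length(view$reactions),
      added = added, merged = merged, stringsAsFactors = FALSE))
  }
  errs <- validate_model(consensus)
  if (length(errs))
    stop("consensus merge produced an invalid model:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  list(model = consensus,
       report = list(per_view = report, conflicts = conflicts))
}

#' Audit consensus invariants against its source views
#'
#' Verifies that (a) the consensus gene set equals the exact union of the
#' views' gene sets, and (b) every consensus dead-end metabolite is a
#' dead-end in every view that contains it (merging can only add producers
#' and consumers, never remove them).
#'
#' @param views List of translated, stripped `gem_model` views.
#' @param consensus The merged consensus model.
#' @return List with `gene_union_ok`, `dead_end_ok`, `ok`, and a character
#'   vector of `violations`.
#' @export
consensus_dead_end_audit <- function(views, consensus) {
  violations <- character()
  gene_union <- sort(unique(unlist(lapply(views, `[[`, "genes"))))
  gene_ok <- identical(gene_union, consensus$genes)
  if (!gene_ok)
    violations <- c(violations, paste0(
      "gene set mismatch: consensus has ", length(consensus$genes),
      " genes, view union has ", length(gene_union)))
  cons_dead <- find_dead_end_metabolites(consensus)
  view_dead <- lapply(views, find_dead_end_metabolites)
  dead_ok <- TRUE
  for (m in cons_dead) {
    for (i in seq_along(views)) {
      if (m %in% views[[i]]$metabolites$id && !(m %in% view_dead[[i]])) {
        dead_ok <- FALSE
        violations <- c(violations, paste0(
          "metabolite ", m, " is dead-end in consensus but not in view ",
          views[[i]]$tool))
      }
    }
  }
  list(gene_union_ok = gene_ok, dead_end_ok = dead_ok,
       ok = gene_ok && dead_ok, violations = violations)
}
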