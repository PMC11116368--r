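#' @importFrom stats setNames sd cor.test kruskal.test wilcox.test phyper p.adjust rlnorm runif sample.int
#' @importFrom utils read.delim write.table head modifyList
NULL

DEFAULT_BOUND <- 1000

#' Metabolite record
#'
#' Metabolite identifiers are namespace-qualified and carry their compartment
#' as an `@<code>` suffix, e.g. `"MNXM2@c"` (cytosol) or `"MNXM2@e"`
#' (extracellular).
#'
#' @param id Metabolite id including compartment suffix.
#' @param name Human-readable name.
#' @param formula Chemical formula string (`""` if unknown).
#' @param charge Integer charge (`NA` if unknown).
#' @param compartment Compartment code; defaults to the id suffix.
#' @return A one-row data.frame.
#' @export
metabolite <- function(id, name = id, formula = "", charge = NA_integer_,
                       compartment = met_compartment(id)) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (is.na(compartment) || !nzchar(compartment))
    stop("metabolite '", id, "' has no compartment (use an '@<code>' suffix)", call. = FALSE)
  data.frame(id = id, name = name, formula = as.character(formula),
             charge = as.integer(charge), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Compartment code of a metabolite id
#'
#' @param id Character vector of metabolite ids (`"base@comp"`).
#' @return Character vector of compartment codes (`NA` when no suffix).
#' @export
met_compartment <- function(id) {
  ifelse(grepl("@", id), sub("^.*@", "", id), NA_character_)
}

#' Base (compartment-free) part of a metabolite id
#'
#' @param id Character vector of metabolite ids.
#' @return Character vector without the `@<code>` suffix.
#' @export
met_base <- function(id) sub("@[^@]*$", "", id)

#' Reaction record
#'
#' @param id Reaction id.
#' @param stoich Named numeric vector of stoichiometric coefficients
#'   (names are metabolite ids; negative = substrate, positive = product).
#' @param lb,ub Flux bounds in mmol/gDW/h; defaults are +/-1000 for a
#'   reversible reaction.
#' @param gpr GPR string (`""` = no genetic support).
#' @param ec Character vector of EC numbers.
#' @param kind One of `"internal"`, `"transport"`, `"exchange"`, `"sink"`,
#'   `"biomass"`, or `NA` to infer from structure via [infer_reaction_kind()].
#' @param source_tools Character vector of reconstruction-tool labels that
#'   contributed this reaction.
#' @return A `gem_reaction` list.
#' @export
reaction <- function(id, stoich, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND,
                     gpr = "", ec = character(), kind = NA_character_,
                     source_tools = character()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  stoich <- unlist(stoich)
  if (length(stoich) && is.null(names(stoich)))
    stop("reaction '", id, "': stoichiometry must be a named vector", call. = FALSE)
  stoich <- stoich[stoich != 0]
  if (lb > ub)
    stop("reaction '", id, "': lower bound exceeds upper bound", call. = FALSE)
  structure(list(id = id, stoich = stoich, lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = as.character(gpr), ec = as.character(ec),
                 kind = kind, source_tools = as.character(source_tools)),
            class = "gem_reaction")
}

#' Infer the functional kind of a reaction
#'
#' Heuristic roles used throughout the comparison pipeline:
#' the objective reaction is `biomass`; an `EX_`-prefixed reaction touching a
#' single metabolite is an `exchange`; an `SK_`-prefixed single-metabolite
#' reaction is a `sink`; a reaction moving one chemical species between two
#' compartments is a `transport`; everything else is `internal`.
#'
#' @param rxn A `gem_reaction`.
#' @param objective Reaction id of the model objective (or `NA`).
#' @return Kind string.
#' @export
infer_reaction_kind <- function(rxn, objective = NA_character_) {
  if (!is.na(objective) && identical(rxn$id, objective)) return("biomass")
  n <- length(rxn$stoich)
  if (n == 1L) {
    if (grepl("^EX_", rxn$id)) return("exchange")
    if (grepl("^(SK_|sink_)", rxn$id)) return("sink")
  }
  comps <- met_compartment(names(rxn$stoich))
  bases <- met_base(names(rxn$stoich))
  if (n >= 2L && length(unique(comps[!is.na(comps)])) > 1L &&
      length(unique(bases)) < length(bases)) return("transport")
  "internal"
}

#' Assemble a genome-scale model
#'
#' The central container: a set of metabolites, a set of reactions, the gene
#' inventory, and an optional biomass objective. Invariants (unique ids,
#' referenced metabolites declared, GPR genes present in the gene set,
#' exchange/sink reactions touching exactly one metabolite) are enforced at
#' construction.
#'
#' @param id Model id (typically a MAG identifier).
#' @param tool Reconstruction-tool label (e.g. `"carveme"`, `"gapseq"`,
#'   `"kbase"`, `"consensus"`, `"synthetic"`).
#' @param metabolites data.frame as built by [metabolite()] (row-bound).
#' @param reactions List of `gem_reaction` objects.
#' @param genes Character vector of gene ids; defaults to the union of GPR
#'   genes.
#' @param objective Reaction id of the biomass objective, or `NA`.
#' @param validate Check invariants (default `TRUE`).
#' @return A `gem_model` object.
#' @export
gem_model <- function(id, tool = "synthetic",
                      metabolites = empty_metabolites(),
                      reactions = list(), genes = NULL,
                      objective = NA_character_, validate = TRUE) {
  if (length(reactions) && is.null(names(reactions)))
    names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  gpr_gene_union <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  if (is.null(genes)) genes <- gpr_gene_union
  m <- structure(list(id = id, tool = tool, metabolites = metabolites,
                      reactions = reactions, genes = sort(unique(as.character(genes))),
                      objective = objective),
                 class = "gem_model")
  for (i in seq_along(m$reactions)) {
    r <- m$reactions[[i]]
    if (is.na(r$kind) || !nzchar(r$kind))
      m$reactions[[i]]$kind <- infer_reaction_kind(r, objective = m$objective)
  }
  if (validate) {
    errs <- validate_model(m)
    if (length(errs))
      stop("invalid model '", id, "':\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  m
}

#' @rdname gem_model
#' @export
empty_metabolites <- function() {
  data.frame(id = character(), name = character(), formula = character(),
             charge = integer(), compartment = character(), stringsAsFactors = FALSE)
}

#' Validate model invariants
#'
#' @param model A `gem_model`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_model <- function(model) {
  errs <- character()
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    errs <- c(errs, paste0("duplicate metabolite ids: ",
                           paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    errs <- c(errs, paste0("duplicate reaction ids: ",
                           paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  if (any(!nzchar(mets$compartment) | is.na(mets$compartment)))
    errs <- c(errs, "metabolite with empty compartment")
  for (r in model$reactions) {
    missing_mets <- setdiff(names(r$stoich), mets$id)
    if (length(missing_mets))
      errs <- c(errs, paste0("reaction '", r$id, "' references undeclared metabolite(s): ",
                             paste(missing_mets, collapse = ", ")))
    if (r$lb > r$ub)
      errs <- c(errs, paste0("reaction '", r$id, "': lb > ub"))
    if (r$kind %in% c("exchange", "sink") && length(r$stoich) != 1L)
      errs <- c(errs, paste0(r$kind, " reaction '", r$id, "' must touch exactly one metabolite"))
    if (length(r$stoich) == 0L && !(r$kind %in% c("exchange", "sink")))
      errs <- c(errs, paste0("reaction '", r$id, "' has empty stoichiometry"))
    bad_genes <- setdiff(gpr_genes(r$gpr), model$genes)
    if (length(bad_genes))
      errs <- c(errs, paste0("reaction '", r$id, "' GPR uses gene(s) absent from model: ",
                             paste(bad_genes, collapse = ", ")))
  }
  if (!is.na(model$objective) && !(model$objective %in% rids))
    errs <- c(errs, paste0("objective reaction '", model$objective, "' not in model"))
  errs
}

#' Reaction ids of a model
#' @param model A `gem_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id", USE.NAMES = FALSE)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `gem_model`.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- reaction_ids(model)
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    if (length(st)) S[names(st), j] <- st
  }
  S
}

#' @export
print.gem_reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]; rhs <- x$stoich[x$stoich > 0]
  fmt <- function(v) if (!length(v)) "" else
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  arrow <- if (x$lb < 0 && x$ub > 0) "<=>" else if (x$ub > 0) "-->" else "<--"
  cat(sprintf("%s: %s %s %s  [%g, %g] %s\n", x$id, fmt(lhs), arrow, fmt(rhs),
              x$lb, x$ub, x$kind))
  invisible(x)
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("<gem_model> %s (%s): %d reactions, %d metabolites, %d genes",
              x$id, x$tool, length(x$reactions), nrow(x$metabolites),
              length(x$genes)))
  if (!is.na(x$objective)) cat(", objective =", x$objective)
  cat("\n")
  invisible(x)
}

#' @export
summary.gem_model <- function(object, ...) {
  s <- model_stats(object)
  print(object)
  cat(sprintf("  dead-end metabolites: %d\n  reactions without GPR: %.1f%%\n",
              s$n_dead_ends, 100 * s$frac_reactions_without_gpr))
  kinds <- table(vapply(object$reactions, `[[`, character(1), "kind"))
  if (length(kinds))
    cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(s)
}

#' Replace or add a reaction in a model
#' @param model A `gem_model`.
#' @param rxn A `gem_reaction`.
#' @param validate Re-validate afterwards.
#' @return Updated model.
#' @export
set_reaction <- function(model, rxn, validate = FALSE) {
  if (is.na(rxn$kind) || !nzchar(rxn$kind))
    rxn$kind <- infer_reaction_kind(rxn, objective = model$objective)
  model$reactions[[rxn$id]] <- rxn
  model$genes <- sort(unique(c(model$genes, gpr_genes(rxn$gpr))))
  if (validate) {
    errs <- validate_model(model)
    if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  }
  model
}

#' Ensure metabolites exist in a model
#'
#' Adds any of the given ids that are missing, with default attributes.
#' @param model A `gem_model`.
#' @param ids Metabolite ids (with compartment suffix).
#' @return Updated model.
#' @export
ensure_metabolites <- function(model, ids) {
  new <- setdiff(ids, model$metabolites$id)
  if (length(new)) {
    add <- do.call(rbind, lapply(new, metabolite))
    model$metabolites <- rbind(model$metabolites, add)
  }
  model
}

#' Structural digest of a model
#'
#' An order-independent summary used for round-trip and merge-invariance
#' checks: sorted metabolite ids, sorted canonical stoichiometries with
#' direction class, gene set, and per-reaction GPR truth-table fingerprints.
#'
#' @param model A `gem_model`.
#' @return A list comparable with [identical()].
#' @export
model_digest <- function(model) {
  canon <- vapply(model$reactions, function(r) {
    st <- r$stoich[order(names(r$stoich))]
    dir <- if (r$lb < 0 && r$ub > 0) "rev" else if (r$ub > 0) "fwd" else "bwd"
    paste0(paste(names(st), format(st, digits = 12), collapse = "|"), "#", dir)
  }, character(1), USE.NAMES = FALSE)
  list(metabolites = sort(model$metabolites$id),
       reactions = sort(canon),
       genes = model$genes)
}
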