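#' Load identifier cross-reference tables
#'
#' Reads TSV tables mapping source-namespace identifiers (e.g. BiGG-like or
#' ModelSEED-like) to a common reference namespace. Tables have three
#' columns — `source_namespace`, `source_id`, `common_id` — and may contain
#' `#` comment lines. Duplicate consistent rows collapse to one entry;
#' conflicting rows (same source id mapped to different common ids) raise an
#' error listing the conflicts.
#'
#' @param metabolite_tables Character vector of TSV paths for metabolite
#'   mappings.
#' @param reaction_tables Character vector of TSV paths for reaction
#'   mappings (optional; reaction coverage of reference namespaces is
#'   typically partial).
#' @return A `namespace_map` object with `met_map`, `rxn_map` (named
#'   character vectors source id -> common id) and `provenance`.
#' @export
load_reference_tables <- function(metabolite_tables, reaction_tables = character()) {
  read_map <- function(paths, what) {
    if (!length(paths))
      return(list(map = setNames(character(), character()),
                  prov = setNames(character(), character())))
    tabs <- lapply(paths, function(p) {
      t <- read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
      need <- c("source_namespace", "source_id", "common_id")
      if (!all(need %in% names(t)))
        stop("reference table '", p, "' must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
      t[, need]
    })
    tab <- unique(do.call(rbind, tabs))
    if (any(!nzchar(tab$common_id)) || anyNA(tab$common_id))
      stop("reference table has empty common_id entries (", what, ")", call. = FALSE)
    dup <- tab$source_id[duplicated(tab$source_id)]
    if (length(dup)) {
      conf <- tab[tab$source_id %in% dup, ]
      stop("conflicting ", what, " mappings:\n",
           paste(sprintf("  %s -> %s (%s)", conf$source_id, conf$common_id,
                         conf$source_namespace), collapse = "\n"),
           call. = FALSE)
    }
    list(map = setNames(tab$common_id, tab$source_id),
         prov = setNames(tab$source_namespace, tab$source_id))
  }
  met <- read_map(metabolite_tables, "metabolite")
  rxn <- read_map(reaction_tables, "reaction")
  structure(list(met_map = met$map, rxn_map = rxn$map,
                 provenance = c(met$prov, rxn$prov)),
            class = "namespace_map")
}

#' @export
print.namespace_map <- function(x, ...) {
  cat("<namespace_map>", length(x$met_map), "metabolite and",
      length(x$rxn_map), "reaction mappings\n")
  invisible(x)
}

translate_one_met <- function(base, map, tool) {
  if (base %in% names(map$met_map)) return(unname(map$met_map[[base]]))
  if (startsWith(base, "unmapped:") || base %in% map$met_map) return(base)
  paste0("unmapped:", tool, ":", base)
}

translate_one_rxn <- function(id, map, tool) {
  if (id %in% names(map$rxn_map)) return(unname(map$rxn_map[[id]]))
  if (startsWith(id, "unmapped:") || id %in% map$rxn_map) return(id)
  paste0("unmapped:", tool, ":", id)
}

#' Translate a model into the common namespace
#'
#' Replaces every mapped metabolite and reaction identifier by its common id
#' (the `@<compartment>` suffix is preserved). Unmapped identifiers are
#' retained with an `unmapped:<tool>:` provenance prefix rather than dropped,
#' so that set comparisons between tools penalize namespace gaps. If two
#' source metabolites in the same compartment map to one common id they are
#' fused and reaction stoichiometries are rewritten; coefficients that cancel
#' exactly are dropped, and a reaction left with empty stoichiometry is
#' removed and logged. Translation is idempotent and never touches gene sets.
#'
#' @param model A `gem_model`.
#' @param map A `namespace_map` from [load_reference_tables()].
#' @return List with `model` (translated) and `report`: fractions of mapped
#'   metabolites/reactions, fusion log, removed reactions.
#' @export
translate_model <- function(model, map) {
  tool <- model$tool
  old_ids <- model$metabolites$id
  bases <- met_base(old_ids)
  comps <- met_compartment(old_ids)
  new_bases <- vapply(bases, translate_one_met, character(1),
                      map = map, tool = tool, USE.NAMES = FALSE)
  new_ids <- paste0(new_bases, "@", comps)
  met_mapped <- bases %in% names(map$met_map) | bases %in% map$met_map |
    startsWith(bases, "unmapped:")
  id_map <- setNames(new_ids, old_ids)

  fusions <- new_ids[duplicated(new_ids)]
  fusion_log <- character()
  keep <- !duplicated(new_ids)
  mets <- model$metabolites[keep, , drop = FALSE]   # first-seen attributes win
  mets$id <- new_ids[keep]
  rownames(mets) <- NULL
  if (length(fusions))
    fusion_log <- vapply(unique(fusions), function(f) {
      srcs <- old_ids[new_ids == f]
      paste0(f, " <- {", paste(srcs, collapse = ", "), "}")
    }, character(1), USE.NAMES = FALSE)

  removed <- character()
  reactions <- list()
  rxn_mapped <- logical(0)
  for (r in model$reactions) {
    st <- r$stoich
    if (length(st)) {
      new_names <- unname(id_map[names(st)])
      agg <- tapply(st, new_names, sum)
      st <- setNames(as.numeric(agg), names(agg))
      st <- st[abs(st) > 1e-12]
    }
    new_id <- translate_one_rxn(r$id, map, tool)
    rxn_mapped <- c(rxn_mapped, r$id %in% names(map$rxn_map) ||
                      r$id %in% map$rxn_map || startsWith(r$id, "unmapped:"))
    if (length(st) == 0 && !(r$kind %in% c("exchange", "sink"))) {
      removed <- c(removed, r$id)
      next
    }
    r$id <- new_id
    r$stoich <- st
    reactions[[new_id]] <- r
  }
  objective <- model$objective
  if (!is.na(objective))
    objective <- translate_one_rxn(objective, map, tool)
  if (!is.na(objective) && !(objective %in% names(reactions)))
    objective <- NA_character_
  out <- gem_model(model$id, tool = tool, metabolites = mets,
                   reactions = reactions, genes = model$genes,
                   objective = objective)
  n_r <- length(model$reactions)
  list(model = out,
       report = list(
         frac_metabolites_mapped = if (length(bases)) mean(met_mapped) else 1,
         frac_reactions_mapped = if (n_r) mean(rxn_mapped) else 1,
         fused = fusion_log,
         removed_reactions = removed))
}

#' Write a translation coverage report
#'
#' @param reports Named list of reports from [translate_model()] (name =
#'   model id).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm,
               frac_metabolites_mapped = r$frac_metabolites_mapped,
               frac_reactions_mapped = r$frac_reactions_mapped,
               n_fused = length(r$fused),
               n_removed_reactions = length(r$removed_reactions))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
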