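# Imported / exported / exchanged metabolite analysis. Membership is
# bound-based (potential transport capability), not flux-based: a metabolite
# is imported if some exchange reaction permits its uptake, exported if some
# sink permits its secretion. Realized fluxes are a separate question
# answered by export_flux_ranges().

#' Metabolites a model can import
#'
#' Metabolites of exchange reactions whose lower bound permits uptake
#' (`lb < 0`).
#'
#' @param model A `gem_model`.
#' @return Sorted character vector of metabolite ids.
#' @export
imported_metabolites <- function(model) {
  out <- character()
  for (r in model$reactions)
    if (identical(r$kind, "exchange") && r$lb < 0)
      out <- c(out, names(r$stoich))
  sort(unique(out))
}

#' Metabolites a model can export
#'
#' Metabolites of sink reactions whose upper bound permits secretion
#' (`ub > 0`).
#'
#' @param model A `gem_model`.
#' @return Sorted character vector of metabolite ids.
#' @export
exported_metabolites <- function(model) {
  out <- character()
  for (r in model$reactions)
    if (identical(r$kind, "sink") && r$ub > 0)
      out <- c(out, names(r$stoich))
  sort(unique(out))
}

#' Community-exchanged metabolites
#'
#' The intersection of the union of exported and the union of imported
#' metabolites over all community members: metabolites that can be both
#' secreted and taken up somewhere in the community.
#'
#' @param models List of gap-filled `gem_model`.
#' @return Sorted character vector of metabolite ids.
#' @export
community_exchanged <- function(models) {
  if (!length(models)) stop("community_exchanged: need at least one model", call. = FALSE)
  exp_all <- sort(unique(unlist(lapply(models, exported_metabolites))))
  imp_all <- sort(unique(unlist(lapply(models, imported_metabolites))))
  intersect(exp_all, imp_all)
}

#' Summarize community exchange potential per reconstruction approach
#'
#' For each approach: mean and sample standard deviation of the per-model
#' numbers of imported and exported metabolites, and the size of the
#' community-exchanged set; plus the cross-approach Jaccard similarity of
#' the exchanged sets.
#'
#' @param communities Named list (approach -> list of gap-filled
#'   `gem_model`).
#' @return List with `summary` (one row per approach) and
#'   `exchanged_jaccard` (approach x approach matrix).
#' @export
exchange_summary <- function(communities) {
  rows <- list()
  exchanged_sets <- list()
  for (approach in names(communities)) {
    models <- communities[[approach]]
    if (!length(models)) {
      rows[[approach]] <- data.frame(
        approach = approach, n_models = 0L, mean_imported = NA_real_,
        sd_imported = NA_real_, mean_exported = NA_real_,
        sd_exported = NA_real_, n_exchanged = NA_integer_)
      exchanged_sets[[approach]] <- character()
      next
    }
    imp <- vapply(models, function(m) length(imported_metabolites(m)), numeric(1))
    exp_ <- vapply(models, function(m) length(exported_metabolites(m)), numeric(1))
    exch <- community_exchanged(models)
    exchanged_sets[[approach]] <- exch
    rows[[approach]] <- data.frame(
      approach = approach, n_models = length(models),
      mean_imported = mean(imp), sd_imported = if (length(imp) > 1) sd(imp) else 0,
      mean_exported = mean(exp_), sd_exported = if (length(exp_) > 1) sd(exp_) else 0,
      n_exchanged = length(exch))
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  n <- length(exchanged_sets)
  J <- matrix(1, n, n, dimnames = list(names(exchanged_sets), names(exchanged_sets)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      J[i, j] <- J[j, i] <- jaccard(exchanged_sets[[i]], exchanged_sets[[j]])
  list(summary = summary_df, exchanged_jaccard = J,
       exchanged_sets = exchanged_sets)
}
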