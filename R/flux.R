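#' Growth medium
#'
#' A medium is a set of extracellular metabolites with maximum uptake rates.
#' Applying a medium to a model sets the lower bound of each exchange
#' reaction: `-rate` for metabolites in the medium, `0` (no uptake) for all
#' other exchanged metabolites. Secretion (positive exchange flux) is never
#' restricted by the medium.
#'
#' @param uptake Named numeric vector: metabolite id (extracellular, e.g.
#'   `"glc@e"`) -> maximum uptake rate (positive, mmol/gDW/h).
#' @return A `gem_medium` object.
#' @export
medium <- function(uptake) {
  uptake <- unlist(uptake)
  if (length(uptake) && (is.null(names(uptake)) || any(!nzchar(names(uptake)))))
    stop("medium uptake vector must be named by metabolite id", call. = FALSE)
  if (any(uptake <= 0))
    stop("medium uptake rates must be positive: ",
         paste(names(uptake)[uptake <= 0], collapse = ", "), call. = FALSE)
  structure(list(uptake = uptake), class = "gem_medium")
}

#' @export
print.gem_medium <- function(x, ...) {
  cat("<gem_medium>", length(x$uptake), "metabolites:",
      paste(utils::head(names(x$uptake), 8), collapse = ", "),
      if (length(x$uptake) > 8) "..." else "", "\n")
  invisible(x)
}

#' Constrain a model's exchange bounds to a medium
#'
#' @param model A `gem_model`.
#' @param med A `gem_medium` (or `NULL` to leave bounds untouched).
#' @return Model with exchange lower bounds set from the medium.
#' @export
apply_medium <- function(model, med) {
  if (is.null(med)) return(model)
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (!identical(r$kind, "exchange")) next
    m <- names(r$stoich)
    if (m %in% names(med$uptake)) {
      model$reactions[[i]]$lb <- -med$uptake[[m]]
    } else {
      model$reactions[[i]]$lb <- max(r$lb, 0)
    }
    if (model$reactions[[i]]$ub < model$reactions[[i]]$lb)
      model$reactions[[i]]$ub <- model$reactions[[i]]$lb
  }
  model
}

model_lp_parts <- function(model) {
  S <- stoich_matrix(model)
  list(S = S,
       lb = vapply(model$reactions, `[[`, numeric(1), "lb", USE.NAMES = FALSE),
       ub = vapply(model$reactions, `[[`, numeric(1), "ub", USE.NAMES = FALSE),
       rids = colnames(S))
}

#' Flux balance analysis
#'
#' Maximizes the model objective subject to steady state (`S v = 0`), flux
#' bounds, and the medium's uptake limits.
#'
#' @param model A `gem_model` with an objective reaction.
#' @param med A `gem_medium` or `NULL` (use bounds as stored).
#' @param objective Optional reaction id to optimize instead of the model
#'   objective.
#' @return List with `objective` (optimal value), `fluxes` (named vector),
#'   `status`.
#' @export
fba <- function(model, med = NULL, objective = NULL) {
  if (is.null(objective)) objective <- model$objective
  if (is.na(objective) || !(objective %in% reaction_ids(model)))
    stop("fba: model has no objective reaction", call. = FALSE)
  model <- apply_medium(model, med)
  p <- model_lp_parts(model)
  obj <- as.numeric(p$rids == objective)
  n_m <- nrow(p$S)
  res <- solve_lp(obj, p$S, rep("==", n_m), rep(0, n_m), p$lb, p$ub, maximize = TRUE)
  if (res$status != "optimal")
    stop("fba: LP ", res$status, " for model '", model$id, "'", call. = FALSE)
  list(objective = res$objective,
       fluxes = setNames(res$solution, p$rids),
       status = res$status)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, bounds,
#' the medium, and (optionally) an objective value at least
#' `fraction_of_optimum` times the FBA optimum.
#'
#' @inheritParams fba
#' @param reactions Reaction ids to scan (default: all).
#' @param fraction_of_optimum In `[0, 1]`; `0` imposes no growth requirement.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, med = NULL, reactions = NULL, fraction_of_optimum = 0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  model <- apply_medium(model, med)
  p <- model_lp_parts(model)
  if (is.null(reactions)) reactions <- p$rids
  unknown <- setdiff(reactions, p$rids)
  if (length(unknown))
    stop("fva: unknown reaction(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  n_m <- nrow(p$S)
  A <- p$S; dir <- rep("==", n_m); rhs <- rep(0, n_m)
  if (fraction_of_optimum > 0) {
    opt <- fba(model)$objective
    row <- as.numeric(p$rids == model$objective)
    A <- rbind(A, row); dir <- c(dir, ">="); rhs <- c(rhs, fraction_of_optimum * opt)
  }
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    obj <- as.numeric(p$rids == reactions[i])
    lo <- solve_lp(obj, A, dir, rhs, p$lb, p$ub, maximize = FALSE)
    hi <- solve_lp(obj, A, dir, rhs, p$lb, p$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("fva: LP ", lo$status, "/", hi$status, " at reaction ", reactions[i],
           call. = FALSE)
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' Blocked reactions
#'
#' Reactions that cannot carry flux in any feasible steady state (FVA with no
#' growth requirement; both extrema within `tol` of zero).
#'
#' @inheritParams fva
#' @param tol Flux tolerance (default 1e-6).
#' @return Sorted character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, med = NULL, tol = 1e-6) {
  v <- fva(model, med, fraction_of_optimum = 0)
  sort(v$reaction[abs(v$min) < tol & abs(v$max) < tol])
}

#' Export flux ranges at optimal growth
#'
#' For each listed exported metabolite, the FVA range of its sink (secretion)
#' reaction with the biomass objective fixed at its optimum.
#'
#' @inheritParams fba
#' @param exported_metabolites Metabolite ids to scan; default: all
#'   metabolites with a sink reaction.
#' @return data.frame with `metabolite`, `min`, `max`, `error` (NA or a
#'   message for metabolites without a sink reaction).
#' @export
export_flux_ranges <- function(model, med = NULL, exported_metabolites = NULL) {
  model2 <- apply_medium(model, med)
  kinds <- vapply(model2$reactions, `[[`, character(1), "kind")
  sinks <- model2$reactions[kinds == "sink"]
  sink_of <- setNames(vapply(sinks, `[[`, character(1), "id"),
                      vapply(sinks, function(r) names(r$stoich), character(1)))
  if (is.null(exported_metabolites)) exported_metabolites <- names(sink_of)
  out <- data.frame(metabolite = exported_metabolites, min = NA_real_,
                    max = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  have <- exported_metabolites %in% names(sink_of)
  out$error[!have] <- "no sink reaction"
  if (any(have)) {
    rng <- fva(model2, reactions = unname(sink_of[exported_metabolites[have]]),
               fraction_of_optimum = 1)
    out$min[have] <- rng$min
    out$max[have] <- rng$max
  }
  out
}
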