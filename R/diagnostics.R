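#' Parse a chemical formula into element counts
#'
#' Supports element symbols with optional counts and parenthesized groups
#' with multipliers, e.g. `"C6H12O6"`, `"Ca(OH)2"`.
#'
#' @param formula Formula string.
#' @return Named numeric vector of element counts, or `NULL` if the formula
#'   is empty or unparsable.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  pos <- 1L
  n <- nchar(formula)
  peek <- function() if (pos <= n) substr(formula, pos, pos) else ""
  read_count <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", substr(formula, pos, pos))) pos <<- pos + 1L
    if (pos == start) 1 else as.numeric(substr(formula, start, pos - 1L))
  }
  parse_group <- function() {
    counts <- numeric()
    repeat {
      ch <- peek()
      if (ch == "" || ch == ")") break
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parse_group()
        if (peek() != ")") return(NA)
        pos <<- pos + 1L
        mult <- read_count()
        if (is.null(inner) || anyNA(inner)) return(NA)
        inner <- inner * mult
        for (el in names(inner))
          counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + inner[el]
      } else if (grepl("[A-Z]", ch)) {
        el <- ch
        pos <<- pos + 1L
        while (pos <= n && grepl("[a-z]", substr(formula, pos, pos))) {
          el <- paste0(el, substr(formula, pos, pos))
          pos <<- pos + 1L
        }
        cnt <- read_count()
        counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + cnt
      } else {
        return(NA)
      }
    }
    counts
  }
  res <- parse_group()
  if (pos <= n || length(res) == 0 || anyNA(res)) return(NULL)
  res
}

producer_consumer_sets <- function(model) {
  # For each metabolite, which reactions can produce / consume it under the
  # directions allowed by the flux bounds. Boundary reactions count.
  producers <- consumers <- setNames(vector("list", nrow(model$metabolites)),
                                     model$metabolites$id)
  for (r in model$reactions) {
    fwd <- r$ub > 0
    bwd <- r$lb < 0
    for (m in names(r$stoich)) {
      coef <- r$stoich[[m]]
      can_produce <- (coef > 0 && fwd) || (coef < 0 && bwd)
      can_consume <- (coef < 0 && fwd) || (coef > 0 && bwd)
      if (can_produce) producers[[m]] <- c(producers[[m]], r$id)
      if (can_consume) consumers[[m]] <- c(consumers[[m]], r$id)
    }
  }
  list(producers = producers, consumers = consumers)
}

#' Find dead-end metabolites
#'
#' A dead-end metabolite lacks any producing reaction or any consuming
#' reaction under the reaction directions allowed by the flux bounds. A
#' reaction produces a metabolite if it can run in a direction where the
#' metabolite's signed coefficient is positive, and consumes it in the
#' opposite case; exchange and sink reactions count as producers/consumers
#' like any other reaction.
#'
#' @param model A `gem_model`.
#' @return Sorted character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  if (nrow(model$metabolites) == 0) return(character())
  pc <- producer_consumer_sets(model)
  dead <- vapply(model$metabolites$id, function(m) {
    length(pc$producers[[m]]) == 0 || length(pc$consumers[[m]]) == 0
  }, logical(1))
  sort(model$metabolites$id[dead])
}

#' Check mass and charge balance of a reaction
#'
#' Sums coefficient-weighted element counts and charges over all metabolites
#' of the reaction. Exchange, sink, and biomass reactions are exempt (they
#' are net material sources/sinks by design) and report `"exempt"`. Any
#' metabolite with an empty or unparsable formula makes the verdict
#' `"undetermined"`.
#'
#' @param rxn A `gem_reaction`.
#' @param metabolite_table data.frame with columns `id`, `formula`, `charge`
#'   (a model's `$metabolites` works directly).
#' @return List with `verdict` (`"balanced"`, `"unbalanced"`,
#'   `"undetermined"`, `"exempt"`), `element_imbalance` (named numeric of
#'   nonzero net element sums), `charge_imbalance` (numeric or `NA`), and
#'   `reason` for undetermined verdicts.
#' @export
check_mass_charge_balance <- function(rxn, metabolite_table) {
  if (!is.na(rxn$kind) && rxn$kind %in% c("exchange", "sink", "biomass"))
    return(list(verdict = "exempt", element_imbalance = numeric(),
                charge_imbalance = NA_real_, reason = rxn$kind))
  idx <- match(names(rxn$stoich), metabolite_table$id)
  if (anyNA(idx))
    stop("metabolite(s) missing from table: ",
         paste(names(rxn$stoich)[is.na(idx)], collapse = ", "), call. = FALSE)
  elements <- numeric()
  charge <- 0
  charge_known <- TRUE
  for (k in seq_along(idx)) {
    coef <- rxn$stoich[[k]]
    f <- metabolite_table$formula[idx[k]]
    counts <- parse_formula(f)
    if (is.null(counts))
      return(list(verdict = "undetermined", element_imbalance = numeric(),
                  charge_imbalance = NA_real_,
                  reason = paste0("metabolite '", names(rxn$stoich)[k],
                                  "' has empty or unparsable formula")))
    for (el in names(counts))
      elements[el] <- (if (el %in% names(elements)) elements[el] else 0) + coef * counts[el]
    ch <- metabolite_table$charge[idx[k]]
    if (is.na(ch)) charge_known <- FALSE else charge <- charge + coef * ch
  }
  elements <- elements[abs(elements) > 1e-9]
  charge_imb <- if (charge_known) charge else NA_real_
  balanced <- length(elements) == 0 && (!charge_known || abs(charge) < 1e-9)
  list(verdict = if (balanced) "balanced" else "unbalanced",
       element_imbalance = elements, charge_imbalance = charge_imb,
       reason = NA_character_)
}

#' Structural statistics of a model
#'
#' Counts of reactions, metabolites, dead-end metabolites, and genes, plus
#' the fraction of gene-associated-eligible reactions (internal + transport)
#' lacking a GPR rule — the quantities used for structural model comparison.
#'
#' @param model A `gem_model`.
#' @return List (`StatRecord`): `n_reactions`, `n_metabolites`, `n_genes`,
#'   `n_dead_ends`, `frac_reactions_without_gpr`.
#' @export
model_stats <- function(model) {
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  eligible <- model$reactions[!(kinds %in% c("exchange", "sink", "biomass"))]
  frac <- if (length(eligible) == 0) 0 else
    mean(vapply(eligible, function(r) is.null(gpr_parse(r$gpr)), logical(1)))
  list(n_reactions = length(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model$genes),
       n_dead_ends = length(find_dead_end_metabolites(model)),
       frac_reactions_without_gpr = frac)
}
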