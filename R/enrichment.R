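#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`; defined as 1 when both sets are empty.
#'
#' @param a,b Vectors treated as sets.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

model_feature_set <- function(model, feature) {
  switch(feature,
         reactions = reaction_ids(model),
         metabolites = model$metabolites$id,
         dead_ends = find_dead_end_metabolites(model),
         genes = model$genes,
         stop("unknown feature '", feature, "'", call. = FALSE))
}

#' Pairwise Jaccard similarity between tool views of one genome
#'
#' @param models_by_tool Named list of `gem_model` (name = tool label),
#'   sharing the same MAG and a common namespace.
#' @param feature `"reactions"`, `"metabolites"`, `"dead_ends"`, or
#'   `"genes"`.
#' @return Symmetric tool x tool matrix of Jaccard similarities (diagonal 1).
#' @export
pairwise_similarity <- function(models_by_tool,
                                feature = c("reactions", "metabolites",
                                            "dead_ends", "genes")) {
  feature <- match.arg(feature)
  tools <- names(models_by_tool)
  sets <- lapply(models_by_tool, model_feature_set, feature = feature)
  n <- length(tools)
  M <- matrix(1, n, n, dimnames = list(tools, tools))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      M[i, j] <- M[j, i] <- jaccard(sets[[i]], sets[[j]])
  M
}

#' EC subclass of an EC number
#'
#' The first two dot-separated fields, when both are numeric (enzyme class
#' and subclass, e.g. `"2.3"` from `"2.3.1.12"`); `NA` otherwise.
#'
#' @param ec Character vector of EC numbers.
#' @return Character vector of subclasses or `NA`.
#' @export
ec_subclass <- function(ec) {
  vapply(ec, function(x) {
    if (is.na(x)) return(NA_character_)
    f <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(f) >= 2 && grepl("^[0-9]+$", f[1]) && grepl("^[0-9]+$", f[2]))
      paste(f[1], f[2], sep = ".")
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)` (population `N` with `K`
#' successes, sample of size `n`), evaluated through the log-space-stable
#' distribution function.
#'
#' @param k Observed successes in the sample.
#' @param n Sample size.
#' @param K Successes in the population.
#' @param N Population size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("hypergeom_upper_tail: arguments violate 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

rxn_subclasses <- function(rxn) {
  s <- ec_subclass(rxn$ec)
  unique(s[!is.na(s)])
}

#' Hypergeometric enrichment of EC subclasses
#'
#' Tests whether enzyme subclasses (EC numbers to the second digit) are
#' over-represented in a target reaction set relative to a background set.
#' The population is the set of background reactions carrying at least one
#' valid subclass annotation; a reaction with EC numbers in several
#' subclasses counts once per subclass. P-values are Benjamini-Hochberg
#' adjusted; a subclass is called enriched when `adjusted_p < alpha`.
#'
#' @param target List of `gem_reaction` (must be a subset of `background`,
#'   matched by reaction id).
#' @param background List of `gem_reaction`.
#' @param alpha Significance threshold after adjustment (default 0.05).
#' @return data.frame (`enrichment_result`): `subclass`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adjusted_p`, `enriched`.
#' @export
enrich_ec_subclasses <- function(target, background, alpha = 0.05) {
  tid <- vapply(target, `[[`, character(1), "id")
  bid <- vapply(background, `[[`, character(1), "id")
  if (length(setdiff(tid, bid)))
    stop("target reactions not contained in background: ",
         paste(utils::head(setdiff(tid, bid), 5), collapse = ", "), call. = FALSE)
  b_sub <- lapply(background, rxn_subclasses)
  t_sub <- lapply(target, rxn_subclasses)
  b_has <- lengths(b_sub) > 0
  t_has <- lengths(t_sub) > 0
  N <- sum(b_has)
  n <- sum(t_has)
  classes <- sort(unique(unlist(b_sub)))
  if (!length(classes))
    return(data.frame(subclass = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), enriched = logical()))
  K <- vapply(classes, function(s) sum(vapply(b_sub, function(x) s %in% x, logical(1))),
              integer(1))
  k <- vapply(classes, function(s) sum(vapply(t_sub, function(x) s %in% x, logical(1))),
              integer(1))
  p <- mapply(hypergeom_upper_tail, k = k, n = n, K = K, N = N)
  adj <- p.adjust(p, method = "BH")
  data.frame(subclass = classes, k = k, n = rep(n, length(classes)),
             K = K, N = rep(N, length(classes)), p_value = p,
             adjusted_p = adj, enriched = adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nonparametric group comparisons
#'
#' Dispatches the comparison used for structural model statistics:
#' Kruskal-Wallis across three or more groups, two-sided Wilcoxon rank-sum
#' for two groups, or Pearson correlation for paired numeric vectors.
#'
#' @param values_by_group Named list of numeric vectors (each of length >=
#'   2), or for `method = "pearson"` a list of exactly two equal-length
#'   paired vectors.
#' @param method `"auto"` (by number of groups), `"kruskal"`, `"wilcoxon"`,
#'   or `"pearson"`.
#' @return List with `method`, `statistic`, `p_value` (and `estimate` for
#'   Pearson).
#' @export
group_tests <- function(values_by_group,
                        method = c("auto", "kruskal", "wilcoxon", "pearson")) {
  method <- match.arg(method)
  g <- lapply(values_by_group, as.numeric)
  if (any(lengths(g) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (method == "auto") method <- if (length(g) >= 3) "kruskal" else "wilcoxon"
  if (method == "pearson") {
    if (length(g) != 2 || length(g[[1]]) != length(g[[2]]))
      stop("pearson requires two equal-length paired vectors", call. = FALSE)
    ct <- cor.test(g[[1]], g[[2]], method = "pearson")
    return(list(method = "pearson", statistic = unname(ct$statistic),
                estimate = unname(ct$estimate), p_value = ct$p.value))
  }
  if (method == "wilcoxon") {
    if (length(g) != 2) stop("wilcoxon requires exactly 2 groups", call. = FALSE)
    wt <- suppressWarnings(wilcox.test(g[[1]], g[[2]], exact = FALSE, correct = TRUE))
    return(list(method = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value))
  }
  kt <- kruskal.test(g)
  list(method = "kruskal", statistic = unname(kt$statistic), p_value = kt$p.value)
}
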