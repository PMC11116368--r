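#' Gene-protein-reaction (GPR) rules
#'
#' GPR rules are boolean expressions over gene identifiers stating the genetic
#' requirements of a reaction, e.g. `"(g1 and g2) or g3"`. Within `commgem`
#' they are stored as strings on each reaction and parsed on demand into an
#' expression tree: a gene leaf is a character scalar, an inner node is
#' `list(op = "and"|"or", args = list(...))`.
#'
#' @name gpr
#' @keywords internal
NULL

gpr_tokenize <- function(x) {
  x <- gsub("\\(", " ( ", x)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR string into an expression tree
#'
#' Grammar (case-insensitive operators, `or` binds loosest):
#' `expr := term (or term)*`, `term := factor (and factor)*`,
#' `factor := gene | ( expr )`.
#'
#' @param x GPR string; empty or `NA` means "no genetic support".
#' @return A tree (`list(op=, args=)` nodes with character leaves), or `NULL`
#'   for an empty rule.
#' @export
gpr_parse <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", x, "'", call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        stop("GPR parse error: missing ')' in '", x, "'", call. = FALSE)
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("GPR parse error: unexpected token '", t, "' in '", x, "'", call. = FALSE)
    advance()
  }
  tree <- parse_expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in '", x, "'", call. = FALSE)
  tree
}

#' Genes referenced by a GPR
#'
#' @param x GPR string or parsed tree.
#' @return Sorted unique character vector of gene ids (empty for empty rule).
#' @export
gpr_genes <- function(x) {
  if (is.character(x) || is.null(x) || (length(x) == 1 && is.na(x[[1]]) && !is.list(x)))
    x <- gpr_parse(if (is.character(x)) x else NULL)
  walk <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  sort(unique(walk(x)))
}

gpr_eval <- function(tree, active) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(tree %in% active)
  vals <- vapply(tree$args, gpr_eval, logical(1), active = active)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Test logical equivalence of two GPR rules
#'
#' Compares truth tables over the union of referenced genes (up to 20 genes;
#' beyond that, falls back to comparing normalized strings).
#'
#' @param a,b GPR strings.
#' @return Logical scalar.
#' @export
gpr_equivalent <- function(a, b) {
  ta <- gpr_parse(a); tb <- gpr_parse(b)
  genes <- sort(unique(c(gpr_genes(ta), gpr_genes(tb))))
  if (length(genes) == 0) return(is.null(ta) == is.null(tb))
  if (is.null(ta) != is.null(tb)) return(FALSE)
  if (length(genes) > 20L) return(gpr_to_string(ta) == gpr_to_string(tb))
  for (mask in 0:(2^length(genes) - 1L)) {
    active <- genes[bitwAnd(mask, bitwShiftL(1L, seq_along(genes) - 1L)) != 0L]
    if (gpr_eval(ta, active) != gpr_eval(tb, active)) return(FALSE)
  }
  TRUE
}

#' Serialize a GPR tree back to a string
#'
#' @param tree Parsed GPR tree (or `NULL`).
#' @return GPR string (`""` for `NULL`).
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  sep <- paste0(" ", tree$op, " ")
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Combine two GPR rules by OR
#'
#' Used when merging duplicate reactions whose rules differ: the merged
#' reaction is supported if either source rule is satisfied. Empty rules are
#' absorbing (an empty rule means no genetic requirement is recorded, and the
#' combination stays empty-free only if both sides are non-empty).
#'
#' @param a,b GPR strings.
#' @return Combined GPR string.
#' @export
gpr_or <- function(a, b) {
  ea <- is.null(gpr_parse(a)); eb <- is.null(gpr_parse(b))
  if (ea && eb) return("")
  if (ea) return(b)
  if (eb) return(a)
  if (gpr_equivalent(a, b)) return(a)
  wrap <- function(x) {
    t <- gpr_parse(x)
    if (is.list(t) && t$op == "or") gpr_to_string(t) else if (is.list(t)) paste0("(", gpr_to_string(t), ")") else gpr_to_string(t)
  }
  paste(wrap(a), "or", wrap(b))
}
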