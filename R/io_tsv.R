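# TSV triplet dialect: a directory with metabolites.tsv, reactions.tsv and
# gprs.tsv. Reaction stoichiometry is written as a readable equation string,
# e.g. "2 A@c + B@c --> C@c" ("<=>" for reversible, "<--" for backward-only).

format_equation <- function(rxn) {
  fmt_side <- function(v) {
    if (!length(v)) return("")
    paste(vapply(names(v), function(m) {
      a <- abs(v[[m]])
      if (a == 1) m else paste(format(a, digits = 12), m)
    }, character(1)), collapse = " + ")
  }
  arrow <- if (rxn$lb < 0 && rxn$ub > 0) "<=>" else if (rxn$ub > 0) "-->" else "<--"
  paste(fmt_side(rxn$stoich[rxn$stoich < 0]), arrow,
        fmt_side(rxn$stoich[rxn$stoich > 0]))
}

parse_equation <- function(eq, rxn_id = "?") {
  m <- regmatches(eq, regexpr("(-->|<=>|<--)", eq))
  if (length(m) == 0)
    stop("reaction '", rxn_id, "': equation lacks an arrow: '", eq, "'", call. = FALSE)
  sides <- strsplit(eq, "(-->|<=>|<--)")[[1]]
  lhs <- trimws(sides[1])
  rhs <- if (length(sides) > 1) trimws(sides[2]) else ""
  parse_side <- function(s, sign) {
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "\\s\\+\\s")[[1]])
    out <- numeric()
    for (t in terms) {
      parts <- strsplit(t, "\\s+")[[1]]
      if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("reaction '", rxn_id, "': bad coefficient in term '", t, "'", call. = FALSE)
        out[parts[2]] <- sign * coef
      } else if (length(parts) == 1) {
        out[parts[1]] <- sign
      } else {
        stop("reaction '", rxn_id, "': malformed term '", t, "'", call. = FALSE)
      }
    }
    out
  }
  st <- c(parse_side(lhs, -1), parse_side(rhs, 1))
  # a metabolite on both sides nets out
  tapply_sum <- tapply(st, names(st), sum)
  setNames(as.numeric(tapply_sum), names(tapply_sum))
}

write_tsv_triplet <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mets <- model$metabolites
  write.table(mets, file.path(path, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  rx <- do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(id = r$id, equation = format_equation(r), lb = r$lb, ub = r$ub,
               ec = paste(r$ec, collapse = ";"), kind = r$kind,
               source_tools = paste(r$source_tools, collapse = ";"),
               objective = as.integer(identical(r$id, model$objective)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rx)) rx <- data.frame(id = character(), equation = character(),
                                    lb = numeric(), ub = numeric(), ec = character(),
                                    kind = character(), source_tools = character(),
                                    objective = integer())
  write.table(rx, file.path(path, "reactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  gp <- do.call(rbind, lapply(model$reactions, function(r)
    if (nzchar(r$gpr)) data.frame(reaction_id = r$id, gpr = r$gpr) else NULL))
  if (is.null(gp)) gp <- data.frame(reaction_id = character(), gpr = character())
  write.table(gp, file.path(path, "gprs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  # model-level metadata
  writeLines(c("key\tvalue",
               paste0("id\t", model$id),
               paste0("tool\t", model$tool)),
             file.path(path, "model.tsv"))
  invisible(path)
}

read_tsv_triplet <- function(path, tool = NA_character_) {
  need <- file.path(path, c("metabolites.tsv", "reactions.tsv", "gprs.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("TSV triplet incomplete; missing: ", paste(missing, collapse = ", "), call. = FALSE)
  mets <- read.delim(need[1], colClasses = c(charge = "integer"), na.strings = "")
  if (nrow(mets) == 0) mets <- empty_metabolites()
  for (cc in c("id", "name", "formula", "compartment"))
    mets[[cc]] <- as.character(mets[[cc]])
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$formula[is.na(mets$formula)] <- ""
  rx <- read.delim(need[2], na.strings = "")
  gp <- read.delim(need[3], na.strings = "")
  meta_file <- file.path(path, "model.tsv")
  model_id <- basename(path); model_tool <- tool
  if (file.exists(meta_file)) {
    meta <- read.delim(meta_file)
    kv <- setNames(meta$value, meta$key)
    if ("id" %in% names(kv)) model_id <- kv[["id"]]
    if (is.na(tool) && "tool" %in% names(kv)) model_tool <- kv[["tool"]]
  }
  if (is.na(model_tool)) model_tool <- "unknown"
  gpr_map <- setNames(as.character(gp$gpr), gp$reaction_id)
  objective <- NA_character_
  reactions <- list()
  for (i in seq_len(nrow(rx))) {
    row <- rx[i, ]
    ec <- if (is.na(row$ec)) character() else strsplit(row$ec, ";")[[1]]
    src <- if (is.null(row$source_tools) || is.na(row$source_tools)) character() else
      strsplit(row$source_tools, ";")[[1]]
    gpr <- if (row$id %in% names(gpr_map)) gpr_map[[row$id]] else ""
    if (!is.null(row$objective) && !is.na(row$objective) && row$objective == 1)
      objective <- row$id
    reactions[[row$id]] <- reaction(
      row$id, parse_equation(row$equation, row$id), lb = row$lb, ub = row$ub,
      gpr = gpr, ec = ec,
      kind = if (is.null(row$kind) || is.na(row$kind)) NA_character_ else row$kind,
      source_tools = src)
  }
  gem_model(model_id, tool = model_tool, metabolites = mets,
            reactions = reactions, objective = objective)
}

#' Read a genome-scale model
#'
#' @param path File path (SBML) or directory (TSV triplet).
#' @param dialect `"sbml-fbc"` (SBML Level 3 + fbc) or `"tsv-triplet"`
#'   (a directory holding `metabolites.tsv`, `reactions.tsv`, `gprs.tsv`).
#' @param tool Override the reconstruction-tool label recorded in the file.
#' @return A validated `gem_model`.
#' @export
read_model <- function(path, dialect = c("sbml-fbc", "tsv-triplet"),
                       tool = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("no such file or directory: ", path, call. = FALSE)
  switch(dialect,
         "sbml-fbc" = read_sbml(path, tool = tool),
         "tsv-triplet" = read_tsv_triplet(path, tool = tool))
}

#' Write a genome-scale model
#'
#' The inverse of [read_model()]: `read_model(write_model(m))` reproduces the
#' structural digest of `m` (ids, stoichiometry, bounds, GPR semantics).
#'
#' @param model A `gem_model`.
#' @param path Output file (SBML) or directory (TSV triplet).
#' @param dialect See [read_model()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("sbml-fbc", "tsv-triplet")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "sbml-fbc" = write_sbml(model, path),
         "tsv-triplet" = write_tsv_triplet(model, path))
}
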