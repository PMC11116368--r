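SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds allow only [A-Za-z0-9_]; namespace-qualified ids like "MNXM2@c"
# are escaped with the usual __<ascii>__ convention so round-trips are
# lossless.
sid_encode <- function(x, prefix = "") {
  enc <- vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch) {
      if (grepl("[A-Za-z0-9_]", ch)) ch else paste0("__", utf8ToInt(ch), "__")
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  paste0(prefix, enc)
}

sid_decode <- function(x, prefix = "") {
  if (nzchar(prefix)) x <- sub(paste0("^", prefix), "", x)
  vapply(x, function(s) {
    while (grepl("__([0-9]+)__", s)) {
      m <- regmatches(s, regexpr("__([0-9]+)__", s))[[1]]
      code <- as.integer(gsub("_", "", m))
      s <- sub("__([0-9]+)__", intToUtf8(code), s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

gpr_to_fbc <- function(tree, indent = "        ") {
  if (is.null(tree)) return(character())
  render <- function(node, ind) {
    if (is.character(node))
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                     ind, sid_encode(node, "G_")))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    inner <- unlist(lapply(node$args, render, ind = paste0(ind, "  ")))
    c(sprintf("%s<%s>", ind, tag), inner, sprintf("%s</%s>", ind, tag))
  }
  c(sprintf("%s<fbc:geneProductAssociation>", indent),
    render(tree, paste0(indent, "  ")),
    sprintf("%s</fbc:geneProductAssociation>", indent))
}

write_sbml <- function(model, path) {
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- sprintf(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
      SBML_CORE_NS, SBML_FBC_NS)
  add('  <model id="%s" name="%s" fbc:strict="true">', sid_encode(model$id),
      xml_escape(paste0(model$id, " [", model$tool, "]")))
  comps <- sort(unique(model$metabolites$compartment))
  if (length(comps)) {
    add('    <listOfCompartments>')
    for (cc in comps)
      add('      <compartment id="%s" constant="true"/>', sid_encode(cc))
    add('    </listOfCompartments>')
  }
  if (nrow(model$metabolites)) {
    add('    <listOfSpecies>')
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      extra <- ""
      if (!is.na(m$charge)) extra <- sprintf(' fbc:charge="%d"', m$charge)
      if (nzchar(m$formula) && !is.na(m$formula))
        extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', xml_escape(m$formula)))
      add(paste0('      <species id="%s" name="%s" compartment="%s"',
                 ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                 ' constant="false"%s/>'),
          sid_encode(m$id, "M_"), xml_escape(m$name), sid_encode(m$compartment), extra)
    }
    add('    </listOfSpecies>')
  }
  if (length(model$reactions)) {
    add('    <listOfParameters>')
    for (r in model$reactions) {
      add('      <parameter id="%s_lb" value="%.10g" constant="true"/>', sid_encode(r$id, "R_"), r$lb)
      add('      <parameter id="%s_ub" value="%.10g" constant="true"/>', sid_encode(r$id, "R_"), r$ub)
    }
    add('    </listOfParameters>')
  }
  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes)
      add('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
          sid_encode(g, "G_"), xml_escape(g))
    add('    </fbc:listOfGeneProducts>')
  }
  if (!is.na(model$objective)) {
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    add('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
        sid_encode(model$objective, "R_"))
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  add('    <listOfReactions>')
  for (r in model$reactions) {
    rid <- sid_encode(r$id, "R_")
    add(paste0('      <reaction id="%s" reversible="%s" fast="false"',
               ' fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">'),
        rid, if (r$lb < 0) "true" else "false", rid, rid)
    if (length(r$source_tools))
      add(paste0('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
                 '<p>source_tools: %s</p></body></notes>'),
          xml_escape(paste(r$source_tools, collapse = ",")))
    if (length(r$ec)) {
      add('        <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">')
      add('          <rdf:Description rdf:about="#%s"><bqbiol:is><rdf:Bag>', rid)
      for (ec in r$ec)
        add('            <rdf:li rdf:resource="https://identifiers.org/ec-code/%s"/>', ec)
      add('          </rdf:Bag></bqbiol:is></rdf:Description>')
      add('        </rdf:RDF></annotation>')
    }
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      add('        <listOfReactants>')
      for (m in names(subs))
        add('          <speciesReference species="%s" stoichiometry="%.10g" constant="true"/>',
            sid_encode(m, "M_"), -subs[[m]])
      add('        </listOfReactants>')
    }
    if (length(prods)) {
      add('        <listOfProducts>')
      for (m in names(prods))
        add('          <speciesReference species="%s" stoichiometry="%.10g" constant="true"/>',
            sid_encode(m, "M_"), prods[[m]])
      add('        </listOfProducts>')
    }
    gl <- gpr_to_fbc(gpr_parse(r$gpr))
    if (length(gl)) L <- c(L, gl)
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  writeLines(unlist(L), path)
  invisible(path)
}

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    attrs <- xml2::xml_attrs(node)
    gid <- attrs[grepl("(^|:)geneProduct$", names(attrs))][1]
    return(sid_decode(unname(gid), "G_"))
  }
  kids <- xml2::xml_children(node)
  if (nm %in% c("and", "or"))
    return(list(op = nm, args = lapply(kids, fbc_to_gpr)))
  if (length(kids) == 1) return(fbc_to_gpr(kids[[1]]))
  stop("unsupported geneProductAssociation element: ", nm, call. = FALSE)
}

attr_any <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hit <- attrs[names(attrs) == name | grepl(paste0("(^|:)", name, "$"), names(attrs))]
  if (length(hit)) unname(hit[1]) else NA_character_
}

read_sbml <- function(path, tool = NA_character_) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e), call. = FALSE))
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing"))
    stop("SBML parse failure: no <model> element in '", path, "'", call. = FALSE)
  model_id <- sid_decode(xml2::xml_attr(model_node, "id"))
  if (is.na(tool)) {
    nm <- xml2::xml_attr(model_node, "name")
    tool <- if (!is.na(nm) && grepl("\\[.*\\]$", nm)) sub("^.*\\[(.*)\\]$", "\\1", nm) else "unknown"
  }

  sp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='species']")
  mets <- empty_metabolites()
  for (sp in sp_nodes) {
    id <- sid_decode(xml2::xml_attr(sp, "id"), "M_")
    charge <- attr_any(sp, "charge")
    formula <- attr_any(sp, "chemicalFormula")
    comp <- sid_decode(xml2::xml_attr(sp, "compartment"))
    mets <- rbind(mets, metabolite(
      id, name = xml2::xml_attr(sp, "name"),
      formula = if (is.na(formula)) "" else formula,
      charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
      compartment = comp))
  }

  params <- xml2::xml_find_all(model_node, ".//*[local-name()='parameter']")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  obj_node <- xml2::xml_find_first(model_node, ".//*[local-name()='fluxObjective']")
  objective <- if (inherits(obj_node, "xml_missing")) NA_character_ else
    sid_decode(attr_any(obj_node, "reaction"), "R_")

  rx_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='reaction']")
  reactions <- list()
  for (rx in rx_nodes) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- sid_decode(rid_raw, "R_")
    get_refs <- function(listname, sign) {
      refs <- xml2::xml_find_all(rx, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", listname))
      if (length(refs) == 0) return(numeric())
      setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               sid_decode(xml2::xml_attr(refs, "species"), "M_"))
    }
    stoich <- c(get_refs("listOfReactants", -1), get_refs("listOfProducts", 1))
    lb_ref <- attr_any(rx, "lowerFluxBound")
    ub_ref <- attr_any(rx, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -DEFAULT_BOUND
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else DEFAULT_BOUND
    gpa <- xml2::xml_find_first(rx, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      gpr_to_string(fbc_to_gpr(xml2::xml_children(gpa)[[1]]))
    ec_nodes <- xml2::xml_find_all(rx, ".//*[local-name()='li']")
    ec <- character()
    if (length(ec_nodes)) {
      res <- unlist(lapply(ec_nodes, function(nd) attr_any(nd, "resource")))
      ec <- sub("^.*ec-code/", "", res[grepl("ec-code/", res)])
    }
    notes <- xml2::xml_find_first(rx, ".//*[local-name()='notes']")
    src <- character()
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      if (grepl("source_tools:", txt))
        src <- strsplit(trimws(sub("^.*source_tools:", "", txt)), ",")[[1]]
    }
    reactions[[rid]] <- reaction(rid, stoich, lb = lb, ub = ub, gpr = gpr,
                                 ec = ec, source_tools = trimws(src))
  }
  gp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='geneProduct']")
  genes <- if (length(gp_nodes))
    sid_decode(vapply(gp_nodes, function(g) attr_any(g, "id"), character(1)), "G_")
  else NULL
  gem_model(model_id, tool = tool, metabolites = mets, reactions = reactions,
            genes = genes, objective = objective)
}
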