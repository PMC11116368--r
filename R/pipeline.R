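# End-to-end orchestration: translate -> merge -> gap-fill -> flux analysis
# -> comparison/enrichment -> exchange analysis, driven by a single YAML
# config, with deterministic TSV/JSON outputs and a machine-readable
# manifest.

#' Read / write a medium TSV (columns: metabolite, max_uptake)
#' @param path TSV path.
#' @return A `gem_medium`.
#' @export
read_medium <- function(path) {
  t <- read.delim(path, comment.char = "#")
  medium(setNames(t$max_uptake, t$metabolite))
}

#' @rdname read_medium
#' @param med A `gem_medium`.
#' @export
write_medium <- function(med, path) {
  df <- data.frame(metabolite = names(med$uptake), max_uptake = unname(med$uptake))
  df <- df[order(df$metabolite), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_abundance <- function(path) {
  t <- read.delim(path, comment.char = "#")
  setNames(t$abundance, t$mag)
}

read_biomass_spec <- function(path) {
  t <- read.delim(path, comment.char = "#")
  setNames(t$coefficient, t$metabolite)
}

#' Write a synthetic community fixture to disk
#'
#' Materializes a [generate_community()] fixture as a self-contained
#' directory: per-tool SBML models, namespace tables, media, abundance and
#' biomass TSVs, the universal database, a JSON manifest with the seed and
#' parameters, and a ready-to-run pipeline `config.yaml`.
#'
#' @param fixture Result of [generate_community()].
#' @param dir Output directory (created).
#' @param order Gap-fill processing order recorded in the config.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir, order = "descending") {
  for (d in c("", "models", "namespace", "media", "db", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  tools_used <- names(fixture$members[[1]]$views)
  for (tool in tools_used)
    dir.create(file.path(dir, "models", tool), showWarnings = FALSE)
  for (mag in names(fixture$members)) {
    mem <- fixture$members[[mag]]
    write_model(mem$truth, file.path(dir, "truth", paste0(mag, ".sbml")))
    for (tool in tools_used) {
      write_model(mem$views[[tool]],
                  file.path(dir, "models", tool, paste0(mag, ".sbml")))
      tb <- mem$tables[[tool]]
      write.table(tb$met, file.path(dir, "namespace", paste0(tool, "_", mag, "_met.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(tb$rxn, file.path(dir, "namespace", paste0(tool, "_", mag, "_rxn.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  ab <- data.frame(mag = names(fixture$abundance),
                   abundance = unname(fixture$abundance))
  write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bs <- data.frame(metabolite = names(fixture$biomass_spec),
                   coefficient = unname(fixture$biomass_spec))
  write.table(bs, file.path(dir, "biomass.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_medium(fixture$media$rich, file.path(dir, "media", "lb.tsv"))
  write_medium(fixture$media$minimal, file.path(dir, "media", "m9.tsv"))
  write_model(fixture$universal_db, file.path(dir, "db", "universal.sbml"))
  jsonlite::write_json(list(seed = fixture$seed,
                            n_members = length(fixture$members),
                            tools = tools_used),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  config <- list(run_dir = "run", order = order, alpha = 0.05, epsilon = 0.05,
                 tol = 1e-6, uptake_rate = 10, tools = tools_used,
                 models_dir = "models", namespace_dir = "namespace",
                 abundance = "abundance.tsv", biomass = "biomass.tsv",
                 universal_db = "db/universal.sbml",
                 media = list(init = "media/lb.tsv", base = "media/m9.tsv"))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$base_dir <- base_dir
  }
  if (is.null(config$base_dir)) config$base_dir <- "."
  defaults <- list(order = "descending", alpha = 0.05, epsilon = 0.05,
                   tol = 1e-6, uptake_rate = 10)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  required <- c("run_dir", "tools", "models_dir", "namespace_dir", "abundance",
                "biomass", "universal_db", "media")
  missing <- required[vapply(required, function(k) is.null(config[[k]]), logical(1))]
  if (length(missing))
    stop("pipeline config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(config$media$init) || is.null(config$media$base))
    stop("pipeline config is missing required field(s): media.init and/or media.base",
         call. = FALSE)
  rel <- function(p) if (grepl("^/", p)) p else file.path(config$base_dir, p)
  for (k in c("models_dir", "namespace_dir", "abundance", "biomass", "universal_db"))
    config[[k]] <- rel(config[[k]])
  config$media$init <- rel(config$media$init)
  config$media$base <- rel(config$media$base)
  for (p in c(config$abundance, config$biomass, config$universal_db,
              config$media$init, config$media$base, config$models_dir,
              config$namespace_dir))
    if (!file.exists(p)) stop("pipeline input not found: ", p, call. = FALSE)
  config
}

write_tsv_out <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Stages, mirroring the analysis order of a community-model comparison:
#' (1) read per-tool draft models and translate them to the common
#' namespace; (2) merge the tool views of each MAG into a consensus model;
#' (3) strip boundary/biomass reactions, insert the universal biomass
#' reaction, and run abundance-ordered iterative community gap-filling for
#' every approach (each tool plus consensus); (4) abundance correlations;
#' (5) structural statistics and pairwise Jaccard similarities;
#' (6) FVA-based blocked-reaction detection and EC-subclass enrichment on
#' shared and unblocked-shared reactions; (7) imported/exported/exchanged
#' metabolite summaries. All outputs are plain TSV/JSON under the run
#' directory; identical config and inputs give byte-identical summary
#' tables.
#'
#' @param config Path to a YAML config file (as written by
#'   [write_fixture()]) or an equivalent named list with `base_dir`.
#' @param run_dir Optional override of the config's run directory.
#' @return Invisibly, a list with the run directory and key in-memory
#'   results.
#' @export
run_pipeline <- function(config, run_dir = NULL) {
  config <- load_pipeline_config(config)
  if (is.null(run_dir))
    run_dir <- if (grepl("^/", config$run_dir)) config$run_dir
               else file.path(config$base_dir, config$run_dir)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(run_dir, "log.txt")
  logln <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ...,
                             "\n", file = log_file, append = TRUE)
  logln("pipeline start; order =", config$order)

  abundance <- read_abundance(config$abundance)
  biomass_spec <- read_biomass_spec(config$biomass)
  init_medium <- read_medium(config$media$init)
  base_medium <- read_medium(config$media$base)
  universal_db <- read_model(config$universal_db)
  tools_used <- unlist(config$tools)

  # stage 1: load + translate
  mags <- sort(names(abundance))
  translated <- list()
  cov_reports <- list()
  for (tool in tools_used) {
    for (mag in mags) {
      path <- file.path(config$models_dir, tool, paste0(mag, ".sbml"))
      if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
      m <- read_model(path, tool = tool)
      met_tab <- file.path(config$namespace_dir, paste0(tool, "_", mag, "_met.tsv"))
      rxn_tab <- file.path(config$namespace_dir, paste0(tool, "_", mag, "_rxn.tsv"))
      map <- load_reference_tables(met_tab[file.exists(met_tab)],
                                   rxn_tab[file.exists(rxn_tab)])
      tr <- translate_model(m, map)
      translated[[tool]][[mag]] <- tr$model
      cov_reports[[paste(tool, mag, sep = ":")]] <- tr$report
    }
  }
  write_coverage_report(cov_reports, file.path(run_dir, "translation_coverage.tsv"))
  logln("translated", length(cov_reports), "models")

  # stage 2: consensus merge per MAG
  consensus <- list()
  merge_rows <- list()
  dir.create(file.path(run_dir, "consensus"), showWarnings = FALSE)
  for (mag in mags) {
    views <- lapply(tools_used, function(t)
      strip_boundary_and_biomass(translated[[t]][[mag]]))
    mm <- merge_models(views, id = mag)
    consensus[[mag]] <- mm$model
    write_model(mm$model, file.path(run_dir, "consensus", paste0(mag, ".sbml")))
    rep <- mm$report$per_view
    rep$mag <- mag
    merge_rows[[mag]] <- rep
  }
  write_tsv_out(do.call(rbind, merge_rows), file.path(run_dir, "merge_report.tsv"))
  logln("merged", length(mags), "consensus models")

  # stage 3: community gap-filling per approach
  approaches <- c(tools_used, "consensus")
  prepared <- list()
  for (ap in approaches) {
    prepared[[ap]] <- lapply(setNames(mags, mags), function(mag) {
      m <- if (ap == "consensus") consensus[[mag]]
           else strip_boundary_and_biomass(translated[[ap]][[mag]])
      add_universal_biomass(m, biomass_spec)
    })
  }
  gap_rows <- list()
  gap_results <- list()
  for (ap in approaches) {
    comm <- community(prepared[[ap]], abundance, order = config$order)
    gf <- iterative_community_gapfill(comm, init_medium, base_medium,
                                      universal_db, epsilon = config$epsilon,
                                      tol = config$tol,
                                      uptake_rate = config$uptake_rate)
    gap_results[[ap]] <- gf
    for (mag in names(gf$results)) {
      r <- gf$results[[mag]]
      gap_rows[[paste(ap, mag)]] <- data.frame(
        approach = ap, mag = mag, status = r$status,
        n_added = length(r$added_reactions),
        n_imported = length(r$imported), n_exported = length(r$exported),
        growth = round(r$growth, 6))
    }
    logln("gap-filled approach", ap)
  }
  write_tsv_out(do.call(rbind, gap_rows[order(names(gap_rows))]),
                file.path(run_dir, "gapfill_summary.tsv"))
  jsonlite::write_json(
    lapply(gap_results, function(gf) lapply(gf$results, function(r)
      list(mag_id = r$mag_id, status = r$status,
           added_reactions = r$added_reactions, imported = r$imported,
           exported = r$exported, growth = r$growth))),
    file.path(run_dir, "gapfill_results.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)

  # stage 4: abundance correlations
  cor_rows <- list()
  for (ap in approaches) for (metric in c("added", "imported", "exported")) {
    res <- tryCatch(correlate_abundance_with_gapfill(gap_results[[ap]]$results,
                                                     abundance, metric),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = length(mags)))
    cor_rows[[paste(ap, metric)]] <- data.frame(
      approach = ap, metric = metric, r = round(res$r, 6), p = round(res$p, 6),
      n = res$n)
  }
  write_tsv_out(do.call(rbind, cor_rows[order(names(cor_rows))]),
                file.path(run_dir, "abundance_correlation.tsv"))

  # stage 5: structural stats + similarity (on stripped draft content)
  stripped <- list()
  for (ap in approaches)
    stripped[[ap]] <- lapply(setNames(mags, mags), function(mag)
      if (ap == "consensus") consensus[[mag]]
      else strip_boundary_and_biomass(translated[[ap]][[mag]]))
  stat_rows <- list()
  for (ap in approaches) for (mag in mags) {
    s <- model_stats(stripped[[ap]][[mag]])
    stat_rows[[paste(ap, mag)]] <- data.frame(
      approach = ap, mag = mag, n_reactions = s$n_reactions,
      n_metabolites = s$n_metabolites, n_genes = s$n_genes,
      n_dead_ends = s$n_dead_ends,
      frac_reactions_without_gpr = round(s$frac_reactions_without_gpr, 6))
  }
  write_tsv_out(do.call(rbind, stat_rows[order(names(stat_rows))]),
                file.path(run_dir, "model_stats.tsv"))
  for (feature in c("reactions", "metabolites", "dead_ends", "genes")) {
    mats <- lapply(mags, function(mag)
      pairwise_similarity(lapply(setNames(approaches, approaches),
                                 function(ap) stripped[[ap]][[mag]]), feature))
    avg <- round(Reduce(`+`, mats) / length(mats), 6)
    df <- data.frame(approach = rownames(avg), avg, check.names = FALSE)
    write_tsv_out(df, file.path(run_dir, paste0("similarity_", feature, ".tsv")))
  }
  logln("stats and similarity written")

  # stage 6: blocked reactions + EC-subclass enrichment
  blocked_rows <- list()
  unblocked_by_ap <- list()
  for (ap in approaches) {
    unblocked <- character()
    for (mag in mags) {
      r <- gap_results[[ap]]$results[[mag]]
      if (r$status != "ok") next
      bl <- blocked_reactions(r$model, tol = config$tol)
      rids <- reaction_ids(r$model)
      blocked_rows[[paste(ap, mag)]] <- data.frame(
        approach = ap, mag = mag, reaction = sort(rids),
        blocked = sort(rids) %in% bl)
      unblocked <- union(unblocked, setdiff(rids, bl))
    }
    unblocked_by_ap[[ap]] <- unblocked
  }
  write_tsv_out(do.call(rbind, blocked_rows[order(names(blocked_rows))]),
                file.path(run_dir, "blocked_reactions.tsv"))

  rxn_pool <- function(ap) {
    out <- list()
    for (mag in mags)
      for (r in stripped[[ap]][[mag]]$reactions)
        if (is.null(out[[r$id]])) out[[r$id]] <- r
    out
  }
  pools <- lapply(setNames(approaches, approaches), rxn_pool)
  enr_rows <- list()
  for (i in seq_along(approaches)) for (j in seq_along(approaches)) {
    if (i >= j) next
    a <- approaches[i]; b <- approaches[j]
    shared_ids <- intersect(names(pools[[a]]), names(pools[[b]]))
    bg <- pools[[a]]
    for (id in setdiff(names(pools[[b]]), names(bg))) bg[[id]] <- pools[[b]][[id]]
    variants <- list(shared = shared_ids,
                     unblocked_shared = intersect(shared_ids,
                                                  intersect(unblocked_by_ap[[a]],
                                                            unblocked_by_ap[[b]])))
    for (vn in names(variants)) {
      tgt <- bg[variants[[vn]]]
      if (!length(tgt)) next
      et <- enrich_ec_subclasses(unname(tgt), unname(bg), alpha = config$alpha)
      if (!nrow(et)) next
      et$pair <- paste(a, b, sep = "~"); et$variant <- vn
      enr_rows[[paste(a, b, vn)]] <- et[, c("pair", "variant", "subclass", "k",
                                            "n", "K", "N", "p_value",
                                            "adjusted_p", "enriched")]
    }
  }
  if (length(enr_rows)) {
    enr <- do.call(rbind, enr_rows[order(names(enr_rows))])
    enr$p_value <- signif(enr$p_value, 6); enr$adjusted_p <- signif(enr$adjusted_p, 6)
    rownames(enr) <- NULL
    write_tsv_out(enr, file.path(run_dir, "enrichment.tsv"))
  }
  logln("enrichment written")

  # stage 7: exchange analysis on gap-filled models
  comm_models <- lapply(setNames(approaches, approaches), function(ap) {
    ok <- Filter(function(r) r$status == "ok", gap_results[[ap]]$results)
    lapply(ok, `[[`, "model")
  })
  ex <- exchange_summary(comm_models)
  sm <- ex$summary
  for (cc in c("mean_imported", "sd_imported", "mean_exported", "sd_exported"))
    sm[[cc]] <- round(sm[[cc]], 6)
  write_tsv_out(sm, file.path(run_dir, "exchange_summary.tsv"))
  jm <- round(ex$exchanged_jaccard, 6)
  write_tsv_out(data.frame(approach = rownames(jm), jm, check.names = FALSE),
                file.path(run_dir, "exchanged_jaccard.tsv"))
  all_exch <- sort(unique(unlist(ex$exchanged_sets)))
  if (length(all_exch)) {
    mem <- data.frame(metabolite = all_exch)
    for (ap in approaches)
      mem[[ap]] <- as.integer(all_exch %in% ex$exchanged_sets[[ap]])
    write_tsv_out(mem, file.path(run_dir, "exchanged_membership.tsv"))
  }
  logln("exchange analysis written")

  manifest <- list(
    package = "commgem",
    version = tryCatch(as.character(utils::packageVersion("commgem")),
                       error = function(e) "dev"),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    order = config$order, alpha = config$alpha, epsilon = config$epsilon,
    tol = config$tol, uptake_rate = config$uptake_rate,
    tools = tools_used, mags = mags,
    input_md5 = as.list(tools::md5sum(c(config$abundance, config$biomass,
                                        config$universal_db, config$media$init,
                                        config$media$base))))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logln("pipeline done")
  invisible(list(run_dir = run_dir, gap_results = gap_results,
                 consensus = consensus, exchange = ex))
}

#' Run the pipeline in both abundance orders
#'
#' Executes [run_pipeline()] with descending and ascending abundance order
#' into `desc/` and `asc/` subdirectories of the run directory and writes a
#' paired comparison: per-approach abundance correlations for each order and
#' per-member added-reaction counts side by side.
#'
#' @inheritParams run_pipeline
#' @return Invisibly, a list with both run results and the comparison
#'   table.
#' @export
compare_orders <- function(config, run_dir = NULL) {
  config <- load_pipeline_config(config)
  if (is.null(run_dir))
    run_dir <- if (grepl("^/", config$run_dir)) config$run_dir
               else file.path(config$base_dir, config$run_dir)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  for (ord in c("descending", "ascending")) {
    cfg <- config
    cfg$order <- ord
    runs[[ord]] <- run_pipeline(cfg, run_dir = file.path(run_dir, substr(ord, 1, 4)))
  }
  rows <- list()
  for (ord in names(runs)) {
    tab <- read.delim(file.path(runs[[ord]]$run_dir, "abundance_correlation.tsv"))
    tab$order <- ord
    rows[[ord]] <- tab
  }
  corr <- do.call(rbind, rows)
  rownames(corr) <- NULL
  write_tsv_out(corr[order(corr$approach, corr$metric, corr$order), ],
                file.path(run_dir, "order_correlations.tsv"))
  added <- list()
  for (ord in names(runs)) {
    tab <- read.delim(file.path(runs[[ord]]$run_dir, "gapfill_summary.tsv"))
    added[[ord]] <- setNames(tab$n_added, paste(tab$approach, tab$mag))
  }
  keys <- sort(union(names(added$descending), names(added$ascending)))
  cmp <- data.frame(approach_mag = keys,
                    added_descending = added$descending[keys],
                    added_ascending = added$ascending[keys], row.names = NULL)
  write_tsv_out(cmp, file.path(run_dir, "order_added_reactions.tsv"))
  invisible(list(runs = runs, correlations = corr, added = cmp))
}
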