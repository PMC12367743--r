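# End-to-end orchestration: simulate (or load) a cohort, then run
# DEG calling -> clustering -> overrepresentation -> set-variation scoring ->
# interferon signature scoring -> clinical statistics, writing a directory of
# TSVs plus a machine-readable JSON manifest. Deterministic given
# (config, seed): every output byte is a function of the two.

#' Default pipeline configuration
#'
#' @param seed integer seed (drives the simulation when no input paths are
#'   given).
#' @return nested list of stage parameters; see the fields in the source.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    inputs = NULL,  # or list(expression=, metadata=, gmt=, signs=, clinical=, survival=)
    deg = list(fc_threshold = 1, p_threshold = 0.05, expression_floor = 1),
    clustering = list(distance = "euclidean", linkage = "average", k = 2),
    enrichment = list(tau = 0.25, gsva_set = "bcell"),
    signature = list(sets = c("typeI", "typeII", "typeIII"),
                     denominator = "n-1"),
    clinical = list(group = "arm"))
}

#' Read / write a pipeline configuration (JSON)
#'
#' JSON is the one supported config dialect; configs round-trip losslessly.
#'
#' @param path JSON file path.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config(cfg$seed %||% 1L)
  out <- utils::modifyList(base, cfg)
  if (!length(out$inputs)) out["inputs"] <- list(NULL)  # JSON has no NULL slot
  out
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stage order: cohort (simulate or load) -> per-patient fold changes & DEG
#' calling -> patient clustering vs outcome -> overrepresentation of down-
#' and upregulated DEGs -> per-sample set-variation scores with an arm
#' comparison -> interferon signature scores, dynamics and the genewise
#' outcome comparison -> clinical baseline report. All tables are written
#' under `outdir` together with `manifest.json` (config hash, seed, stage
#' counts, package version).
#'
#' @param config configuration list (see [default_pipeline_config()]); when
#'   `config$inputs` is NULL a synthetic cohort is generated from
#'   [default_study_design()] at `config$seed`.
#' @param outdir output directory.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[mda5tx] ", ...)

  cohort <- run_stage("cohort", {
    if (is.null(config$inputs)) {
      generate_cohort(default_study_design(seed = config$seed))
    } else {
      io <- config$inputs
      expr <- read_expression(io$expression)
      list(expression = expr,
           metadata = read_metadata(io$metadata, expr),
           gene_sets = read_gmt(io$gmt, io$signs),
           clinical = if (!is.null(io$clinical)) read_clinical(io$clinical),
           survival = if (!is.null(io$survival)) read_survival(io$survival))
    }
  })
  expr <- cohort$expression
  meta <- cohort$metadata
  log_msg("cohort: ", nrow(expr), " genes, ", ncol(expr), " samples")

  degs <- run_stage("deg", {
    kept <- filter_low_expression(expr, config$deg$expression_floor)
    fc <- per_patient_log2fc(kept, meta)
    list(fc = fc,
         table = call_degs(fc, fc_threshold = config$deg$fc_threshold,
                           p_threshold = config$deg$p_threshold),
         universe = rownames(kept))
  })
  deg_ids <- degs$table$gene_id[degs$table$is_deg]
  log_msg("deg: ", length(degs$universe), " genes tested, ",
          length(deg_ids), " DEGs")
  utils::write.table(degs$table, file.path(outdir, "deg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  clust <- run_stage("clustering", {
    if (length(deg_ids) < 1) {
      log_msg("clustering skipped: no DEGs")
      NULL
    } else {
      dend <- cluster_patients(degs$fc, deg_ids,
                               distance = config$clustering$distance,
                               linkage = config$clustering$linkage)
      conc <- outcome_concordance(dend, meta, k = config$clustering$k)
      writeLines(as_newick(dend), file.path(outdir, "dendrogram.newick"))
      utils::write.table(
        data.frame(patient_id = names(conc$clusters),
                   cluster = unname(conc$clusters)),
        file.path(outdir, "clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(dendrogram = dend, concordance = conc)
    }
  })

  enr <- run_stage("enrichment", {
    res <- list()
    for (dirn in c("down", "up")) {
      genes <- deg_gene_list(degs$table, dirn)
      tab <- if (length(genes))
        overrepresentation(genes, cohort$gene_sets, degs$universe)
      else
        suppressWarnings(overrepresentation(character(0), cohort$gene_sets,
                                            degs$universe))
      utils::write.table(tab,
                         file.path(outdir, paste0("enrichment_", dirn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res[[dirn]] <- tab
    }
    res$gsva <- set_variation_scores(expr, meta, cohort$gene_sets,
                                     tau = config$enrichment$tau)
    utils::write.table(res$gsva, file.path(outdir, "set_variation_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs <- config$enrichment$gsva_set
    if (!is.null(gs) && gs %in% names(cohort$gene_sets$sets))
      res$gsva_arm_comparison <- compare_set_scores(res$gsva, meta, gs)
    res
  })
  log_msg("enrichment: ", nrow(enr$down), " sets (down), ",
          nrow(enr$up), " sets (up)")

  sig <- run_stage("ifn_signature", {
    sets <- intersect(config$signature$sets, names(cohort$gene_sets$sets))
    if (!length(sets)) stop2("no configured signature set found")
    scores <- score_signatures(expr, meta, cohort$gene_sets, sets = sets,
                               denominator = config$signature$denominator)
    dyn <- score_dynamics(scores, meta)
    comp <- lapply(stats::setNames(sets, sets), function(nm)
      compare_fc_by_outcome(degs$fc, meta, cohort$gene_sets$sets[[nm]]))
    utils::write.table(scores, file.path(outdir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dyn$per_patient,
                       file.path(outdir, "signature_deltas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp_tab <- do.call(rbind, lapply(names(comp), function(nm)
      data.frame(set_name = nm, t = comp[[nm]]$t, p_value = comp[[nm]]$p_value,
                 mean_survivor = comp[[nm]]$mean_survivor,
                 mean_deceased = comp[[nm]]$mean_deceased)))
    utils::write.table(comp_tab, file.path(outdir, "fc_outcome_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(scores = scores, dynamics = dyn, fc_comparison = comp)
  })
  log_msg("signature: ", length(unique(sig$scores$set_name)), " sets scored")

  clin <- run_stage("clinical_stats", {
    if (is.null(cohort$clinical)) NULL else {
      rep <- clinical_report(cohort$clinical, cohort$survival,
                             group = config$clinical$group)
      utils::write.table(rep, file.path(outdir, "clinical_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    }
  })

  manifest <- list(
    package = "mda5tx",
    version = as.character(utils::packageVersion("mda5tx")),
    seed = config$seed,
    config_hash = fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)),
    counts = list(
      genes = nrow(expr), samples = ncol(expr),
      genes_tested = length(degs$universe), degs = length(deg_ids),
      sets_tested = nrow(enr$down)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, degs = degs, clustering = clust,
                 enrichment = enr, signature = sig, clinical = clin,
                 manifest = manifest))
}
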