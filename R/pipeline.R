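#' Build a validated pipeline configuration
#'
#' Collects the input paths and thresholds of a full catalog ->
#' druggability -> interactions -> enrichment run. Thresholds are
#' domain-checked immediately; file paths are checked when the pipeline
#' runs. `linkage` may point to a two-column TSV (`compound`, `set_name`)
#' recording which compounds are linked to curated significant sets — the
#' explicit allow-list used instead of hard-coding disease semantics.
#'
#' @param catalogs character vector of compound-table paths (one per
#'   source, priority order).
#' @param protein_edges,gene_edges,network,pathways_gmt,disease_gmt,linkage
#'   optional input paths; stages lacking their input are skipped.
#' @param ob_min,dl_min,max_violations druggability thresholds.
#' @param min_confidence,confidence_inclusive protein-edge filter.
#' @param frequency_mode,frequency_value gene-frequency filter
#'   (`"mean"`/`"fixed"`).
#' @param restart RWR restart probability.
#' @param xd_min,p_max pathway / disease significance thresholds.
#' @param seed RNG seed recorded in the manifest.
#' @param outdir output directory for stage artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(catalogs,
                            protein_edges = NULL, gene_edges = NULL,
                            network = NULL, pathways_gmt = NULL,
                            disease_gmt = NULL, linkage = NULL,
                            ob_min = 30, dl_min = 0.18, max_violations = 1,
                            min_confidence = 0.5, confidence_inclusive = TRUE,
                            frequency_mode = "mean", frequency_value = NULL,
                            restart = 0.3, xd_min = 0.67, p_max = 0.01,
                            seed = 1L, outdir = tempfile("netpharm_run_")) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$catalogs) >= 1,
            cfg$ob_min >= 0, cfg$dl_min >= 0, cfg$dl_min <= 1,
            cfg$max_violations >= 0, cfg$max_violations <= 4,
            cfg$min_confidence >= 0, cfg$min_confidence <= 1,
            cfg$frequency_mode %in% c("mean", "fixed"),
            cfg$restart > 0, cfg$restart < 1,
            cfg$p_max >= 0, cfg$p_max <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the same fields as [pipeline_config()] arguments; unknown
#' fields are an error (schema validation before any work).
#'
#' @param path `.yaml`/`.yml` (needs the yaml package) or `.json` file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_usage("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Intersect druggable compounds with interaction-supported set linkage
#'
#' A compound is linked to a significant pathway iff one of its retained
#' protein targets belongs to that pathway's annotation set (analogously
#' for disease classes via genes), or iff an explicit linkage table names
#' it. The final flag marks compounds that are druggable AND linked to at
#' least one significant pathway or disease class.
#'
#' @param verdicts verdict data frame from [screen_druggable()] on the
#'   deduplicated catalog.
#' @param protein_edges_retained protein [interaction_edges] surviving the
#'   confidence filter (may be `NULL`).
#' @param gene_targets_retained a gene [target_set] from the frequency
#'   filter (may be `NULL`).
#' @param gene_edges gene [interaction_edges] used to trace compounds to
#'   retained genes (required with `gene_targets_retained`).
#' @param significant_pathways,significant_diseases filtered enrichment
#'   data frames (need `set_name`).
#' @param pathway_annotations,disease_annotations the
#'   [annotation_collection()]s the enrichment ran on.
#' @param linkage optional data frame (`compound`, `set_name`) of curated
#'   compound-to-significant-set links.
#' @return a `netpharm_report` data frame: `compound_id`, `druggable`,
#'   `pathways` and `diseases` (semicolon-joined linked set names),
#'   `final_flag`.
#' @export
intersect_druggable_linked <- function(verdicts,
                                       protein_edges_retained = NULL,
                                       gene_targets_retained = NULL,
                                       gene_edges = NULL,
                                       significant_pathways = NULL,
                                       significant_diseases = NULL,
                                       pathway_annotations = NULL,
                                       disease_annotations = NULL,
                                       linkage = NULL) {
  compounds <- unique(verdicts$compound_id)
  druggable <- vapply(split(verdicts$overall_pass, verdicts$compound_id)[compounds],
                      any, logical(1))

  link_names <- function(edges, keep_targets, sig, annotations) {
    out <- stats::setNames(vector("list", length(compounds)), compounds)
    if (is.null(edges) || is.null(sig) || !nrow(sig) || is.null(annotations))
      return(out)
    edges <- edges[edges$target_id %in% keep_targets, , drop = FALSE]
    for (nm in intersect(sig$set_name, names(annotations$sets))) {
      members <- annotations$sets[[nm]]
      hit <- unique(edges$compound_id[edges$target_id %in% members])
      hit <- intersect(hit, compounds)
      for (cid in hit) out[[cid]] <- c(out[[cid]], nm)
    }
    out
  }

  pw <- link_names(protein_edges_retained,
                   unique(protein_edges_retained$target_id),
                   significant_pathways, pathway_annotations)
  dz <- link_names(gene_edges,
                   if (!is.null(gene_targets_retained)) gene_targets_retained$ids else character(0),
                   significant_diseases, disease_annotations)

  if (!is.null(linkage)) {
    if (!all(c("compound", "set_name") %in% names(linkage)))
      stop_usage("linkage table needs 'compound' and 'set_name' columns")
    lid <- normalize_compound_id(linkage$compound)
    unmatched <- setdiff(lid, compounds)
    if (length(unmatched))
      stop_usage("linkage compounds not in the catalog: ",
                 paste(utils::head(unmatched, 5), collapse = ", "))
    for (k in seq_along(lid))
      pw[[lid[k]]] <- c(pw[[lid[k]]], linkage$set_name[k])
  }

  linked <- vapply(compounds, function(cid)
    length(pw[[cid]]) + length(dz[[cid]]) > 0, logical(1))
  report <- data.frame(
    compound_id = compounds,
    druggable = unname(druggable),
    pathways = vapply(pw, function(v) paste(unique(v), collapse = ";"), character(1)),
    diseases = vapply(dz, function(v) paste(unique(v), collapse = ";"), character(1)),
    final_flag = unname(druggable & linked),
    row.names = NULL, stringsAsFactors = FALSE)
  class(report) <- c("netpharm_report", "data.frame")
  report
}

#' @export
print.netpharm_report <- function(x, ...) {
  cat("Final compound report: ", nrow(x), " compound(s); ",
      sum(x$druggable), " druggable; ", sum(x$final_flag),
      " druggable and disease-linked\n", sep = "")
  invisible(x)
}

#' Run the full network-pharmacology pipeline
#'
#' Stages, each persisted under `config$outdir` and logged with row counts:
#' \enumerate{
#'   \item read and merge the source catalogs, deduplicate;
#'   \item druggability screen and per-herb summary (`table1_summary.tsv`,
#'     `druggable.tsv`, `verdicts.tsv`);
#'   \item confidence-filter protein edges (`protein_targets.txt`) and
#'     frequency-filter genes (`gene_targets.txt`);
#'   \item pathway enrichment (Fisher + RWR XD score,
#'     `pathway_enrichment.tsv`) over the network and GMT, disease
#'     enrichment over the disease GMT (`disease_enrichment.tsv`);
#'   \item intersect druggable and linked compounds
#'     (`final_compounds.tsv`), and write `run_manifest.json`.
#' }
#' Stages whose inputs are absent from the config are skipped. Outputs are
#' pure functions of (inputs, config): reruns are byte-identical. Any stage
#' error aborts the run, names the stage, and removes the partially written
#' output directory.
#'
#' @param config a [pipeline_config()].
#' @return list with the stage results and the final `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  fresh <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  res <- tryCatch(
    .run_pipeline_stages(config, outdir, set_stage = function(s) stage <<- s),
    error = function(e) {
      if (fresh) unlink(outdir, recursive = TRUE)
      stop_usage("pipeline failed at stage [", stage, "]: ", conditionMessage(e))
    })
  res
}

.run_pipeline_stages <- function(config, outdir, set_stage) {
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  set_stage("catalog")
  cats <- lapply(config$catalogs, read_compound_table)
  merged <- merge_sources(cats)
  catalog <- deduplicate(merged)
  .stage_log("catalog", nrow(merged), " records in, ",
             nrow(catalog), " unique compounds")

  set_stage("druggability")
  herb_level <- expand_herbs(catalog)
  scr <- screen_druggable(herb_level, config$ob_min, config$dl_min,
                          config$max_violations)
  summary <- herb_summary(herb_level, scr$verdicts)
  retained <- deduplicate(scr$retained)
  tsv(summary, "table1_summary.tsv")
  tsv(scr$verdicts, "verdicts.tsv")
  write_compound_table(retained, file.path(outdir, "druggable.tsv"))
  .stage_log("druggability", sum(scr$verdicts$overall_pass),
             " herb-level records pass, ", nrow(retained), " unique druggable")

  set_stage("interactions")
  protein_edges <- gene_edges <- NULL
  protein_targets <- gene_targets <- NULL
  if (!is.null(config$protein_edges)) {
    protein_edges <- read_interactions(config$protein_edges, "protein")
    protein_targets <- filter_by_confidence(protein_edges,
                                            config$min_confidence,
                                            config$confidence_inclusive)
    writeLines(protein_targets$ids, file.path(outdir, "protein_targets.txt"))
    .stage_log("interactions", nrow(protein_edges), " protein edges, ",
               length(protein_targets), " targets past confidence filter")
  }
  if (!is.null(config$gene_edges)) {
    gene_edges <- read_interactions(config$gene_edges, "gene")
    freq <- gene_frequency(gene_edges)
    gene_targets <- frequency_threshold_filter(freq, config$frequency_mode,
                                               config$frequency_value)
    writeLines(gene_targets$ids, file.path(outdir, "gene_targets.txt"))
    .stage_log("interactions", nrow(gene_edges), " gene edges, ",
               length(gene_targets), " genes past frequency filter")
  }

  set_stage("enrichment")
  pathway_annotations <- disease_annotations <- NULL
  sig_pathways <- sig_diseases <- NULL
  if (!is.null(config$pathways_gmt) && !is.null(protein_targets)) {
    pathway_annotations <- read_gmt(config$pathways_gmt, kind = "pathway")
    enr <- fisher_enrichment(protein_targets, pathway_annotations)
    if (!is.null(config$network)) {
      net <- read_network(config$network)
      scores <- propagate(net, protein_targets, config$restart)
      xd <- xd_scores(scores, pathway_annotations)
      enr <- merge(enr, xd[, c("set_name", "xd_score")],
                   by = "set_name", sort = FALSE)
      sig_pathways <- threshold_filter(enr, xd_min = config$xd_min)
    } else {
      sig_pathways <- threshold_filter(enr, p_max = config$p_max)
    }
    tsv(enr, "pathway_enrichment.tsv")
    .stage_log("enrichment", nrow(enr), " pathways scored, ",
               nrow(sig_pathways), " significant")
  }
  if (!is.null(config$disease_gmt) && !is.null(gene_targets)) {
    disease_annotations <- read_gmt(config$disease_gmt, kind = "disease_class")
    denr <- fisher_enrichment(gene_targets, disease_annotations)
    sig_diseases <- threshold_filter(denr, p_max = config$p_max)
    tsv(denr, "disease_enrichment.tsv")
    .stage_log("enrichment", nrow(denr), " disease classes scored, ",
               nrow(sig_diseases), " significant")
  }

  set_stage("report")
  linkage <- NULL
  if (!is.null(config$linkage))
    linkage <- utils::read.table(config$linkage, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, quote = "\"")
  retained_edges <- if (!is.null(protein_edges)) {
    keep <- if (config$confidence_inclusive)
      protein_edges$confidence >= config$min_confidence
    else protein_edges$confidence > config$min_confidence
    protein_edges[keep, , drop = FALSE]
  }
  report <- intersect_druggable_linked(
    scr$verdicts, retained_edges, gene_targets, gene_edges,
    sig_pathways, sig_diseases, pathway_annotations, disease_annotations,
    linkage)
  tsv(as.data.frame(report), "final_compounds.tsv")
  .stage_log("report", sum(report$final_flag),
             " compounds druggable and disease-linked")

  manifest <- list(
    config = config[setdiff(names(config), "outdir")],
    config_hash = .config_hash(config),
    inputs = .input_versions(config),
    counts = list(records_in = nrow(merged), unique_compounds = nrow(catalog),
                  druggable = nrow(retained),
                  final = sum(report$final_flag)))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  list(catalog = catalog, summary = summary, verdicts = scr$verdicts,
       druggable = retained, protein_targets = protein_targets,
       gene_targets = gene_targets, pathways = sig_pathways,
       diseases = sig_diseases, report = report, outdir = outdir)
}

.config_hash <- function(config) {
  dump <- paste(deparse(config[setdiff(names(config), "outdir")]), collapse = "")
  ## small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(dump)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.input_versions <- function(config) {
  paths <- unlist(config[c("catalogs", "protein_edges", "gene_edges",
                           "network", "pathways_gmt", "disease_gmt",
                           "linkage")], use.names = FALSE)
  paths <- paths[!is.null(paths) & file.exists(paths)]
  lapply(stats::setNames(paths, basename(paths)),
         function(p) list(size = file.info(p)$size))
}
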