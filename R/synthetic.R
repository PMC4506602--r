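#' Parameterize a synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators into one object so a
#' scenario is fully reproducible from (scenario, seed). The defaults
#' emulate a six-herb formula screen: per-herb catalogs whose descriptor
#' marginals (log-normal MW, normal AlogP, Poisson H-bond counts,
#' beta-scaled OB, beta DL) put roughly 10--30% of compounds past the
#' default druggability screen, cross-herb/cross-source duplicates, a
#' bipartite compound--target graph with beta-distributed confidence scores
#' and evidence-multiplied hub genes, and a scale-free protein network with
#' planted dense modules preferentially populated by true targets.
#'
#' The global `seed` fans out to independent per-generator substreams
#' (catalog / interactions / network) so any stage can be regenerated in
#' isolation and still match an end-to-end run.
#'
#' @param seed integer RNG seed.
#' @param n_herbs number of herbs.
#' @param compounds_per_herb compounds initially drawn per herb.
#' @param duplicate_rate probability that a compound is shared with a
#'   second herb and a second source.
#' @param druggable_fraction fraction of compounds planted as druggable
#'   (descriptors generated to satisfy every screen criterion; the rest are
#'   planted to fail at least one).
#' @param descriptor_model list of distribution parameters:
#'   `mw_meanlog`, `mw_sdlog`, `alogp_mean`, `alogp_sd`, `hbd_lambda`,
#'   `hba_lambda`, `ob_shape1`, `ob_shape2`, `dl_shape1`, `dl_shape2`.
#' @param n_proteins,n_genes target universe sizes.
#' @param confidence_model beta shape parameters `c(shape1, shape2)` for
#'   protein-edge confidence scores.
#' @param edges_per_compound Poisson mean of protein and of gene edges per
#'   compound.
#' @param n_hub_genes,hub_multiplier hub genes receive `hub_multiplier`
#'   times the evidence rows of ordinary genes.
#' @param network_power preferential-attachment exponent of the scale-free
#'   background network.
#' @param planted_modules list of planted pathway modules, each a list with
#'   `size`, `density` (internal edge probability) and `enrichment` (factor
#'   by which module membership prefers true target proteins).
#' @param n_background_sets random annotation sets emitted besides the
#'   planted modules.
#' @param background_set_sizes size range for background sets.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 42L,
                               n_herbs = 6L,
                               compounds_per_herb = 100L,
                               duplicate_rate = 0.1,
                               druggable_fraction = 0.2,
                               descriptor_model = list(
                                 mw_meanlog = log(350), mw_sdlog = 0.35,
                                 alogp_mean = 2.5, alogp_sd = 1.8,
                                 hbd_lambda = 2.5, hba_lambda = 5,
                                 ob_shape1 = 2, ob_shape2 = 3,
                                 dl_shape1 = 1.5, dl_shape2 = 4),
                               n_proteins = 2000L,
                               n_genes = 600L,
                               confidence_model = c(2, 2),
                               edges_per_compound = 4,
                               n_hub_genes = 20L,
                               hub_multiplier = 10,
                               network_power = 1,
                               planted_modules = list(
                                 list(size = 50, density = 0.3, enrichment = 5),
                                 list(size = 50, density = 0.3, enrichment = 5)),
                               n_background_sets = 20L,
                               background_set_sizes = c(20L, 400L)) {
  sc <- as.list(environment())
  stopifnot(sc$duplicate_rate >= 0, sc$duplicate_rate <= 1,
            sc$druggable_fraction >= 0, sc$druggable_fraction <= 1,
            sc$n_herbs >= 1, sc$compounds_per_herb >= 1,
            sc$n_proteins >= 1, sc$n_genes >= 1)
  class(sc) <- "synthetic_scenario"
  sc
}

## per-generator substream seeds derived from the global seed (kept < 2^31)
.substream <- function(seed, stage) {
  offset <- c(catalog = 1L, interactions = 2L, network = 3L)[[stage]]
  (as.integer(seed) * 7919L + offset * 104729L) %% 2147483647L
}

#' Generate a synthetic compound catalog with planted druggability
#'
#' Draws `n_herbs * compounds_per_herb` compounds; each is planted as
#' druggable (all screen criteria satisfied by construction) with
#' probability `druggable_fraction`, otherwise planted to fail at least one
#' criterion (low OB, low DL, or two or more Lipinski violations).
#' Duplicates are injected at `duplicate_rate`: a duplicated compound is
#' listed again under another herb and a second source tag, with identical
#' descriptors. Fully deterministic given (scenario, scenario$seed).
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `catalog` (herb-level [compound_catalog], one row per
#'   herb membership) and `truth` (data frame `compound_id`, `druggable`,
#'   `duplicated`).
#' @export
gen_catalog <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(.substream(scenario$seed, "catalog"))
  dm <- scenario$descriptor_model
  n <- scenario$n_herbs * scenario$compounds_per_herb
  herbs <- paste0("H", sprintf("%02d", rep(seq_len(scenario$n_herbs),
                                           each = scenario$compounds_per_herb)))
  id <- sprintf("cmpd%04d", seq_len(n))
  druggable <- stats::runif(n) < scenario$druggable_fraction

  mw <- stats::rlnorm(n, dm$mw_meanlog, dm$mw_sdlog)
  alogp <- stats::rnorm(n, dm$alogp_mean, dm$alogp_sd)
  hbd <- stats::rpois(n, dm$hbd_lambda)
  hba <- stats::rpois(n, dm$hba_lambda)
  ob <- 100 * stats::rbeta(n, dm$ob_shape1, dm$ob_shape2)
  dl <- stats::rbeta(n, dm$dl_shape1, dm$dl_shape2)

  ## planted druggable: force all criteria to hold (0 LR violations)
  i <- which(druggable)
  mw[i] <- pmin(mw[i], 480); alogp[i] <- pmin(alogp[i], 4.8)
  hbd[i] <- pmin(hbd[i], 5L); hba[i] <- pmin(hba[i], 10L)
  ob[i] <- 30 + (ob[i] %% 70); dl[i] <- 0.18 + 0.82 * (dl[i] %% 1)

  ## planted non-druggable: force a definite failure mode
  j <- which(!druggable)
  mode <- sample(c("ob", "dl", "lr"), length(j), replace = TRUE)
  ob[j[mode == "ob"]] <- ob[j[mode == "ob"]] %% 29.9
  dl[j[mode == "dl"]] <- dl[j[mode == "dl"]] %% 0.179
  lr <- j[mode == "lr"]
  mw[lr] <- 500 + mw[lr]; hbd[lr] <- 6L + hbd[lr]   # two guaranteed violations

  cat <- new_compound_catalog(data.frame(
    compound_id = id, name = id, herbs = herbs, sources = "simdb1",
    mw = mw, alogp = alogp, hbd = as.numeric(hbd), hba = as.numeric(hba),
    ob = ob, dl = dl, flags = "", stringsAsFactors = FALSE))

  dup <- stats::runif(n) < scenario$duplicate_rate & scenario$n_herbs > 1
  if (any(dup)) {
    extra <- cat[dup, , drop = FALSE]
    other <- vapply(extra$herbs, function(h) {
      pool <- setdiff(unique(herbs), h)
      sample(pool, 1L)
    }, character(1))
    extra$herbs <- other
    extra$sources <- "simdb2"
    cat <- new_compound_catalog(rbind(as.data.frame(cat), as.data.frame(extra)))
  }
  list(catalog = cat,
       truth = data.frame(compound_id = id, druggable = druggable,
                          duplicated = dup, stringsAsFactors = FALSE))
}

#' Generate synthetic compound--protein and compound--gene interactions
#'
#' Per unique compound, a Poisson number of protein edges with
#' beta-distributed confidence scores and a Poisson number of gene edges.
#' A designated hub-gene subset receives `hub_multiplier` times the
#' sampling weight, planting the frequency skew the gene-ranking stage is
#' meant to detect. Gene evidence is emitted as duplicated rows.
#'
#' @param scenario a [synthetic_scenario()].
#' @param catalog catalog from [gen_catalog()].
#' @return list with `protein_edges`, `gene_edges` (see
#'   [interaction_edges]) and `truth` (list with `hub_genes`,
#'   `protein_universe`, `gene_universe`).
#' @export
gen_interactions <- function(scenario, catalog) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(catalog, "compound_catalog"))
  set.seed(.substream(scenario$seed, "interactions"))
  compounds <- unique(catalog$compound_id)
  proteins <- sprintf("P%04d", seq_len(scenario$n_proteins))
  genes <- sprintf("G%04d", seq_len(scenario$n_genes))
  hubs <- sample(genes, min(scenario$n_hub_genes, length(genes)))
  gene_w <- ifelse(genes %in% hubs, scenario$hub_multiplier, 1)

  np <- stats::rpois(length(compounds), scenario$edges_per_compound)
  pe <- new_interaction_edges(
    rep(compounds, np),
    sample(proteins, sum(np), replace = TRUE),
    "protein",
    stats::rbeta(sum(np), scenario$confidence_model[1], scenario$confidence_model[2]))

  ng <- stats::rpois(length(compounds), scenario$edges_per_compound)
  ge <- new_interaction_edges(
    rep(compounds, ng),
    sample(genes, sum(ng), replace = TRUE, prob = gene_w),
    "gene", NA_real_)

  list(protein_edges = pe, gene_edges = ge,
       truth = list(hub_genes = hubs, protein_universe = proteins,
                    gene_universe = genes))
}

#' Generate a synthetic protein network with planted pathway modules
#'
#' Builds a scale-free (preferential attachment) background over the
#' protein universe, then plants each module: its members are sampled with
#' weight `enrichment` for true target proteins and weight 1 otherwise, and
#' internal edges are added at the stated density. Annotation sets are
#' emitted for the planted modules plus `n_background_sets` uniformly
#' random sets; the universe is the full node set.
#'
#' @param scenario a [synthetic_scenario()].
#' @param protein_targets a [target_set] (or character vector) of true
#'   target proteins inside the protein universe.
#' @return list with `network` (igraph), `annotations`
#'   ([annotation_collection()]) and `truth` (character vector of planted
#'   module set names).
#' @export
gen_network_and_annotations <- function(scenario, protein_targets) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ids <- if (inherits(protein_targets, "target_set")) protein_targets$ids
         else as.character(protein_targets)
  if (!length(ids)) stop_usage("need a non-empty target set")
  set.seed(.substream(scenario$seed, "network"))
  n <- scenario$n_proteins
  proteins <- sprintf("P%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = scenario$network_power, m = 2,
                         directed = FALSE)
  igraph::V(g)$name <- proteins
  is_target <- proteins %in% ids

  sets <- list()
  planted <- character(0)
  for (k in seq_along(scenario$planted_modules)) {
    pm <- scenario$planted_modules[[k]]
    w <- ifelse(is_target, pm$enrichment, 1)
    members <- sample(proteins, pm$size, prob = w)
    ## wire the module at the stated internal density
    pairs <- utils::combn(members, 2)
    keep <- stats::runif(ncol(pairs)) < pm$density
    if (any(keep))
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    nm <- sprintf("planted_module_%02d", k)
    sets[[nm]] <- members
    planted <- c(planted, nm)
  }
  g <- igraph::simplify(g)
  sizes <- sort(unique(round(seq(scenario$background_set_sizes[1],
                                 scenario$background_set_sizes[2],
                                 length.out = scenario$n_background_sets))))
  sizes <- rep_len(sizes, scenario$n_background_sets)
  for (k in seq_len(scenario$n_background_sets))
    sets[[sprintf("background_set_%02d", k)]] <- sample(proteins, sizes[k])
  list(network = g,
       annotations = annotation_collection(sets, universe = proteins,
                                           kind = "pathway"),
       truth = planted)
}

#' Write a full synthetic scenario to disk
#'
#' Emits `catalog.tsv`, `protein_edges.tsv`, `gene_edges.tsv`, `ppi.tsv`,
#' `pathways.gmt` and `truth.json` under `outdir`, the same shapes the
#' module readers consume, so generated data round-trips through the whole
#' pipeline.
#'
#' @param scenario a [synthetic_scenario()].
#' @param outdir output directory (created if needed).
#' @param min_confidence confidence threshold used to derive the true
#'   target set that seeds the planted network modules (default 0.5).
#' @return `outdir`, invisibly.
#' @export
simulate_scenario <- function(scenario, outdir, min_confidence = 0.5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cat <- gen_catalog(scenario)
  ints <- gen_interactions(scenario, cat$catalog)
  targets <- filter_by_confidence(ints$protein_edges, min_confidence)
  net <- gen_network_and_annotations(scenario, targets)

  write_compound_table(cat$catalog, file.path(outdir, "catalog.tsv"))
  utils::write.table(ints$protein_edges[, c("compound_id", "target_id", "confidence")],
                     file.path(outdir, "protein_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ints$gene_edges[, c("compound_id", "target_id")],
                     file.path(outdir, "gene_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  el <- igraph::as_data_frame(net$network, what = "edges")
  utils::write.table(el[, c("from", "to")], file.path(outdir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_gmt(net$annotations, file.path(outdir, "pathways.gmt"))
  jsonlite::write_json(
    list(druggable = cat$truth$compound_id[cat$truth$druggable],
         duplicated = cat$truth$compound_id[cat$truth$duplicated],
         hub_genes = ints$truth$hub_genes,
         planted_modules = net$truth),
    file.path(outdir, "truth.json"))
  invisible(outdir)
}
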