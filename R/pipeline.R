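# Full pipeline: dataset construction -> fingerprints/clusters -> mapping ->
# score filtering -> pair classification -> prediction -> similarity
# extension -> known-pair removal -> pathway grouping (-> benchmark).

#' Run configuration for the end-to-end pipeline
#'
#' Every numeric default is the method's operating point: activity bands at
#' 10/20 uM, compound clustering at Tanimoto 0.7, similarity propagation at
#' Tanimoto 0.8, mapping score threshold 0.5, eligibility minima of 3 targets
#' per side for compounds and 5 for clusters.
#'
#' @param bioactivity,annotations Paths to the bioactivity and domain
#'   annotation TSVs (required).
#' @param hierarchy,reference,pathways Optional paths to the domain hierarchy,
#'   reference mapping, and pathway annotation TSVs.
#' @param active_um,inactive_um Activity classification bounds (uM).
#' @param cluster_tanimoto,propagate_tanimoto Tanimoto thresholds for
#'   clustering and for similarity propagation.
#' @param mapping_score Mapping score threshold applied to the raw mappings.
#' @param min_compound_targets,min_cluster_targets Eligibility minima.
#' @param use_hierarchy Use the hierarchy (when given) for hierarchy-aware
#'   single-domain counting.
#' @param use_clusters Compute cluster-based mappings.
#' @param features Which feature kinds to map: subset of
#'   `c("single", "pair")`.
#' @param threshold_metrics Metrics the score threshold applies to.
#' @param cluster_mode Cluster semantics, see [cluster_compounds()].
#' @param dedup_scope Deduplication scope, see [build_dataset()].
#' @return A `run_config` list.
#' @export
run_config <- function(bioactivity, annotations,
                       hierarchy = NULL, reference = NULL, pathways = NULL,
                       active_um = 10, inactive_um = 20,
                       cluster_tanimoto = 0.7, propagate_tanimoto = 0.8,
                       mapping_score = 0.5,
                       min_compound_targets = 3, min_cluster_targets = 5,
                       use_hierarchy = TRUE, use_clusters = TRUE,
                       features = c("single", "pair"),
                       threshold_metrics = c(
                         "recall", "precision", "accuracy", "f1", "mcc"
                       ),
                       cluster_mode = "seed",
                       dedup_scope = "global") {
  structure(
    list(
      bioactivity = bioactivity, annotations = annotations,
      hierarchy = hierarchy, reference = reference, pathways = pathways,
      active_um = active_um, inactive_um = inactive_um,
      cluster_tanimoto = cluster_tanimoto,
      propagate_tanimoto = propagate_tanimoto,
      mapping_score = mapping_score,
      min_compound_targets = min_compound_targets,
      min_cluster_targets = min_cluster_targets,
      use_hierarchy = use_hierarchy, use_clusters = use_clusters,
      features = match.arg(features,
        c("single", "pair"),
        several.ok = TRUE
      ),
      threshold_metrics = threshold_metrics,
      cluster_mode = cluster_mode, dedup_scope = dedup_scope
    ),
    class = "run_config"
  )
}

#' Run the full mapping and prediction pipeline
#'
#' Executes every stage in order, writes each intermediate table under
#' `out_dir`, and returns (and writes) a JSON manifest of per-stage counts
#' together with the effective configuration. Stages: build the labeled
#' dataset; fingerprint compounds and form clusters; compute raw mappings
#' (individual + cluster, single domains + pairs); apply the score threshold;
#' classify pair mappings and keep positive pairs; predict targets by domain
#' containment; extend predictions to similar compounds; remove known pairs;
#' group by pathway; and, when a reference set is given, benchmark the raw
#' mappings across thresholds.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (a list of stage counts and the config).
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (!inherits(cfg, "run_config")) {
    stop("cfg must be a run_config()", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  counts <- list()

  records <- stage("read-bioactivity", read_bioactivity(cfg$bioactivity))
  dataset <- stage("build-dataset", build_dataset(
    records,
    dedup_scope = cfg$dedup_scope,
    active_um = cfg$active_um, inactive_um = cfg$inactive_um
  ))
  write_dataset(
    dataset, file.path(out_dir, "dataset.tsv"),
    file.path(out_dir, "dataset_summary.json")
  )
  counts$records <- nrow(records)
  counts$dataset_pairs <- nrow(dataset$pairs)

  world_proteome <- stage(
    "read-annotations",
    read_domain_annotations(cfg$annotations)
  )
  hier <- NULL
  if (!is.null(cfg$hierarchy) && cfg$use_hierarchy) {
    hier <- stage("read-hierarchy", read_domain_hierarchy(cfg$hierarchy))
  }
  counts$proteins <- length(world_proteome$domains)

  compounds <- unique(records[, c("compound_id", "smiles")])
  fps <- stage(
    "fingerprint",
    suppressWarnings(compute_fingerprints(compounds))
  )
  counts$fingerprinted_compounds <- nrow(fps)
  clusters <- NULL
  if (cfg$use_clusters) {
    clusters <- stage("cluster", cluster_compounds(
      fps, cfg$cluster_tanimoto,
      mode = cfg$cluster_mode
    ))
    counts$clusters <- length(clusters)
  }

  raw <- stage("map", suppressWarnings(map_all(
    dataset, world_proteome, hier, clusters,
    features = cfg$features,
    min_compound_targets = cfg$min_compound_targets,
    min_cluster_targets = cfg$min_cluster_targets
  )))
  write_mappings(raw, file.path(out_dir, "mappings_raw.tsv"))
  counts$raw_mappings <- nrow(raw)

  filtered <- stage(
    "filter",
    threshold_filter(raw, cfg$mapping_score, cfg$threshold_metrics)
  )
  classified <- stage(
    "pairs",
    classify_domain_pairs(filtered, singles = raw)
  )
  final_mappings <- filter_positive_pairs(classified)
  write_mappings(classified, file.path(out_dir, "mappings_filtered.tsv"))
  counts$filtered_mappings <- nrow(filtered)
  counts$final_mappings <- nrow(final_mappings)

  predictions <- stage(
    "predict",
    predict_from_mappings(final_mappings, world_proteome)
  )
  write_predictions(
    predictions,
    file.path(out_dir, "predictions_direct.tsv")
  )
  counts$direct_predictions <- nrow(predictions)

  extended <- stage("extend", suppressWarnings(
    extend_by_similarity(predictions, fps, cfg$propagate_tanimoto)
  ))
  counts$extended_predictions <- nrow(extended)

  novel <- stage("subtract-known", remove_known(extended, dataset))
  write_predictions(novel, file.path(out_dir, "predictions.tsv"))
  counts$novel_predictions <- nrow(novel)

  if (!is.null(cfg$pathways)) {
    ann <- stage("read-pathways", read_pathway_annotations(cfg$pathways))
    summary <- stage("pathways", group_by_pathway(novel, ann))
    write_tsv_table(summary, file.path(out_dir, "pathway_summary.tsv"))
    counts$pathways <- nrow(summary)
  }

  if (!is.null(cfg$reference)) {
    reference <- stage("read-reference", read_reference(cfg$reference))
    report <- stage("benchmark", benchmark_mappings(
      raw, reference,
      metrics = cfg$threshold_metrics
    ))
    write_tsv_table(report, file.path(out_dir, "benchmark.tsv"))
    counts$benchmark_rows <- nrow(report)
  }

  manifest <- list(config = unclass(cfg), counts = counts)
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(manifest)
}
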