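# Turning filtered mappings into drug/compound-target interaction
# predictions: domain containment, one round of compound-similarity
# extension, removal of known pairs, pathway grouping.

empty_predictions <- function() {
  data.frame(
    compound_id = character(), target_accession = character(),
    features = character(), via_compound = character(),
    stringsAsFactors = FALSE
  )
}

merge_predictions <- function(pred) {
  if (nrow(pred) == 0L) {
    return(empty_predictions())
  }
  collapse <- function(x) {
    x <- sort(unique(x[!is.na(x) & nzchar(x)]))
    if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")
  }
  key <- paste(pred$compound_id, pred$target_accession, sep = "\r")
  groups <- split(seq_len(nrow(pred)), key)
  keys <- names(groups)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    compound_id = vapply(parts, `[`, "", 1L),
    target_accession = vapply(parts, `[`, "", 2L),
    features = vapply(groups, function(i) {
      collapse(unlist(strsplit(pred$features[i], ";", fixed = TRUE)))
    }, ""),
    via_compound = vapply(groups, function(i) {
      collapse(pred$via_compound[i])
    }, ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$compound_id, out$target_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict compound-target interactions from filtered mappings
#'
#' Crosses each mapping's compound with every protein containing the mapped
#' feature (both ids for a pair feature). Duplicate (compound, target) pairs
#' arising from multiple licensing features are merged, accumulating the
#' features in the provenance column.
#'
#' @param mappings Mapping data frame, already score-filtered and (for pair
#'   rows) restricted to positive pairs.
#' @param proteome A [proteome()] over which to search for the features
#'   (typically broader than the mapping targets).
#' @return Prediction data frame with columns `compound_id`,
#'   `target_accession`, `features` (`;`-separated licensing features), and
#'   `via_compound` (`NA` for direct predictions).
#' @export
predict_from_mappings <- function(mappings, proteome) {
  if (nrow(mappings) == 0L) {
    return(empty_predictions())
  }
  feats <- unique(mappings$feature)
  hits <- lapply(feats, function(f) proteins_with_feature(proteome, f))
  names(hits) <- feats
  rows <- lapply(seq_len(nrow(mappings)), function(i) {
    targets <- hits[[mappings$feature[i]]]
    if (length(targets) == 0L) {
      return(NULL)
    }
    data.frame(
      compound_id = mappings$subject_id[i],
      target_accession = targets,
      features = mappings$feature[i],
      via_compound = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  merge_predictions(do.call(rbind, rows) %||% empty_predictions())
}

#' Extend predictions to similar compounds
#'
#' One propagation round: for every prediction (c, p), adds (c', p) for each
#' compound c' whose Tanimoto similarity to c is at least `threshold`. The
#' result is the union with the input (the extension is monotone); no
#' transitive chaining is performed. Source compounds without a fingerprint
#' are skipped for extension with a warning.
#'
#' @param predictions Prediction data frame (see [predict_from_mappings()]).
#' @param fps A `fingerprint_set` covering the compound universe.
#' @param threshold Tanimoto threshold, default 0.8.
#' @return Prediction data frame; extended rows carry the source compound in
#'   `via_compound`.
#' @export
extend_by_similarity <- function(predictions, fps, threshold = 0.8) {
  if (nrow(predictions) == 0L) {
    return(predictions)
  }
  sources <- unique(predictions$compound_id)
  missing_fp <- setdiff(sources, rownames(fps))
  if (length(missing_fp) > 0L) {
    warning(
      length(missing_fp),
      " predicted compound(s) without fingerprints skipped for extension",
      call. = FALSE
    )
  }
  new_rows <- list()
  for (cpd in setdiff(sources, missing_fp)) {
    neighbors <- similar_compounds(cpd, fps, threshold)
    if (length(neighbors) == 0L) next
    base <- predictions[predictions$compound_id == cpd, , drop = FALSE]
    for (nb in neighbors) {
      ext <- base
      ext$compound_id <- nb
      ext$via_compound <- cpd
      new_rows[[length(new_rows) + 1L]] <- ext
    }
  }
  if (length(new_rows) == 0L) {
    return(predictions)
  }
  merge_predictions(rbind(predictions, do.call(rbind, new_rows)))
}

#' Remove known compound-target pairs from predictions
#'
#' Drops every prediction recorded in the interaction dataset with either
#' label: active pairs are already known, and inactive pairs are known
#' non-binders that would be contradicted by a prediction.
#'
#' @param predictions Prediction data frame.
#' @param dataset An `interaction_dataset`.
#' @return Prediction data frame disjoint from the dataset's pairs.
#' @export
remove_known <- function(predictions, dataset) {
  if (nrow(predictions) == 0L) {
    return(predictions)
  }
  known <- paste(dataset$pairs$compound_id, dataset$pairs$target_id,
    sep = "\r"
  )
  key <- paste(predictions$compound_id, predictions$target_accession,
    sep = "\r"
  )
  out <- predictions[!(key %in% known), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize predictions by pathway
#'
#' @param predictions Prediction data frame.
#' @param pathway_annotations Data frame with columns `target_accession` and
#'   `pathway_id`; a target may belong to several pathways, in which case its
#'   predictions are counted in every one. Predictions whose target has no
#'   annotation are collected under pathway id `"unannotated"`.
#' @return Data frame `pathway_id`, `n_interactions`, `n_compounds`,
#'   `n_proteins`, sorted by decreasing interaction count.
#' @export
group_by_pathway <- function(predictions, pathway_annotations) {
  empty <- data.frame(
    pathway_id = character(), n_interactions = integer(),
    n_compounds = integer(), n_proteins = integer(),
    stringsAsFactors = FALSE
  )
  if (nrow(predictions) == 0L) {
    return(empty)
  }
  ann <- pathway_annotations
  if (is.null(ann) || nrow(ann) == 0L) {
    ann <- data.frame(
      target_accession = character(), pathway_id = character(),
      stringsAsFactors = FALSE
    )
  }
  merged <- merge(predictions[, c("compound_id", "target_accession")],
    ann[, c("target_accession", "pathway_id")],
    by = "target_accession", all.x = TRUE
  )
  merged$pathway_id[is.na(merged$pathway_id)] <- "unannotated"
  split_rows <- split(merged, merged$pathway_id)
  out <- do.call(rbind, lapply(names(split_rows), function(pw) {
    g <- split_rows[[pw]]
    data.frame(
      pathway_id = pw,
      n_interactions = nrow(g),
      n_compounds = length(unique(g$compound_id)),
      n_proteins = length(unique(g$target_accession)),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(-out$n_interactions, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein-to-pathway annotation table
#'
#' @param path TSV with columns `target_accession`, `pathway_id`.
#' @return Data frame with those columns.
#' @export
read_pathway_annotations <- function(path) {
  df <- read_tsv_table(path, c("target_accession", "pathway_id"))
  df[, c("target_accession", "pathway_id")]
}

#' Write / read a prediction table
#'
#' @param predictions Prediction data frame.
#' @param path File path.
#' @return `path` invisibly (write) or the prediction data frame (read).
#' @export
write_predictions <- function(predictions, path) {
  write_tsv_table(predictions, path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- read_tsv_table(path, c(
    "compound_id", "target_accession", "features", "via_compound"
  ))
  df$via_compound[df$via_compound == "NA"] <- NA_character_
  df
}
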