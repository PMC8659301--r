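# Construction of the labeled interaction dataset from raw bioactivity
# records: activity classification, median deduplication, source merging,
# contradiction handling.

#' Classify a bioactivity value as active, inactive, or ambiguous
#'
#' Compound--target pairs with an xC50-type potency below 10 uM are treated as
#' active (interacting); pairs above 20 uM as inactive (not interacting at the
#' desired level). Values inside the closed band \[10, 20\] uM are ambiguous
#' and are discarded downstream: they are too potent to call inactive and too
#' weak to call active. The boundary values 10 and 20 fall in the ambiguous
#' band so that the three classes partition the positive reals.
#'
#' @param activity_um Numeric vector of activity values in micromolar
#'   (IC50/EC50/AC50/Ki-type; lower = more potent). Must be positive and
#'   finite.
#' @param active_um Upper bound (exclusive) for the active class, in uM.
#' @param inactive_um Lower bound (exclusive) for the inactive class, in uM.
#' @return Character vector, one of `"active"`, `"inactive"`, `"ambiguous"`.
#' @examples
#' classify_activity(c(5, 79.4, 15))
#' @export
classify_activity <- function(activity_um, active_um = 10, inactive_um = 20) {
  if (!is.numeric(activity_um)) {
    stop("activity_um must be numeric", call. = FALSE)
  }
  if (any(!is.finite(activity_um)) || any(activity_um <= 0)) {
    stop("activity values must be positive and finite", call. = FALSE)
  }
  if (active_um > inactive_um) {
    stop("active_um must not exceed inactive_um", call. = FALSE)
  }
  ifelse(activity_um < active_um, "active",
    ifelse(activity_um > inactive_um, "inactive", "ambiguous")
  )
}

#' Collapse duplicated activity measurements to a single value
#'
#' Multiple reported measurements for the same compound--target pair are
#' summarized by their median; for an even number of values, the arithmetic
#' mean of the two central values.
#'
#' @param values Non-empty numeric vector of positive activity values (uM).
#' @return A single numeric value.
#' @examples
#' aggregate_duplicates(c(1, 2, 9)) # 2
#' aggregate_duplicates(c(4, 8)) # 6
#' @export
aggregate_duplicates <- function(values) {
  if (length(values) == 0L) {
    stop("cannot aggregate an empty set of activity values", call. = FALSE)
  }
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
    stop("activity values must be positive and finite", call. = FALSE)
  }
  stats::median(values)
}

#' Read bioactivity records from a tab-separated file
#'
#' Expects a header line with columns `compound_id`, `smiles`,
#' `target_accession`, `activity_um`, `source`. Lines starting with `#` are
#' ignored. Rows with a non-positive, non-finite, or unparseable activity
#' value, or an empty compound/target id, are skipped with a warning that
#' reports how many rows were dropped.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `compound_id`, `smiles`, `target_id`,
#'   `activity_um`, `source`.
#' @export
read_bioactivity <- function(path) {
  df <- read_tsv_table(path, c(
    "compound_id", "smiles", "target_accession", "activity_um", "source"
  ))
  records <- data.frame(
    compound_id = df$compound_id,
    smiles = df$smiles,
    target_id = df$target_accession,
    activity_um = suppressWarnings(as.numeric(df$activity_um)),
    source = df$source,
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(records$activity_um) | records$activity_um <= 0 |
    !nzchar(records$compound_id) | !nzchar(records$target_id)
  if (any(bad)) {
    warning(sum(bad), " malformed bioactivity row(s) skipped", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Build a consistent interaction dataset from bioactivity records
#'
#' Collapses duplicated measurements per (compound, target) pair to their
#' median first, then classifies the aggregated value. Pairs whose aggregate
#' falls in the ambiguous 10--20 uM band are dropped. With
#' `dedup_scope = "global"` (default) the median is taken over all sources
#' jointly, which makes active/inactive contradictions impossible by
#' construction; with `"per_source"` each source is aggregated separately and
#' pairs that end up carrying both labels are dropped and counted.
#'
#' @param records Data frame with columns `compound_id`, `target_id`,
#'   `activity_um`, and (for `per_source`) `source`, as returned by
#'   [read_bioactivity()]. A `smiles` column is allowed and ignored here.
#' @param dedup_scope Either `"global"` or `"per_source"`.
#' @param active_um,inactive_um Classification thresholds in uM, see
#'   [classify_activity()].
#' @return An object of class `interaction_dataset`: a list with `pairs`
#'   (data frame `compound_id`, `target_id`, `label`) and `summary`
#'   (record/pair counts, ambiguous and contradictory pairs dropped).
#' @examples
#' recs <- data.frame(
#'   compound_id = c("c1", "c1", "c1"),
#'   target_id = c("p1", "p1", "p2"),
#'   activity_um = c(5, 3, 50),
#'   source = "x"
#' )
#' ds <- build_dataset(recs)
#' active_targets(ds, "c1") # "p1"
#' @export
build_dataset <- function(records, dedup_scope = c("global", "per_source"),
                          active_um = 10, inactive_um = 20) {
  dedup_scope <- match.arg(dedup_scope)
  required <- c("compound_id", "target_id", "activity_um")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n_records <- nrow(records)
  if (n_records == 0L) {
    return(new_interaction_dataset(
      data.frame(
        compound_id = character(), target_id = character(),
        label = character(), stringsAsFactors = FALSE
      ),
      list(
        n_records = 0L, n_pairs = 0L,
        n_ambiguous_dropped = 0L, n_contradictions_dropped = 0L
      )
    ))
  }

  if (dedup_scope == "global") {
    key <- paste(records$compound_id, records$target_id, sep = "\r")
  } else {
    if (is.null(records$source)) {
      stop("per_source deduplication requires a 'source' column",
        call. = FALSE
      )
    }
    key <- paste(records$compound_id, records$target_id, records$source,
      sep = "\r"
    )
  }
  med <- tapply(records$activity_um, key, aggregate_duplicates)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  pairs <- data.frame(
    compound_id = vapply(parts, `[`, "", 1L),
    target_id = vapply(parts, `[`, "", 2L),
    label = classify_activity(as.numeric(med), active_um, inactive_um),
    stringsAsFactors = FALSE
  )

  n_ambiguous <- sum(pairs$label == "ambiguous")
  pairs <- pairs[pairs$label != "ambiguous", , drop = FALSE]

  # Per-source aggregation can leave the same pair with both labels once
  # sources are merged; such contradictions are dropped outright.
  pair_key <- paste(pairs$compound_id, pairs$target_id, sep = "\r")
  n_contradictions <- 0L
  if (anyDuplicated(pair_key)) {
    n_labels <- tapply(pairs$label, pair_key, function(x) length(unique(x)))
    contradicted <- names(n_labels)[n_labels > 1L]
    n_contradictions <- length(contradicted)
    pairs <- pairs[!(pair_key %in% contradicted), , drop = FALSE]
    pairs <- pairs[!duplicated(paste(pairs$compound_id, pairs$target_id,
      sep = "\r"
    )), , drop = FALSE]
  }

  pairs <- pairs[order(pairs$compound_id, pairs$target_id), , drop = FALSE]
  rownames(pairs) <- NULL
  new_interaction_dataset(pairs, list(
    n_records = n_records,
    n_pairs = nrow(pairs),
    n_ambiguous_dropped = as.integer(n_ambiguous),
    n_contradictions_dropped = as.integer(n_contradictions)
  ))
}

new_interaction_dataset <- function(pairs, summary) {
  structure(list(pairs = pairs, summary = summary),
    class = "interaction_dataset"
  )
}

#' @export
print.interaction_dataset <- function(x, ...) {
  s <- x$summary
  cat(
    "Interaction dataset:", s$n_pairs, "labeled pairs (",
    sum(x$pairs$label == "active"), "active,",
    sum(x$pairs$label == "inactive"), "inactive )\n"
  )
  cat(
    "  from", s$n_records, "records;",
    s$n_ambiguous_dropped, "ambiguous and",
    s$n_contradictions_dropped, "contradictory pair(s) dropped\n"
  )
  invisible(x)
}

#' Active / inactive target sets of a compound
#'
#' @param dataset An `interaction_dataset`.
#' @param compound_id A single compound identifier.
#' @return Character vector of target accessions (possibly empty).
#' @export
active_targets <- function(dataset, compound_id) {
  p <- dataset$pairs
  p$target_id[p$compound_id == compound_id & p$label == "active"]
}

#' @rdname active_targets
#' @export
inactive_targets <- function(dataset, compound_id) {
  p <- dataset$pairs
  p$target_id[p$compound_id == compound_id & p$label == "inactive"]
}

#' Write an interaction dataset and its run summary
#'
#' Writes the labeled pairs as TSV (`compound_id  target_accession  label`)
#' and, if `summary_path` is given, the run summary as JSON.
#'
#' @param dataset An `interaction_dataset`.
#' @param path Output TSV path.
#' @param summary_path Optional JSON path for the run summary.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, summary_path = NULL) {
  out <- data.frame(
    compound_id = dataset$pairs$compound_id,
    target_accession = dataset$pairs$target_id,
    label = dataset$pairs$label,
    stringsAsFactors = FALSE
  )
  write_tsv_table(out, path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(dataset$summary, summary_path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a labeled interaction dataset written by [write_dataset()]
#'
#' @param path TSV with columns `compound_id`, `target_accession`, `label`.
#' @return An `interaction_dataset`.
#' @export
read_dataset <- function(path) {
  df <- read_tsv_table(path, c("compound_id", "target_accession", "label"))
  pairs <- data.frame(
    compound_id = df$compound_id,
    target_id = df$target_accession,
    label = df$label,
    stringsAsFactors = FALSE
  )
  if (!all(pairs$label %in% c("active", "inactive"))) {
    stop("labels must be 'active' or 'inactive'", call. = FALSE)
  }
  key <- paste(pairs$compound_id, pairs$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (compound, target) pairs in ", path, call. = FALSE)
  }
  new_interaction_dataset(pairs, list(
    n_records = nrow(pairs), n_pairs = nrow(pairs),
    n_ambiguous_dropped = 0L, n_contradictions_dropped = 0L
  ))
}
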