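# Core of the method: score compound -> domain-feature associations from
# active/inactive target sets, for individual compounds and compound
# clusters, for single domains and unordered domain pairs.
#
# For a compound and a candidate single domain d, each ACTIVE target counts
# as TP if it contains d (or, with a hierarchy, any domain sharing d's root)
# and FN otherwise; each INACTIVE target counts as FP if it contains d (or a
# same-root domain) and TN otherwise. Pair features require exact containment
# of both ids and never use hierarchy substitution.

#' Classification metrics from confusion counts
#'
#' Recall, precision, accuracy, F1, and Matthews correlation coefficient from
#' TP/FP/FN/TN. Any metric whose denominator is zero is defined as 0, so that
#' score thresholding stays total for all-positive or all-negative subjects.
#'
#' @param tp,fp,fn,tn Nonnegative integer vectors (recycled to common length).
#' @return Data frame with columns `recall`, `precision`, `accuracy`, `f1`,
#'   `mcc`.
#' @examples
#' compute_scores(3, 1, 0, 2) # recall 1, precision 0.75, mcc ~0.71
#' @export
compute_scores <- function(tp, fp, fn, tn) {
  n <- max(length(tp), length(fp), length(fn), length(tn))
  tp <- rep_len(as.numeric(tp), n)
  fp <- rep_len(as.numeric(fp), n)
  fn <- rep_len(as.numeric(fn), n)
  tn <- rep_len(as.numeric(tn), n)
  if (any(c(tp, fp, fn, tn) < 0)) {
    stop("confusion counts must be nonnegative", call. = FALSE)
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, 0)
  data.frame(
    recall = recall, precision = precision, accuracy = accuracy,
    f1 = f1, mcc = mcc
  )
}

#' Confusion counts of one compound-feature association
#'
#' @param actives,inactives Disjoint character vectors of protein accessions
#'   (the compound's active and inactive target sets). Every accession must be
#'   present in the proteome.
#' @param feature Feature string (`"IPRx"` single or `"IPRx+IPRy"` pair).
#' @param proteome A [proteome()].
#' @param hierarchy Optional [domain_hierarchy()]; when supplied, an active
#'   target containing a domain from the same hierarchy tree as a single
#'   feature counts as TP (instead of FN) and an inactive one as FP (instead
#'   of TN). Pair features ignore the hierarchy.
#' @return Named integer vector `c(tp, fp, fn, tn)` with `tp + fn ==
#'   length(actives)` and `fp + tn == length(inactives)`.
#' @export
count_confusion <- function(actives, inactives, feature, proteome,
                            hierarchy = NULL) {
  if (length(intersect(actives, inactives)) > 0L) {
    stop("active and inactive target sets overlap", call. = FALSE)
  }
  unknown <- setdiff(c(actives, inactives), names(proteome$domains))
  if (length(unknown) > 0L) {
    stop(
      "accession(s) not in proteome: ",
      paste(utils::head(unknown, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  parts <- feature_parts(feature)
  contains <- function(p) {
    dom <- proteome$domains[[p]]
    if (length(parts) == 2L) {
      all(parts %in% dom)
    } else if (!is.null(hierarchy)) {
      domain_root(hierarchy, parts) %in% domain_root(hierarchy, dom)
    } else {
      parts %in% dom
    }
  }
  tp <- sum(vapply(actives, contains, logical(1)))
  fp <- sum(vapply(inactives, contains, logical(1)))
  c(
    tp = as.integer(tp), fp = as.integer(fp),
    fn = length(actives) - as.integer(tp),
    tn = length(inactives) - as.integer(fp)
  )
}

#' Eligibility of a mapping subject
#'
#' Individual compounds need at least 3 active and 3 inactive targets;
#' compound clusters (pooling their members' targets) need at least 5 of
#' each. Subjects with fewer data points would produce spuriously high
#' mapping scores and are excluded up front.
#'
#' @param subject_kind `"compound"` or `"cluster"`.
#' @param n_active,n_inactive Nonnegative target counts.
#' @param min_compound_targets,min_cluster_targets Minimum per-side counts.
#' @return Logical.
#' @export
eligible <- function(subject_kind, n_active, n_inactive,
                     min_compound_targets = 3, min_cluster_targets = 5) {
  min_n <- switch(match.arg(subject_kind, c("compound", "cluster")),
    compound = min_compound_targets,
    cluster = min_cluster_targets
  )
  n_active >= min_n & n_inactive >= min_n
}

# Score every candidate feature of one subject. Candidates are limited to
# features occurring in at least one active target: a feature absent from all
# actives has tp = 0 and cannot pass any positive score threshold.
score_subject <- function(actives, inactives, proteome, hierarchy, features) {
  dom_act <- proteome$domains[actives]
  dom_ina <- proteome$domains[inactives]
  n_act <- length(actives)
  n_ina <- length(inactives)
  out <- list()

  if ("single" %in% features) {
    candidates <- sort(unique(unlist(dom_act, use.names = FALSE)))
    if (length(candidates) > 0L) {
      if (!is.null(hierarchy)) {
        act_tab <- table(unlist(
          lapply(dom_act, function(d) unique(domain_root(hierarchy, d))),
          use.names = FALSE
        ))
        ina_tab <- table(unlist(
          lapply(dom_ina, function(d) unique(domain_root(hierarchy, d))),
          use.names = FALSE
        ))
        keys <- domain_root(hierarchy, candidates)
      } else {
        act_tab <- table(unlist(dom_act, use.names = FALSE))
        ina_tab <- table(unlist(dom_ina, use.names = FALSE))
        keys <- candidates
      }
      tp <- as.integer(act_tab[keys])
      tp[is.na(tp)] <- 0L
      fp <- as.integer(ina_tab[keys])
      fp[is.na(fp)] <- 0L
      out$single <- data.frame(
        feature = candidates, tp = tp, fp = fp,
        fn = n_act - tp, tn = n_ina - fp,
        stringsAsFactors = FALSE
      )
    }
  }

  if ("pair" %in% features) {
    act_pairs <- lapply(dom_act, enumerate_domain_pairs)
    candidates <- sort(unique(unlist(act_pairs, use.names = FALSE)))
    if (length(candidates) > 0L) {
      act_tab <- table(unlist(act_pairs, use.names = FALSE))
      ina_tab <- table(unlist(lapply(dom_ina, enumerate_domain_pairs),
        use.names = FALSE
      ))
      tp <- as.integer(act_tab[candidates])
      tp[is.na(tp)] <- 0L
      fp <- as.integer(ina_tab[candidates])
      fp[is.na(fp)] <- 0L
      out$pair <- data.frame(
        feature = candidates, tp = tp, fp = fp,
        fn = n_act - tp, tn = n_ina - fp,
        stringsAsFactors = FALSE
      )
    }
  }

  if (length(out) == 0L) {
    return(NULL)
  }
  do.call(rbind, out)
}

empty_mappings <- function() {
  data.frame(
    subject_id = character(), subject_kind = character(),
    feature = character(),
    tp = integer(), fp = integer(), fn = integer(), tn = integer(),
    recall = numeric(), precision = numeric(), accuracy = numeric(),
    f1 = numeric(), mcc = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Score all compound-feature and cluster-feature associations
#'
#' For each eligible individual compound, and for each eligible compound
#' cluster (pooling member actives/inactives by union), scores every
#' candidate feature occurring in at least one active target. Cluster-derived
#' scores are propagated to every member compound. When a compound ends up
#' holding both an individual and a cluster-derived score for the same
#' feature, the one with the larger MCC is retained (the individual one on
#' ties).
#'
#' Targets missing from the proteome (no domain annotation) carry no domain
#' signal and are excluded from a subject's counts; a single warning reports
#' how many were skipped.
#'
#' @param dataset An [build_dataset()] `interaction_dataset`.
#' @param proteome A [proteome()].
#' @param hierarchy Optional [domain_hierarchy()] for hierarchy-aware single
#'   domain counting.
#' @param clusters Optional [cluster_compounds()] result; when supplied,
#'   cluster-based mappings are computed and merged in.
#' @param features Character subset of `c("single", "pair")`.
#' @param min_compound_targets,min_cluster_targets Eligibility minima, see
#'   [eligible()].
#' @return Data frame of raw (unfiltered) mappings with columns `subject_id`
#'   (compound id), `subject_kind` (`"compound"` or `"cluster"`, the origin
#'   of the retained score), `feature`, `tp`, `fp`, `fn`, `tn`, `recall`,
#'   `precision`, `accuracy`, `f1`, `mcc`.
#' @export
map_all <- function(dataset, proteome, hierarchy = NULL, clusters = NULL,
                    features = c("single", "pair"),
                    min_compound_targets = 3, min_cluster_targets = 5) {
  features <- match.arg(features, several.ok = TRUE)
  pairs <- dataset$pairs
  known <- pairs$target_id %in% names(proteome$domains)
  if (any(!known)) {
    warning(
      sum(!known),
      " dataset pair(s) with targets lacking domain annotation skipped",
      call. = FALSE
    )
    pairs <- pairs[known, , drop = FALSE]
  }
  act_by_cpd <- split(
    pairs$target_id[pairs$label == "active"],
    pairs$compound_id[pairs$label == "active"]
  )
  ina_by_cpd <- split(
    pairs$target_id[pairs$label == "inactive"],
    pairs$compound_id[pairs$label == "inactive"]
  )

  score_one <- function(actives, inactives, subject_kind) {
    counts <- score_subject(actives, inactives, proteome, hierarchy, features)
    if (is.null(counts)) {
      return(NULL)
    }
    cbind(
      subject_kind = subject_kind, counts,
      compute_scores(counts$tp, counts$fp, counts$fn, counts$tn),
      stringsAsFactors = FALSE
    )
  }

  rows <- list()
  for (cpd in union(names(act_by_cpd), names(ina_by_cpd))) {
    actives <- unique(act_by_cpd[[cpd]] %||% character())
    inactives <- unique(ina_by_cpd[[cpd]] %||% character())
    if (!eligible("compound", length(actives), length(inactives),
      min_compound_targets, min_cluster_targets
    )) {
      next
    }
    scored <- score_one(actives, inactives, "compound")
    if (!is.null(scored)) {
      rows[[length(rows) + 1L]] <- cbind(
        subject_id = cpd, scored,
        stringsAsFactors = FALSE
      )
    }
  }

  if (!is.null(clusters)) {
    n_conflicted <- 0L
    for (members in clusters) {
      actives <- unique(unlist(act_by_cpd[members], use.names = FALSE))
      inactives <- unique(unlist(ina_by_cpd[members], use.names = FALSE))
      conflicted <- intersect(actives, inactives)
      if (length(conflicted) > 0L) {
        # Pooling can put one target in both sets when members disagree.
        n_conflicted <- n_conflicted + length(conflicted)
        actives <- setdiff(actives, conflicted)
        inactives <- setdiff(inactives, conflicted)
      }
      if (!eligible("cluster", length(actives), length(inactives),
        min_compound_targets, min_cluster_targets
      )) {
        next
      }
      scored <- score_one(actives, inactives, "cluster")
      if (is.null(scored)) next
      for (member in members) {
        rows[[length(rows) + 1L]] <- cbind(
          subject_id = member, scored,
          stringsAsFactors = FALSE
        )
      }
    }
    if (n_conflicted > 0L) {
      warning(
        n_conflicted,
        " pooled cluster target(s) with conflicting member labels dropped",
        call. = FALSE
      )
    }
  }

  if (length(rows) == 0L) {
    return(empty_mappings())
  }
  mappings <- do.call(rbind, rows)

  # One score per (compound, feature): keep the max-MCC row, preferring the
  # compound's own evidence over a cluster-derived score on ties.
  kind_rank <- match(mappings$subject_kind, c("compound", "cluster"))
  ord <- order(
    mappings$subject_id, mappings$feature,
    -mappings$mcc, kind_rank
  )
  mappings <- mappings[ord, , drop = FALSE]
  dup <- duplicated(paste(mappings$subject_id, mappings$feature, sep = "\r"))
  mappings <- mappings[!dup, , drop = FALSE]
  mappings <- mappings[
    order(mappings$subject_id, mappings$feature), ,
    drop = FALSE
  ]
  rownames(mappings) <- NULL
  mappings[, names(empty_mappings())]
}

#' Filter mappings by a score threshold
#'
#' Keeps a mapping iff the minimum over the selected metrics is at least `t`.
#' The default applies the threshold to all five metrics (recall, precision,
#' accuracy, F1, and MCC), the strictest consistent reading; the metric list
#' is configurable.
#'
#' @param mappings A mapping data frame from [map_all()].
#' @param t Score threshold in `[0, 1]`.
#' @param metrics Character vector of metric columns to threshold on.
#' @return The filtered mapping data frame.
#' @export
threshold_filter <- function(mappings, t,
                             metrics = c(
                               "recall", "precision", "accuracy",
                               "f1", "mcc"
                             )) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop("threshold t must be a single value in [0, 1]", call. = FALSE)
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (nrow(mappings) == 0L) {
    return(mappings)
  }
  min_score <- do.call(pmin, mappings[metrics])
  out <- mappings[min_score >= t, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify domain-pair mappings against their constituent single mappings
#'
#' A pair mapping of a subject is `positive` when its MCC strictly exceeds
#' the best MCC among the subject's single-domain mappings to the pair's
#' constituents (a missing constituent mapping counts as score -1), `neutral`
#' when it equals that maximum (the second domain adds nothing detectable),
#' and `non_positive` otherwise. Only positive pairs carry information beyond
#' the single domains and survive to prediction.
#'
#' @param mappings Mapping data frame containing the pair rows to classify.
#' @param singles Mapping table to look the constituent single-domain scores
#'   up in; defaults to `mappings` itself. Passing the raw (unfiltered) table
#'   here compares each pair against all computed single scores even when the
#'   pair table has already been thresholded.
#' @return `mappings` with an added character column `pair_class` (`NA` for
#'   single-domain rows).
#' @export
classify_domain_pairs <- function(mappings, singles = mappings) {
  mappings$pair_class <- NA_character_
  is_pair <- vapply(mappings$feature, is_pair_feature, logical(1))
  if (!any(is_pair)) {
    return(mappings)
  }
  singles_pair <- vapply(singles$feature, is_pair_feature, logical(1))
  singles <- singles[!singles_pair, c("subject_id", "feature", "mcc")]
  single_key <- paste(singles$subject_id, singles$feature, sep = "\r")
  single_mcc <- stats::setNames(singles$mcc, single_key)
  pair_rows <- which(is_pair)
  for (i in pair_rows) {
    parts <- feature_parts(mappings$feature[i])
    keys <- paste(mappings$subject_id[i], parts, sep = "\r")
    best <- max(ifelse(is.na(single_mcc[keys]), -1, single_mcc[keys]))
    mappings$pair_class[i] <- if (mappings$mcc[i] > best) {
      "positive"
    } else if (mappings$mcc[i] == best) {
      "neutral"
    } else {
      "non_positive"
    }
  }
  mappings
}

#' Keep single-domain mappings and positive pair mappings only
#'
#' @param mappings Output of [classify_domain_pairs()] (or any mapping table;
#'   unclassified pair rows are classified first).
#' @return Mapping data frame where every pair row is `positive`.
#' @export
filter_positive_pairs <- function(mappings) {
  if (is.null(mappings$pair_class)) {
    mappings <- classify_domain_pairs(mappings)
  }
  keep <- is.na(mappings$pair_class) | mappings$pair_class == "positive"
  out <- mappings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a mapping table
#'
#' TSV with columns `subject_id  subject_kind  feature  tp  fp  fn  tn
#' recall  precision  accuracy  f1  mcc` (plus `pair_class` when present);
#' features serialized as `IPRx` or lexicographic `IPRx+IPRy`.
#'
#' @param mappings Mapping data frame.
#' @param path File path.
#' @return `path` invisibly (write) or the mapping data frame (read).
#' @export
write_mappings <- function(mappings, path) {
  write_tsv_table(mappings, path)
}

#' @rdname write_mappings
#' @export
read_mappings <- function(path) {
  df <- read_tsv_table(path, c(
    "subject_id", "subject_kind", "feature", "tp", "fp", "fn", "tn",
    "recall", "precision", "accuracy", "f1", "mcc"
  ))
  for (col in c("tp", "fp", "fn", "tn")) df[[col]] <- as.integer(df[[col]])
  for (col in c("recall", "precision", "accuracy", "f1", "mcc")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
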