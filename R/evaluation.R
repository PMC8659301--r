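# Benchmarking a compound-domain mapping set against a reference
# (gold-standard) set across score thresholds: retrieval confusion counts,
# classification metrics, coverage, coverage extension, and hypergeometric
# enrichment.

#' Read a reference compound-domain mapping set
#'
#' @param path TSV with columns `compound_id`, `domain_id` (identifiers
#'   already harmonized to the mapping set's vocabulary).
#' @return Data frame of unique reference pairs.
#' @export
read_reference <- function(path) {
  df <- read_tsv_table(path, c("compound_id", "domain_id"))
  df <- df[, c("compound_id", "domain_id")]
  df[!duplicated(paste(df$compound_id, df$domain_id, sep = "\r")), ,
    drop = FALSE
  ]
}

#' Coverage extension of a mapping set relative to a reference
#'
#' The fraction of the intersecting entity universe (the entities shared
#' between the raw mapping set and the reference) that the mapping set maps
#' but the reference does not: `(n_mapped - n_shared) / n_intersecting_total`.
#'
#' @param n_mapped Number of entities (domains or compounds) carrying a
#'   mapping at the current threshold.
#' @param n_shared Of those, the number also present in the reference pairs.
#' @param n_intersecting_total Total number of intersecting entities between
#'   the raw mapping set and the reference (the fixed denominator).
#' @return The coverage extension as a fraction.
#' @examples
#' coverage_extension(250, 50, 1043) # 0.1917...
#' @export
coverage_extension <- function(n_mapped, n_shared, n_intersecting_total) {
  assert_scalar_number(n_mapped, "n_mapped")
  assert_scalar_number(n_shared, "n_shared")
  assert_scalar_number(n_intersecting_total, "n_intersecting_total")
  if (n_shared > n_mapped) {
    stop("n_shared cannot exceed n_mapped", call. = FALSE)
  }
  if (n_intersecting_total <= 0) {
    stop("n_intersecting_total must be positive", call. = FALSE)
  }
  (n_mapped - n_shared) / n_intersecting_total
}

#' Fold enrichment and hypergeometric significance of retrieved mappings
#'
#' The enrichment score is the observed/expected ratio
#' `(m/n) / (M/N)`: the rate of reference ("true") pairs among retrieved
#' mappings relative to the rate expected when the same number of pairs is
#' drawn at random from the restricted universe. Significance is the
#' upper-tail hypergeometric probability `P(X >= m)` for
#' `X ~ Hypergeometric(N, M, n)`.
#'
#' @param m Retrieved mappings that are also reference pairs.
#' @param n Total retrieved mappings.
#' @param M Reference pairs inside the restricted universe.
#' @param N Size of the restricted universe (all compound x domain
#'   combinations over the retrieved compound and domain lists).
#' @return List with `score` (fold enrichment) and `p` (upper-tail p-value).
#' @export
enrichment <- function(m, n, M, N) {
  for (v in list(m = m, n = n, M = M, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
      v != round(v)) {
      stop("enrichment inputs must be single nonnegative integers",
        call. = FALSE
      )
    }
  }
  if (n <= 0 || M <= 0) {
    stop("n and M must be positive", call. = FALSE)
  }
  if (m > min(n, M) || n > N || M > N) {
    stop("inconsistent enrichment counts: need m <= min(n, M) <= N",
      call. = FALSE
    )
  }
  score <- (m / n) / (M / N)
  p <- stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  list(score = score, p = p)
}

#' Benchmark a mapping set against a reference at one threshold
#'
#' Applies [threshold_filter()] at `t` to the single-domain mappings, then
#' restricts the analysis to the compounds and domains occurring in both the
#' thresholded mapping set and the reference. Over the finite universe of all
#' (intersecting compound) x (intersecting domain) combinations: a pair found
#' in both sets is TP, reference-only is FN, mappings-only is FP, and neither
#' is TN; [compute_scores()] is applied to those counts. Coverage and
#' coverage extension are reported relative to the fixed intersecting totals
#' of the raw (unthresholded) mapping set, and fold enrichment uses the full
#' retrieved set's compound/domain lists as its universe.
#'
#' @param mappings Raw (unfiltered) mapping data frame from [map_all()]; pair
#'   features are ignored here since the reference pairs single domains.
#' @param reference Reference pair data frame (`compound_id`, `domain_id`).
#' @param t Score threshold in `[0, 1]`.
#' @param metrics Metric columns passed to [threshold_filter()].
#' @return One-row data frame: threshold, retrieved mapping/domain/compound
#'   counts, coverages and coverage extensions (percent of the intersecting
#'   totals), confusion counts, the five metrics, enrichment score, and
#'   p-value. When the thresholded set shares no compound or domain with the
#'   reference, counts and metrics are 0 and the row is flagged
#'   (`empty_intersection = TRUE`).
#' @export
benchmark_at_threshold <- function(mappings, reference, t,
                                   metrics = c(
                                     "recall", "precision", "accuracy",
                                     "f1", "mcc"
                                   )) {
  singles <- mappings[!vapply(mappings$feature, is_pair_feature, logical(1)), ,
    drop = FALSE
  ]
  ref_key <- paste(reference$compound_id, reference$domain_id, sep = "\r")

  # Fixed denominators: entities shared between the raw mapping set and the
  # reference, independent of t.
  total_domains <- length(intersect(singles$feature, reference$domain_id))
  total_compounds <- length(intersect(
    singles$subject_id, reference$compound_id
  ))

  retained <- threshold_filter(singles, t, metrics)
  n_mappings <- nrow(retained)
  map_domains <- unique(retained$feature)
  map_compounds <- unique(retained$subject_id)

  shared_domains <- intersect(map_domains, reference$domain_id)
  shared_compounds <- intersect(map_compounds, reference$compound_id)

  row <- data.frame(
    threshold = t,
    n_mappings = n_mappings,
    n_domains = length(map_domains),
    n_compounds = length(map_compounds),
    domain_coverage = if (total_domains > 0) {
      100 * length(shared_domains) / total_domains
    } else {
      0
    },
    compound_coverage = if (total_compounds > 0) {
      100 * length(shared_compounds) / total_compounds
    } else {
      0
    },
    domain_coverage_extension = if (total_domains > 0) {
      100 * coverage_extension(
        length(map_domains), length(shared_domains), total_domains
      )
    } else {
      0
    },
    compound_coverage_extension = if (total_compounds > 0) {
      100 * coverage_extension(
        length(map_compounds), length(shared_compounds), total_compounds
      )
    } else {
      0
    },
    tp = 0L, fp = 0L, fn = 0L, tn = 0L,
    recall = 0, precision = 0, accuracy = 0, f1 = 0, mcc = 0,
    enrichment = NA_real_, p_value = NA_real_,
    empty_intersection = FALSE,
    stringsAsFactors = FALSE
  )

  if (length(shared_domains) == 0L || length(shared_compounds) == 0L) {
    row$empty_intersection <- TRUE
    return(row)
  }

  # Fourfold partition of the intersecting cross-product universe.
  ret_key <- paste(retained$subject_id, retained$feature, sep = "\r")
  in_universe <- function(cpd, dom) {
    cpd %in% shared_compounds & dom %in% shared_domains
  }
  ret_in <- ret_key[in_universe(retained$subject_id, retained$feature)]
  ref_in <- ref_key[in_universe(reference$compound_id, reference$domain_id)]
  universe_size <- length(shared_compounds) * length(shared_domains)
  tp <- length(intersect(ret_in, ref_in))
  fp <- length(setdiff(ret_in, ref_in))
  fn <- length(setdiff(ref_in, ret_in))
  tn <- universe_size - tp - fp - fn
  row[c("tp", "fp", "fn", "tn")] <- list(tp, fp, fn, tn)
  row[c("recall", "precision", "accuracy", "f1", "mcc")] <-
    compute_scores(tp, fp, fn, tn)

  # Enrichment over the retrieved set's own compound x domain universe.
  if (n_mappings > 0L) {
    e_universe <- length(map_compounds) * length(map_domains)
    ref_in_ret_universe <- sum(
      reference$compound_id %in% map_compounds &
        reference$domain_id %in% map_domains
    )
    m_t <- sum(ret_key %in% ref_key)
    if (ref_in_ret_universe > 0L) {
      e <- enrichment(m_t, n_mappings, ref_in_ret_universe, e_universe)
      row$enrichment <- e$score
      row$p_value <- e$p
    }
  }
  row
}

#' Benchmark a mapping set across a grid of thresholds
#'
#' @inheritParams benchmark_at_threshold
#' @param thresholds Numeric vector of thresholds (default 0, 0.1, ..., 1).
#' @return Data frame with one [benchmark_at_threshold()] row per threshold.
#' @export
benchmark_mappings <- function(mappings, reference,
                               thresholds = seq(0, 1, by = 0.1),
                               metrics = c(
                                 "recall", "precision", "accuracy",
                                 "f1", "mcc"
                               )) {
  rows <- lapply(
    thresholds,
    function(t) benchmark_at_threshold(mappings, reference, t, metrics)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
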