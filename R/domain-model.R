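# Proteins as ordered domain annotations ("domain architectures"), unordered
# domain-pair enumeration ("bag of domains"), and hierarchy queries.

#' Construct a proteome from domain annotation hits
#'
#' @param hits Data frame with columns `accession`, `domain_id`, `start`,
#'   `end` (1-based inclusive residue coordinates). Hits are sorted by start
#'   within each protein. Positions are retained for provenance and
#'   architecture display but play no role in pair enumeration or containment,
#'   which use the unordered set of distinct domain ids ("bag of domains").
#' @return An object of class `proteome`: list with `hits` (the sorted
#'   annotation table) and `domains` (named list, accession -> character
#'   vector of distinct domain ids).
#' @export
proteome <- function(hits) {
  required <- c("accession", "domain_id", "start", "end")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop("hits lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  hits$start <- as.integer(hits$start)
  hits$end <- as.integer(hits$end)
  if (any(!nzchar(hits$domain_id)) || any(!nzchar(hits$accession))) {
    stop("empty accession or domain_id in annotations", call. = FALSE)
  }
  if (any(hits$start > hits$end) || any(hits$start < 1L)) {
    stop("domain hit coordinates must satisfy 1 <= start <= end",
      call. = FALSE
    )
  }
  hits <- hits[order(hits$accession, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  domains <- lapply(
    split(hits$domain_id, hits$accession),
    function(d) sort(unique(d))
  )
  structure(list(hits = hits, domains = domains), class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(
    "Proteome:", length(x$domains), "proteins,",
    length(unique(x$hits$domain_id)), "distinct domains,",
    nrow(x$hits), "domain hits\n"
  )
  invisible(x)
}

#' Read protein domain annotations from a tab-separated file
#'
#' Expects columns `accession`, `domain_id`, `start`, `end`, and optionally
#' `entry_type`. When `entry_type` is present only rows labeled `Domain` are
#' kept (case-insensitive), so that family- and site-type signature hits from
#' an InterPro-style export are excluded.
#'
#' @param path Path to the annotation TSV.
#' @return A [proteome()] object.
#' @export
read_domain_annotations <- function(path) {
  df <- read_tsv_table(path, c("accession", "domain_id", "start", "end"))
  if ("entry_type" %in% names(df)) {
    df <- df[tolower(df$entry_type) == "domain", , drop = FALSE]
  }
  proteome(df[, c("accession", "domain_id", "start", "end")])
}

#' Domain hierarchy: map every domain to the root of its tree
#'
#' InterPro-style hierarchies group related domain entries under distinct
#' trees. Two domains are considered interchangeable for hierarchy-aware
#' confusion counting when they share the same root. Domains absent from the
#' parent map are their own roots.
#'
#' @param parent Named character vector mapping `domain_id` to its parent id.
#'   Roots may be listed mapping to themselves or omitted.
#' @return An object of class `domain_hierarchy`: a named character vector
#'   mapping each listed domain id to its root.
#' @export
domain_hierarchy <- function(parent = character()) {
  if (length(parent) == 0L) {
    return(structure(character(), class = "domain_hierarchy"))
  }
  if (is.null(names(parent)) || any(!nzchar(names(parent)))) {
    stop("parent map must be a named character vector", call. = FALSE)
  }
  root <- vapply(names(parent), function(d) {
    seen <- character()
    cur <- d
    repeat {
      nxt <- unname(parent[cur])
      if (is.na(nxt) || !nzchar(nxt) || identical(nxt, cur)) {
        return(cur)
      }
      if (nxt %in% seen) {
        stop("cycle in domain hierarchy at ", d, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- nxt
    }
  }, "")
  structure(root, class = "domain_hierarchy")
}

#' Read a domain hierarchy table
#'
#' @param path TSV with columns `domain_id`, `parent_id`. Roots may be listed
#'   with themselves as parent or omitted entirely.
#' @return A [domain_hierarchy()] object.
#' @export
read_domain_hierarchy <- function(path) {
  df <- read_tsv_table(path, c("domain_id", "parent_id"))
  domain_hierarchy(stats::setNames(df$parent_id, df$domain_id))
}

#' Root of each domain in a hierarchy
#'
#' @param hierarchy A [domain_hierarchy()] or `NULL` (every domain is then its
#'   own root, i.e. hierarchy-aware substitution is disabled).
#' @param domain_ids Character vector of domain ids; ids not present in the
#'   hierarchy are their own roots.
#' @return Character vector of root ids, same length as `domain_ids`.
#' @export
domain_root <- function(hierarchy, domain_ids) {
  if (is.null(hierarchy) || length(hierarchy) == 0L) {
    return(domain_ids)
  }
  r <- unname(unclass(hierarchy)[domain_ids])
  ifelse(is.na(r), domain_ids, r)
}

#' Do two domains belong to the same hierarchy tree?
#'
#' @param d1,d2 Domain id vectors (recycled to common length).
#' @inheritParams domain_root
#' @return Logical vector: `TRUE` where the two domains share a root.
#' @export
same_hierarchy <- function(d1, d2, hierarchy = NULL) {
  domain_root(hierarchy, d1) == domain_root(hierarchy, d2)
}

#' Canonical serialization of a domain feature
#'
#' A feature is either a single domain id, serialized as the id itself, or an
#' unordered pair of two distinct ids, serialized lexicographically as
#' `"A+B"`. Homotypic pairs (the same id twice) are rejected.
#'
#' @param ids Character vector of one or two domain ids.
#' @return The canonical feature string.
#' @export
domain_feature <- function(ids) {
  ids <- unique(as.character(ids))
  if (length(ids) == 1L) {
    return(ids)
  }
  if (length(ids) != 2L) {
    stop("a domain feature holds one id or two distinct ids", call. = FALSE)
  }
  paste(sort(ids), collapse = "+")
}

#' @rdname domain_feature
#' @param feature A feature string as produced by [domain_feature()].
#' @return For `feature_parts()`, the character vector of constituent ids; for
#'   `is_pair_feature()`, a logical vector.
#' @export
feature_parts <- function(feature) {
  strsplit(feature, "+", fixed = TRUE)[[1]]
}

#' @rdname domain_feature
#' @export
is_pair_feature <- function(feature) {
  grepl("+", feature, fixed = TRUE)
}

#' Enumerate unordered domain pairs of a protein
#'
#' All unordered pairs of distinct domain ids, ignoring order, copy number,
#' and sequence positions; a protein with k distinct domain ids yields
#' k(k-1)/2 pairs. Self-pairs (two copies of the same id) are excluded.
#'
#' @param domain_ids Character vector of domain ids (repeats allowed).
#' @return Character vector of canonical `"A+B"` pair features (possibly
#'   empty).
#' @examples
#' enumerate_domain_pairs(c("A", "B", "C")) # "A+B" "A+C" "B+C"
#' enumerate_domain_pairs(c("A", "A", "B")) # "A+B"
#' @export
enumerate_domain_pairs <- function(domain_ids) {
  d <- sort(unique(as.character(domain_ids)))
  k <- length(d)
  if (k < 2L) {
    return(character())
  }
  idx <- utils::combn(k, 2L)
  paste(d[idx[1L, ]], d[idx[2L, ]], sep = "+")
}

#' Proteins containing a domain feature
#'
#' For a single-domain feature, the proteins whose domain-id set contains the
#' id; for a pair feature, the proteins containing both ids (exact ids, no
#' hierarchy substitution).
#'
#' @param proteome A [proteome()].
#' @param feature A feature string (`"IPRx"` or `"IPRx+IPRy"`).
#' @return Character vector of protein accessions.
#' @export
proteins_with_feature <- function(proteome, feature) {
  parts <- feature_parts(feature)
  hit <- vapply(
    proteome$domains,
    function(d) all(parts %in% d),
    logical(1)
  )
  names(proteome$domains)[hit]
}
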