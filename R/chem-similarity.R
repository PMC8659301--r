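# Circular fingerprints (ECFP4 via OpenBabel), Tanimoto similarity,
# seed-centered compound clusters, and fixed-threshold neighbor queries.

#' Compute ECFP4 fingerprints for a set of compounds
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2), computed from
#' SMILES through OpenBabel and folded to a fixed-length bit vector (4096
#' bits, OpenBabel's fold length). Fingerprints are deterministic and
#' invariant to the SMILES spelling of a molecule (canonical vs kekulized).
#' Compounds whose SMILES cannot be parsed are excluded with a warning.
#'
#' @param compounds Data frame with columns `compound_id` and `smiles`, or two
#'   character vectors via `compound_id=`/`smiles=`.
#' @param compound_id,smiles Alternative vector interface.
#' @return An object of class `fingerprint_set`: a binary (0/1) integer matrix
#'   with one row per successfully fingerprinted compound, row names the
#'   compound ids, and attribute `nbits` the fold length.
#' @export
compute_fingerprints <- function(compounds = NULL, compound_id = NULL,
                                 smiles = NULL) {
  if (!is.null(compounds)) {
    compound_id <- compounds$compound_id
    smiles <- compounds$smiles
  }
  if (length(compound_id) != length(smiles)) {
    stop("compound_id and smiles must have equal length", call. = FALSE)
  }
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound ids in fingerprint input", call. = FALSE)
  }
  if (length(compound_id) == 0L) {
    m <- matrix(integer(), nrow = 0, ncol = 0)
    return(structure(m, nbits = NA_integer_, class = "fingerprint_set"))
  }

  rows <- vector("list", length(compound_id))
  ok <- logical(length(compound_id))
  for (i in seq_along(smiles)) {
    fp <- tryCatch(
      suppressWarnings(ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smiles[[i]], identity), "ECFP4"
      )),
      error = function(e) NULL
    )
    if (!is.null(fp) && length(fp) > 0 && sum(fp) > 0) {
      rows[[i]] <- as.integer(fp > 0)
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(
      sum(!ok), " compound(s) with unparseable or empty SMILES excluded: ",
      paste(utils::head(compound_id[!ok], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  if (!any(ok)) {
    m <- matrix(integer(), nrow = 0, ncol = 0)
    return(structure(m, nbits = NA_integer_, class = "fingerprint_set"))
  }
  m <- do.call(rbind, rows[ok])
  rownames(m) <- compound_id[ok]
  structure(m, nbits = ncol(m), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(
    "Fingerprint set:", nrow(x), "compounds x", attr(x, "nbits"),
    "bits (ECFP4)\n"
  )
  invisible(x)
}

#' Tanimoto coefficient between two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both vectors are all-zero, so a
#' pair of featureless molecules is never spuriously clustered.
#'
#' @param a,b Binary vectors of equal length (0/1 or logical).
#' @return A similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints have different lengths", call. = FALSE)
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) {
    return(0)
  }
  sum(a & b) / union
}

#' Pairwise Tanimoto similarity matrix of a fingerprint set
#'
#' @param fps A `fingerprint_set`.
#' @return Symmetric numeric matrix of similarities with compound ids as
#'   dimnames. All-zero rows (excluded at fingerprinting) cannot occur.
#' @export
tanimoto_matrix <- function(fps) {
  m <- unclass(fps)
  attr(m, "nbits") <- NULL
  if (nrow(m) == 0L) {
    return(matrix(numeric(), 0, 0))
  }
  inter <- tcrossprod(m)
  counts <- diag(inter)
  uni <- outer(counts, counts, `+`) - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}

#' Seed-centered compound clusters at a Tanimoto threshold
#'
#' One cluster per seed compound: the seed together with every compound whose
#' Tanimoto similarity to the seed is at least `threshold`. Clusters overlap
#' by construction and singletons are allowed (they are removed later by the
#' cluster-eligibility filter). With `mode = "connected_components"` the
#' threshold graph's connected components are returned instead (disjoint
#' clusters keyed by their lexicographically first member).
#'
#' @param fps A `fingerprint_set`.
#' @param threshold Tanimoto threshold in (0, 1]; default 0.7.
#' @param mode `"seed"` (default) or `"connected_components"`.
#' @return A named list mapping seed id to the character vector of member ids
#'   (seed included), of class `compound_clusters`.
#' @export
cluster_compounds <- function(fps, threshold = 0.7,
                              mode = c("seed", "connected_components")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  sim <- tanimoto_matrix(fps)
  ids <- rownames(sim)
  if (length(ids) == 0L) {
    return(structure(list(), class = "compound_clusters"))
  }
  adj <- sim >= threshold
  diag(adj) <- TRUE
  if (mode == "seed") {
    clusters <- lapply(seq_along(ids), function(i) ids[adj[i, ]])
    names(clusters) <- ids
  } else {
    comp <- seq_along(ids)
    repeat {
      nxt <- apply(adj, 1L, function(row) min(comp[row]))
      if (identical(nxt, comp)) break
      comp <- nxt
    }
    clusters <- lapply(
      split(ids, comp),
      function(members) sort(members)
    )
    names(clusters) <- vapply(clusters, `[`, "", 1L)
  }
  structure(clusters, class = "compound_clusters")
}

#' @export
print.compound_clusters <- function(x, ...) {
  sizes <- lengths(x)
  cat(
    "Compound clusters:", length(x), "clusters; sizes",
    if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "0", "\n"
  )
  invisible(x)
}

#' Compounds similar to a query at a Tanimoto threshold
#'
#' @param query A compound id present in `fps`.
#' @param fps A `fingerprint_set`.
#' @param threshold Minimum Tanimoto similarity (default 0.8, the propagation
#'   threshold).
#' @return Character vector of compound ids with similarity `>= threshold`,
#'   excluding the query itself.
#' @export
similar_compounds <- function(query, fps, threshold = 0.8) {
  m <- unclass(fps)
  if (!query %in% rownames(m)) {
    stop("unknown query compound: ", query, call. = FALSE)
  }
  q <- m[query, ]
  inter <- as.vector(m %*% q)
  uni <- rowSums(m) + sum(q) - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  ids <- rownames(m)[sim >= threshold]
  setdiff(ids, query)
}

#' Read a compound table (`compound_id  smiles`)
#'
#' @param path TSV with header columns `compound_id` and `smiles`.
#' @return Data frame with those two columns.
#' @export
read_compounds <- function(path) {
  df <- read_tsv_table(path, c("compound_id", "smiles"))
  df[, c("compound_id", "smiles")]
}
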