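# Fixture builders shared across test files.

# A proteome from a named list accession -> character vector of domain ids;
# fake but valid coordinates.
make_proteome <- function(domain_sets) {
  hits <- do.call(rbind, lapply(names(domain_sets), function(acc) {
    d <- domain_sets[[acc]]
    data.frame(
      accession = acc, domain_id = d,
      start = seq(1, by = 100, length.out = length(d)),
      end = seq(50, by = 100, length.out = length(d)),
      stringsAsFactors = FALSE
    )
  }))
  proteome(hits)
}

# A fingerprint_set from a raw 0/1 matrix with compound ids as row names.
make_fps <- function(mat, ids = rownames(mat)) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  structure(mat, nbits = ncol(mat), class = "fingerprint_set")
}

# An interaction dataset straight from labeled pairs.
make_dataset <- function(compound_id, target_id, label) {
  records <- data.frame(
    compound_id = compound_id, target_id = target_id,
    activity_um = ifelse(label == "active", 1, 100),
    source = "fixture", stringsAsFactors = FALSE
  )
  build_dataset(records)
}

# The KDM-subfamily worked case: one compound, three active targets carrying
# both domains of interest, one inactive carrying only the first, one only
# the second, one neither.
kdm_fixture <- function() {
  prot <- make_proteome(list(
    KDM4C = c("IPR003349", "IPR001965", "IPR000001"),
    KDM5C = c("IPR003349", "IPR001965"),
    KDM4A = c("IPR003349", "IPR001965", "IPR000002"),
    KDM4E = c("IPR003349", "IPR000003"),
    KDM2A = c("IPR001965", "IPR000004"),
    KDM6B = c("IPR000005", "IPR000006")
  ))
  list(
    proteome = prot,
    actives = c("KDM4C", "KDM5C", "KDM4A"),
    inactives = c("KDM4E", "KDM2A", "KDM6B")
  )
}

# Random small synthetic world used by property-style loops.
small_world <- function(seed, ...) {
  generate_world(world_config(
    seed = seed,
    n_domains = 12L, n_hierarchy_roots = 9L,
    n_proteins = 40L, max_domains_per_protein = 3L,
    n_compounds = 12L, planted_associations = 5L,
    actives_per_association = 4L, inactives_per_association = 4L,
    decoy_targets_per_side = 4L,
    ...
  ))
}
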