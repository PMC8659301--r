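# Deterministic generator of synthetic chemogenomics worlds with planted
# compound-domain associations, so that every pipeline stage is testable with
# known ground truth and no external downloads.

# Drug-like SMILES scaffolds; each ends in an atom with a free valence so a
# substituent token can be appended by concatenation. Same-scaffold compounds
# with small substituent edits form high-Tanimoto neighborhoods; different
# scaffolds are dissimilar.
smiles_templates <- c(
  "CC(=O)Nc1ccccc1",
  "O=C(O)c1ccccc1",
  "c1ccc2ncccc2c1",
  "c1ccc(cc1)S(=O)(=O)N",
  "c1ccc(cc1)C(=O)NCC",
  "Clc1ccccc1CN",
  "c1ccnc(c1)NC(=O)C",
  "O=C1CCCCC1",
  "c1csc(n1)C",
  "c1ccc(cc1)OCC",
  "CC(C)Cc1ccccc1",
  "c1ccc(cc1)C(=O)OC",
  "N#Cc1ccccc1",
  "OCC(O)c1ccccc1",
  "c1ccc(cc1)CCN",
  "Fc1ccc(cc1)C(=O)N",
  "c1ccc2c(c1)cccc2",
  "CC(N)c1ccccc1",
  "c1ccc(cc1)NC(=O)CC",
  "CCOc1ccccc1C"
)

smiles_substituents <- c(
  "", "C", "CC", "CCC", "O", "OC", "N", "NC", "Cl", "Br",
  "F", "C(=O)O", "C(=O)N", "OCC", "C#N", "S", "SC", "CO", "CN", "CCO"
)

#' Configuration of a synthetic chemogenomics world
#'
#' Defaults describe a desk-scale world: 30 domains under 24 hierarchy roots,
#' 100 proteins carrying 1--4 domains each, 50 compounds of which half carry a
#' planted domain association backed by 6 active and 6 inactive targets.
#' Activity values are drawn log-normally around 1 uM (actives) and 100 uM
#' (inactives), so the 10/20 uM classification band separates the two cleanly
#' at the default spread.
#'
#' @param seed Integer seed; the world is reproducible given the seed.
#' @param n_domains,n_hierarchy_roots,n_proteins,n_compounds World sizes.
#' @param max_domains_per_protein Each protein carries 1..this many distinct
#'   domains.
#' @param planted_associations Number of ground-truth (compound, domain)
#'   associations; at most one per compound.
#' @param actives_per_association,inactives_per_association Targets backing
#'   each planted association (before noise); must satisfy the compound
#'   eligibility minimum of 3 each.
#' @param decoy_targets_per_side Active and inactive record count given to
#'   each unplanted (decoy) compound, against randomly drawn proteins.
#' @param active_mu,inactive_mu Log-normal location parameters (uM) for the
#'   two activity bands.
#' @param sigma Log-scale standard deviation of the activity draws.
#' @param label_noise Fraction of records whose value is flipped into the
#'   opposite band.
#' @param ambiguous_fraction Fraction of records redrawn uniformly inside the
#'   discarded 10--20 uM band.
#' @param n_pathways Number of pathway ids proteins are assigned to.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_domains = 30L,
                         n_hierarchy_roots = 24L,
                         n_proteins = 100L,
                         max_domains_per_protein = 4L,
                         n_compounds = 50L,
                         planted_associations = 25L,
                         actives_per_association = 6L,
                         inactives_per_association = 6L,
                         decoy_targets_per_side = 8L,
                         active_mu = 1,
                         inactive_mu = 100,
                         sigma = 0.75,
                         label_noise = 0,
                         ambiguous_fraction = 0.02,
                         n_pathways = 6L) {
  cfg <- list(
    seed = as.integer(seed),
    n_domains = as.integer(n_domains),
    n_hierarchy_roots = as.integer(n_hierarchy_roots),
    n_proteins = as.integer(n_proteins),
    max_domains_per_protein = as.integer(max_domains_per_protein),
    n_compounds = as.integer(n_compounds),
    planted_associations = as.integer(planted_associations),
    actives_per_association = as.integer(actives_per_association),
    inactives_per_association = as.integer(inactives_per_association),
    decoy_targets_per_side = as.integer(decoy_targets_per_side),
    active_mu = active_mu,
    inactive_mu = inactive_mu,
    sigma = sigma,
    label_noise = label_noise,
    ambiguous_fraction = ambiguous_fraction,
    n_pathways = as.integer(n_pathways)
  )
  counts <- c(
    "n_domains", "n_hierarchy_roots", "n_proteins",
    "max_domains_per_protein", "n_compounds", "n_pathways",
    "actives_per_association", "inactives_per_association",
    "decoy_targets_per_side"
  )
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop(nm, " must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$planted_associations < 0L ||
    cfg$planted_associations > cfg$n_compounds) {
    stop("planted_associations must be in [0, n_compounds]", call. = FALSE)
  }
  if (cfg$n_hierarchy_roots > cfg$n_domains) {
    stop("n_hierarchy_roots cannot exceed n_domains", call. = FALSE)
  }
  if (cfg$max_domains_per_protein > cfg$n_domains) {
    stop("max_domains_per_protein cannot exceed n_domains", call. = FALSE)
  }
  if (cfg$actives_per_association < 3L ||
    cfg$inactives_per_association < 3L) {
    stop("planted associations must satisfy compound eligibility (>= 3)",
      call. = FALSE
    )
  }
  if (cfg$label_noise < 0 || cfg$label_noise >= 1) {
    stop("label_noise must be in [0, 1)", call. = FALSE)
  }
  if (cfg$ambiguous_fraction < 0 || cfg$ambiguous_fraction > 1) {
    stop("ambiguous_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$active_mu <= 0 || cfg$inactive_mu <= 0 || cfg$sigma <= 0) {
    stop("activity distribution parameters must be positive", call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

# Log-normal draw constrained to one activity band.
draw_in_band <- function(n, mu, sigma, lower = 0, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in 1:100) {
      v <- stats::rlnorm(1, meanlog = log(mu), sdlog = sigma)
      if (v > lower && v < upper) break
    }
    if (!(v > lower && v < upper)) {
      v <- if (is.finite(upper)) (lower + upper) / 2 else lower * 2
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic chemogenomics world
#'
#' Builds a proteome with a flat domain hierarchy, compounds with generated
#' SMILES, and bioactivity records realizing the planted associations: each
#' planted (compound, domain) pair receives active-band records against
#' proteins containing the domain and inactive-band records against proteins
#' carrying no domain from the domain's hierarchy tree. Unplanted (decoy)
#' compounds receive records against randomly drawn proteins, split evenly
#' between the two bands, so they are score-eligible but carry no domain
#' signal. Label noise flips a record's band; the ambiguous fraction redraws
#' a record inside the discarded 10--20 uM window.
#'
#' @param cfg A [world_config()].
#' @return An object of class `synthetic_world`: list with `config`,
#'   `proteome`, `hierarchy`, `compounds` (data frame `compound_id`,
#'   `smiles`), `records` (bioactivity data frame), `truth` (planted
#'   `compound_id`/`domain_id` pairs), and `pathways` (protein-to-pathway
#'   table).
#' @export
generate_world <- function(cfg = world_config()) {
  if (!inherits(cfg, "world_config")) {
    stop("cfg must be a world_config()", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(cfg$seed)

  domain_ids <- sprintf("IPR%06d", seq_len(cfg$n_domains))
  roots <- domain_ids[seq_len(cfg$n_hierarchy_roots)]
  parent <- stats::setNames(
    c(
      roots,
      if (cfg$n_domains > cfg$n_hierarchy_roots) {
        sample(roots, cfg$n_domains - cfg$n_hierarchy_roots, replace = TRUE)
      }
    ),
    domain_ids
  )
  hierarchy <- domain_hierarchy(parent)

  accessions <- sprintf("PROT%05d", seq_len(cfg$n_proteins))
  protein_domains <- lapply(seq_len(cfg$n_proteins), function(i) {
    k <- sample.int(cfg$max_domains_per_protein, 1L)
    sample(domain_ids, k)
  })
  hits <- do.call(rbind, lapply(seq_len(cfg$n_proteins), function(i) {
    d <- protein_domains[[i]]
    len <- sample(60:150, length(d), replace = TRUE)
    gaps <- sample(5:40, length(d), replace = TRUE)
    start <- cumsum(gaps) + c(0, cumsum(len))[seq_along(d)]
    data.frame(
      accession = accessions[i], domain_id = d,
      start = start, end = start + len - 1L,
      stringsAsFactors = FALSE
    )
  }))
  world_proteome <- proteome(hits)
  domain_sets <- world_proteome$domains[accessions]
  root_sets <- lapply(domain_sets, function(d) {
    unique(domain_root(hierarchy, d))
  })

  compound_ids <- sprintf("CPD%05d", seq_len(cfg$n_compounds))
  n_templates <- length(smiles_templates)
  smiles <- paste0(
    smiles_templates[((seq_len(cfg$n_compounds) - 1L) %% n_templates) + 1L],
    smiles_substituents[
      (((seq_len(cfg$n_compounds) - 1L) %/% n_templates) %%
        length(smiles_substituents)) + 1L
    ]
  )
  compounds <- data.frame(
    compound_id = compound_ids, smiles = smiles,
    stringsAsFactors = FALSE
  )

  # Domains plantable for an association: enough proteins carry the exact
  # domain (actives) and enough carry nothing from its hierarchy tree
  # (inactives), so eligibility holds by construction before noise.
  with_domain <- lapply(domain_ids, function(d) {
    accessions[vapply(domain_sets, function(s) d %in% s, logical(1))]
  })
  names(with_domain) <- domain_ids
  without_root <- lapply(domain_ids, function(d) {
    r <- domain_root(hierarchy, d)
    accessions[!vapply(root_sets, function(s) r %in% s, logical(1))]
  })
  names(without_root) <- domain_ids
  plantable <- domain_ids[
    lengths(with_domain) >= cfg$actives_per_association &
      lengths(without_root) >= cfg$inactives_per_association
  ]
  if (cfg$planted_associations > 0L && length(plantable) == 0L) {
    stop(
      "infeasible configuration: no domain has enough hosting and ",
      "domain-free proteins to plant an association",
      call. = FALSE
    )
  }

  planted_compounds <- compound_ids[seq_len(cfg$planted_associations)]
  truth <- data.frame(
    compound_id = planted_compounds,
    domain_id = if (cfg$planted_associations > 0L) {
      sample(plantable, cfg$planted_associations, replace = TRUE)
    } else {
      character()
    },
    stringsAsFactors = FALSE
  )

  rec <- list()
  add_records <- function(cpd, smi, targets, band) {
    values <- if (band == "active") {
      draw_in_band(length(targets), cfg$active_mu, cfg$sigma, upper = 10)
    } else {
      draw_in_band(length(targets), cfg$inactive_mu, cfg$sigma, lower = 20)
    }
    data.frame(
      compound_id = cpd, smiles = smi, target_id = targets,
      activity_um = values, source = "synthetic",
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(truth))) {
    cpd <- truth$compound_id[i]
    d <- truth$domain_id[i]
    smi <- compounds$smiles[match(cpd, compounds$compound_id)]
    actives <- sample(with_domain[[d]], cfg$actives_per_association)
    inactives <- sample(without_root[[d]], cfg$inactives_per_association)
    rec[[length(rec) + 1L]] <- add_records(cpd, smi, actives, "active")
    rec[[length(rec) + 1L]] <- add_records(cpd, smi, inactives, "inactive")
  }
  for (cpd in setdiff(compound_ids, planted_compounds)) {
    smi <- compounds$smiles[match(cpd, compounds$compound_id)]
    n_side <- cfg$decoy_targets_per_side
    targets <- sample(accessions, 2L * n_side)
    rec[[length(rec) + 1L]] <-
      add_records(cpd, smi, targets[seq_len(n_side)], "active")
    rec[[length(rec) + 1L]] <-
      add_records(cpd, smi, targets[n_side + seq_len(n_side)], "inactive")
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL

  # Ambiguous injection, then band flips on the remaining records.
  n <- nrow(records)
  is_ambiguous <- stats::runif(n) < cfg$ambiguous_fraction
  records$activity_um[is_ambiguous] <- stats::runif(sum(is_ambiguous), 10, 20)
  flip <- !is_ambiguous & stats::runif(n) < cfg$label_noise
  if (any(flip)) {
    was_active <- records$activity_um < 10 & flip
    was_inactive <- records$activity_um > 20 & flip
    records$activity_um[was_active] <- draw_in_band(
      sum(was_active), cfg$inactive_mu, cfg$sigma,
      lower = 20
    )
    records$activity_um[was_inactive] <- draw_in_band(
      sum(was_inactive), cfg$active_mu, cfg$sigma,
      upper = 10
    )
  }

  pathway_ids <- sprintf("path%03d", seq_len(cfg$n_pathways))
  pathways <- do.call(rbind, lapply(accessions, function(acc) {
    k <- sample.int(2L, 1L)
    data.frame(
      target_accession = acc,
      pathway_id = sample(pathway_ids, min(k, cfg$n_pathways)),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(
      config = cfg,
      proteome = world_proteome,
      hierarchy = hierarchy,
      compounds = compounds,
      records = records,
      truth = truth,
      pathways = pathways
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(
    "Synthetic world (seed", x$config$seed, "):",
    nrow(x$compounds), "compounds,",
    length(x$proteome$domains), "proteins,",
    x$config$n_domains, "domains,",
    nrow(x$truth), "planted associations,",
    nrow(x$records), "bioactivity records\n"
  )
  invisible(x)
}

#' Write a synthetic world as pipeline input files
#'
#' Writes the five external-interface files consumed by the pipeline:
#' `bioactivity.tsv`, `annotations.tsv` (with an `entry_type` column, all
#' `Domain`), `hierarchy.tsv`, `reference.tsv` (the planted truth, usable as
#' a benchmark reference), and `pathways.tsv`.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the five file paths, invisibly.
#' @export
world_to_inputs <- function(world, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    bioactivity = file.path(dir, "bioactivity.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    reference = file.path(dir, "reference.tsv"),
    pathways = file.path(dir, "pathways.tsv")
  )
  write_tsv_table(
    data.frame(
      compound_id = world$records$compound_id,
      smiles = world$records$smiles,
      target_accession = world$records$target_id,
      activity_um = world$records$activity_um,
      source = world$records$source,
      stringsAsFactors = FALSE
    ),
    paths["bioactivity"]
  )
  write_tsv_table(
    cbind(world$proteome$hits, entry_type = "Domain"),
    paths["annotations"]
  )
  h <- unclass(world$hierarchy)
  write_tsv_table(
    data.frame(
      domain_id = names(h), parent_id = unname(h),
      stringsAsFactors = FALSE
    ),
    paths["hierarchy"]
  )
  write_tsv_table(world$truth, paths["reference"])
  write_tsv_table(world$pathways, paths["pathways"])
  invisible(paths)
}
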