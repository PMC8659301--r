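mapping_row <- function(subject, feature) {
  cbind(
    data.frame(
      subject_id = subject, subject_kind = "compound", feature = feature,
      tp = 3L, fp = 0L, fn = 0L, tn = 3L, stringsAsFactors = FALSE
    ),
    compute_scores(3, 0, 0, 3)
  )
}

test_that("predictions are the containment cross product with merged provenance", {
  prot <- make_proteome(list(
    P1 = c("d", "e"), P2 = "d", P3 = c("d", "f"), P4 = "g", P5 = c("e", "f")
  ))
  one <- predict_from_mappings(mapping_row("c1", "d"), prot)
  expect_equal(nrow(one), 3L)
  expect_setequal(one$target_accession, c("P1", "P2", "P3"))
  expect_true(all(one$features == "d"))
  expect_true(all(is.na(one$via_compound)))

  # two features of one compound licensing the same protein merge
  two <- predict_from_mappings(
    rbind(mapping_row("c1", "d"), mapping_row("c1", "e")), prot
  )
  p1 <- two[two$target_accession == "P1", ]
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$features, "d;e")

  # 2 compounds x {2, 3} proteins sharing one pair -> 4 unique predictions
  toy <- predict_from_mappings(
    rbind(mapping_row("c1", "d+e"), mapping_row("c2", "d+f")),
    make_proteome(list(
      Q1 = c("d", "e"), Q2 = c("d", "e", "f"), Q3 = c("d", "f")
    ))
  )
  expect_equal(nrow(toy), 4L)
  expect_setequal(
    paste(toy$compound_id, toy$target_accession),
    c("c1 Q1", "c1 Q2", "c2 Q2", "c2 Q3")
  )

  # brute-force cross product on random worlds
  for (s in 1:3) {
    w <- small_world(s)
    ds <- build_dataset(w$records)
    m <- suppressWarnings(map_all(ds, w$proteome))
    f <- threshold_filter(m, 0.5)
    pred <- predict_from_mappings(f, w$proteome)
    expected <- unique(unlist(lapply(seq_len(nrow(f)), function(i) {
      paste(f$subject_id[i],
        proteins_with_feature(w$proteome, f$feature[i]),
        sep = "\r"
      )
    })))
    expect_setequal(
      paste(pred$compound_id, pred$target_accession, sep = "\r"),
      expected
    )
  }
})

test_that("similarity extension is a single monotone round", {
  prot <- make_proteome(list(P1 = "d", P2 = "d"))
  pred <- predict_from_mappings(mapping_row("c1", "d"), prot)

  a <- c(rep(1L, 12), rep(0L, 8))
  near <- c(rep(1L, 11), rep(0L, 9)) # 11/12 to a
  far <- c(rep(0L, 12), rep(1L, 8)) # 0 to a
  fps <- make_fps(rbind(c1 = a, c_near = near, c_far = far))

  ext <- extend_by_similarity(pred, fps, 0.8)
  expect_true(all(
    paste(pred$compound_id, pred$target_accession) %in%
      paste(ext$compound_id, ext$target_accession)
  ))
  new_rows <- ext[ext$compound_id == "c_near", ]
  expect_equal(nrow(new_rows), 2L) # both targets of c1
  expect_true(all(new_rows$via_compound == "c1"))
  expect_false("c_far" %in% ext$compound_id)
  # no transitive chaining: c_near's neighbors are not consulted
  expect_equal(nrow(ext), 4L)

  # no neighbor above threshold: unchanged
  expect_identical(extend_by_similarity(pred, fps, 1.0), pred)

  # a neighbor already predicted on its own merges rather than duplicating
  both <- rbind(pred, predict_from_mappings(mapping_row("c_near", "d"), prot))
  both <- domainmapr:::merge_predictions(both)
  ext2 <- extend_by_similarity(both, fps, 0.8)
  key <- paste(ext2$compound_id, ext2$target_accession)
  expect_false(anyDuplicated(key) > 0)
  merged <- ext2[ext2$compound_id == "c_near" &
    ext2$target_accession == "P1", ]
  expect_equal(merged$via_compound, "c1") # provenance accumulated

  # missing fingerprint: warning, compound skipped
  expect_warning(
    same <- extend_by_similarity(pred, make_fps(rbind(other = a)), 0.8),
    "without fingerprints"
  )
  expect_identical(same, pred)
})

test_that("known pairs of either label are removed", {
  prot <- make_proteome(list(P1 = "d", P2 = "d", P3 = "d"))
  ds <- make_dataset(
    c("c1", "c1"), c("P1", "P2"), c("active", "inactive")
  )
  pred <- predict_from_mappings(mapping_row("c1", "d"), prot)
  kept <- remove_known(pred, ds)
  expect_equal(kept$target_accession, "P3")
  # disjointness invariant
  expect_length(
    intersect(
      paste(kept$compound_id, kept$target_accession),
      paste(ds$pairs$compound_id, ds$pairs$target_id)
    ),
    0L
  )
})

test_that("pathway grouping counts multi-membership and unannotated targets", {
  pred <- data.frame(
    compound_id = c("c1", "c1", "c2"),
    target_accession = c("P1", "P2", "P1"),
    features = "d", via_compound = NA_character_,
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    target_accession = c("P1", "P1"),
    pathway_id = c("pw1", "pw2"),
    stringsAsFactors = FALSE
  )
  g <- group_by_pathway(pred, ann)
  expect_setequal(g$pathway_id, c("pw1", "pw2", "unannotated"))
  expect_equal(g$n_interactions[g$pathway_id == "pw1"], 2L)
  expect_equal(g$n_interactions[g$pathway_id == "pw2"], 2L)
  expect_equal(g$n_compounds[g$pathway_id == "pw1"], 2L)
  expect_equal(g$n_interactions[g$pathway_id == "unannotated"], 1L)

  # single pathway holding everything
  all_one <- group_by_pathway(pred, data.frame(
    target_accession = c("P1", "P2"), pathway_id = "pw1",
    stringsAsFactors = FALSE
  ))
  expect_equal(nrow(all_one), 1L)
  expect_equal(all_one$n_interactions, 3L)
  expect_equal(all_one$n_proteins, 2L)

  # empty annotation table: everything unannotated
  none <- group_by_pathway(pred, ann[0, ])
  expect_equal(none$pathway_id, "unannotated")
  expect_equal(none$n_interactions, 3L)
})
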