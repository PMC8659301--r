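test_that("metric arithmetic reproduces the worked subfamily case", {
  kdm <- compute_scores(3, 1, 0, 2)
  expect_equal(round(kdm$recall, 2), 1.00)
  expect_equal(round(kdm$precision, 2), 0.75)
  expect_equal(round(kdm$accuracy, 2), 0.83)
  expect_equal(round(kdm$f1, 2), 0.86)
  expect_equal(round(kdm$mcc, 2), 0.71)
  perfect <- compute_scores(3, 0, 0, 3)
  expect_equal(unlist(perfect), c(
    recall = 1, precision = 1,
    accuracy = 1, f1 = 1, mcc = 1
  ))
})

test_that("zero-denominator metrics are defined as zero", {
  all_zero <- compute_scores(0, 0, 0, 0)
  expect_equal(unlist(all_zero), c(
    recall = 0, precision = 0,
    accuracy = 0, f1 = 0, mcc = 0
  ))
  # all-negative subject: recall/precision/f1/mcc degenerate, accuracy not
  neg <- compute_scores(0, 0, 0, 5)
  expect_equal(neg$recall, 0)
  expect_equal(neg$precision, 0)
  expect_equal(neg$mcc, 0)
  expect_equal(neg$accuracy, 1)
  expect_error(compute_scores(-1, 0, 0, 0), "nonnegative")
})

test_that("confusion counting matches the subfamily worked example", {
  kdm <- kdm_fixture()
  for (d in c("IPR003349", "IPR001965")) {
    counts <- count_confusion(kdm$actives, kdm$inactives, d, kdm$proteome)
    expect_equal(counts, c(tp = 3L, fp = 1L, fn = 0L, tn = 2L))
  }
  pair <- count_confusion(
    kdm$actives, kdm$inactives, "IPR001965+IPR003349", kdm$proteome
  )
  expect_equal(pair, c(tp = 3L, fp = 0L, fn = 0L, tn = 3L))

  # perfect separation
  prot <- make_proteome(list(A1 = "d", A2 = "d", I1 = "e", I2 = "e"))
  expect_equal(
    count_confusion(c("A1", "A2"), c("I1", "I2"), "d", prot),
    c(tp = 2L, fp = 0L, fn = 0L, tn = 2L)
  )
  expect_error(
    count_confusion("A1", "ZZ", "d", prot),
    "ZZ"
  )
  expect_error(
    count_confusion(c("A1"), c("A1"), "d", prot),
    "overlap"
  )
})

test_that("hierarchy substitution upgrades sibling hits for singles only", {
  h <- domain_hierarchy(c(root = "root", d = "root", sib = "root"))
  prot <- make_proteome(list(
    A1 = "d", A2 = "sib", A3 = "other",
    I1 = "sib", I2 = "other2"
  ))
  with_h <- count_confusion(
    c("A1", "A2", "A3"), c("I1", "I2"), "d", prot, h
  )
  expect_equal(with_h, c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  without_h <- count_confusion(
    c("A1", "A2", "A3"), c("I1", "I2"), "d", prot, NULL
  )
  expect_equal(without_h, c(tp = 1L, fp = 0L, fn = 2L, tn = 2L))
  # pair counting never substitutes
  prot2 <- make_proteome(list(A1 = c("d", "x"), A2 = c("sib", "x"), I1 = "y"))
  pair <- count_confusion(c("A1", "A2"), "I1", "d+x", prot2, h)
  expect_equal(pair, c(tp = 1L, fp = 0L, fn = 1L, tn = 1L))

  # adding a sibling domain to an active target never decreases tp
  prot3 <- make_proteome(list(A1 = "d", A2 = "other", I1 = "z"))
  before <- count_confusion(c("A1", "A2"), "I1", "d", prot3, h)
  prot4 <- make_proteome(list(A1 = "d", A2 = c("other", "sib"), I1 = "z"))
  after <- count_confusion(c("A1", "A2"), "I1", "d", prot4, h)
  expect_gte(after["tp"], before["tp"])
})

test_that("eligibility thresholds sit at 3/3 for compounds, 5/5 for clusters", {
  expect_true(eligible("compound", 3, 3))
  expect_false(eligible("compound", 10, 2))
  expect_false(eligible("compound", 2, 10))
  expect_true(eligible("cluster", 5, 5))
  expect_false(eligible("cluster", 5, 4))
  expect_false(eligible("cluster", 4, 100))
})

test_that("map_all scores the single-compound toy worlds", {
  # two actives sharing the blue domain; three inactives with other domains
  prot <- make_proteome(list(
    P1 = "blue", P2 = "blue",
    P3 = "red", P4 = "red", P5 = "green"
  ))
  ds <- make_dataset(
    rep("c1", 5), paste0("P", 1:5),
    c("active", "active", "inactive", "inactive", "inactive")
  )
  m <- map_all(ds, prot, features = "single", min_compound_targets = 2)
  blue <- m[m$feature == "blue", ]
  expect_equal(blue$tp, 2L)
  expect_equal(blue$fp, 0L)
  expect_equal(blue$fn, 0L)
  expect_equal(blue$tn, 3L)
  expect_equal(blue$mcc, 1)

  # one eligible compound, one domain present only in actives -> 1 mapping
  prot2 <- make_proteome(list(
    A1 = "d", A2 = "d", A3 = "d", I1 = "e", I2 = "e", I3 = "f"
  ))
  ds2 <- make_dataset(
    rep("c1", 6), c("A1", "A2", "A3", "I1", "I2", "I3"),
    rep(c("active", "inactive"), each = 3)
  )
  m2 <- map_all(ds2, prot2, features = "single")
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$feature, "d")
  expect_equal(m2$subject_kind, "compound")

  # ineligible compounds yield nothing
  ds3 <- make_dataset(
    rep("c1", 4), c("A1", "A2", "I1", "I2"),
    rep(c("active", "inactive"), each = 2)
  )
  expect_equal(nrow(map_all(ds3, prot2)), 0L)
})

test_that("cluster pooling, propagation, and max-MCC merge work", {
  prot <- make_proteome(list(
    A1 = "d", A2 = "d", A3 = "d", A4 = "d", A5 = "d",
    I1 = "e", I2 = "e", I3 = "f", I4 = "f", I5 = "g"
  ))
  # c1 and c2 split the targets; individually ineligible at the 3/3 minimum
  ds <- make_dataset(
    c(rep("c1", 5), rep("c2", 5)),
    c(
      "A1", "A2", "A3", "I1", "I2",
      "A4", "A5", "I3", "I4", "I5"
    ),
    c(
      "active", "active", "active", "inactive", "inactive",
      "active", "active", "inactive", "inactive", "inactive"
    )
  )
  clusters <- structure(
    list(c1 = c("c1", "c2"), c2 = c("c1", "c2")),
    class = "compound_clusters"
  )
  m <- map_all(ds, prot, clusters = clusters, features = "single")
  d_rows <- m[m$feature == "d", ]
  # propagated to both members with pooled counts (5,0,0,5)
  expect_setequal(d_rows$subject_id, c("c1", "c2"))
  expect_true(all(d_rows$subject_kind == "cluster"))
  expect_true(all(d_rows$tp == 5L & d_rows$tn == 5L))
  expect_true(all(d_rows$mcc == 1))

  # individual score beats a weaker cluster-derived score for c2
  ds2 <- make_dataset(
    c(rep("c2", 6), rep("c3", 10)),
    c(
      "A1", "A2", "A3", "I1", "I2", "I3",
      "A4", "A5", "I4", "I5", "A1", "A2", "A3", "I1", "I2", "I3"
    ),
    c(
      rep(c("active", "inactive"), each = 3),
      "active", "active", "inactive", "inactive",
      rep("inactive", 3), rep("active", 3)
    )
  )
  clusters2 <- structure(
    list(c2 = c("c2", "c3")),
    class = "compound_clusters"
  )
  expect_warning(
    m2 <- map_all(ds2, prot, clusters = clusters2, features = "single"),
    "conflicting member labels"
  )
  c2_d <- m2[m2$subject_id == "c2" & m2$feature == "d", ]
  expect_equal(nrow(c2_d), 1L)
  expect_equal(c2_d$subject_kind, "compound")
  expect_equal(c2_d$mcc, 1)

  # cluster-derived score wins when it has the larger MCC
  ds3 <- make_dataset(
    c(rep("c1", 7), rep("c2", 4)),
    c(
      "A1", "A2", "A3", "I1", "I2", "I3", "E1",
      "A4", "A5", "I4", "I5"
    ),
    c(
      "active", "active", "active", "inactive", "inactive", "inactive",
      "active",
      "active", "active", "inactive", "inactive"
    )
  )
  prot3 <- make_proteome(list(
    A1 = "d", A2 = "d", A3 = "d", A4 = "d", A5 = "d",
    I1 = "e", I2 = "e", I3 = "f", I4 = "f", I5 = "g",
    E1 = "e" # an active lacking d: costs c1's individual mapping one FN
  ))
  m3 <- map_all(ds3, prot3,
    clusters = structure(list(c1 = c("c1", "c2")),
      class = "compound_clusters"
    ),
    features = "single"
  )
  c1_d <- m3[m3$subject_id == "c1" & m3$feature == "d", ]
  expect_equal(nrow(c1_d), 1L)
  expect_equal(c1_d$subject_kind, "cluster")
  expect_equal(c1_d$tp, 5L) # pooled counts, not c1's own (3,0,1,3)
  expect_equal(c1_d$fn, 1L)
})

test_that("score thresholding takes the minimum over the chosen metrics", {
  m <- rbind(
    cbind(
      data.frame(
        subject_id = "c1", subject_kind = "compound", feature = "d",
        tp = 3L, fp = 0L, fn = 0L, tn = 3L, stringsAsFactors = FALSE
      ),
      compute_scores(3, 0, 0, 3)
    ),
    cbind(
      data.frame(
        subject_id = "c1", subject_kind = "compound", feature = "e",
        tp = 3L, fp = 1L, fn = 0L, tn = 2L, stringsAsFactors = FALSE
      ),
      compute_scores(3, 1, 0, 2)
    )
  )
  expect_equal(threshold_filter(m, 0.9)$feature, "d")
  # min of the subfamily single scores is the MCC, 0.71: dropped at 0.8
  expect_equal(threshold_filter(m, 0.8)$feature, "d")
  expect_equal(nrow(threshold_filter(m, 0)), 2L)
  # excluding mcc from the metric list keeps the 0.75-precision row at 0.7
  expect_equal(
    nrow(threshold_filter(m, 0.7,
      metrics = c("recall", "precision", "accuracy", "f1")
    )),
    2L
  )
  expect_error(threshold_filter(m, 1.5), "\\[0, 1\\]")
})

test_that("pair classification compares against the best constituent single", {
  row <- function(feature, mcc, subject = "c1") {
    data.frame(
      subject_id = subject, subject_kind = "compound", feature = feature,
      tp = 1L, fp = 0L, fn = 0L, tn = 1L,
      recall = 1, precision = 1, accuracy = 1, f1 = 1, mcc = mcc,
      stringsAsFactors = FALSE
    )
  }
  m <- rbind(
    row("A", 0.71), row("B", 0.71), row("A+B", 1.00),
    row("C", 0.9), row("A+C", 0.9),
    row("D", 0.8), row("B+D", 0.5),
    row("X+Y", 0.2) # no constituent singles: compared against -1
  )
  cl <- classify_domain_pairs(m)
  expect_equal(cl$pair_class[cl$feature == "A+B"], "positive")
  expect_equal(cl$pair_class[cl$feature == "A+C"], "neutral")
  expect_equal(cl$pair_class[cl$feature == "B+D"], "non_positive")
  expect_equal(cl$pair_class[cl$feature == "X+Y"], "positive")
  expect_true(all(is.na(cl$pair_class[!grepl("+", cl$feature, fixed = TRUE)])))
  pos <- filter_positive_pairs(cl)
  expect_setequal(
    pos$feature,
    c("A", "B", "C", "D", "A+B", "X+Y")
  )
})

test_that("counts are conserved and pairs never beat singles on tp", {
  for (s in 1:5) {
    w <- small_world(s)
    ds <- build_dataset(w$records)
    m <- suppressWarnings(map_all(ds, w$proteome, hierarchy = NULL))
    expect_gt(nrow(m), 0)
    for (cpd in unique(m$subject_id)) {
      rows <- m[m$subject_id == cpd & m$subject_kind == "compound", ]
      if (nrow(rows) == 0L) next
      n_act <- length(intersect(
        active_targets(ds, cpd), names(w$proteome$domains)
      ))
      n_ina <- length(intersect(
        inactive_targets(ds, cpd), names(w$proteome$domains)
      ))
      expect_true(all(rows$tp + rows$fn == n_act))
      expect_true(all(rows$fp + rows$tn == n_ina))
      # pair dominance with hierarchy disabled
      pair_rows <- rows[grepl("+", rows$feature, fixed = TRUE), ]
      if (nrow(pair_rows) > 0L) {
        single_tp <- stats::setNames(rows$tp, rows$feature)
        for (j in seq_len(nrow(pair_rows))) {
          parts <- feature_parts(pair_rows$feature[j])
          present <- parts[parts %in% names(single_tp)]
          expect_true(all(pair_rows$tp[j] <= single_tp[present]))
        }
      }
    }
  }
})
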