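test_that("per-position confusion counts partition the sequence", {
  full <- parse_dotbracket(WORKED_FULL_DB)
  cc <- confusion_counts(full, full)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 16L, tn = 6L, fp = 0L, fn = 0L))

  dots10 <- rna_structure(10L)
  expect_equal(confusion_counts(dots10, dots10)$tn, 10L)

  ref3 <- rna_structure(10L, p = c(1, 2, 3), q = c(10, 9, 8),
                        layer = rep("round", 3))
  cc2 <- confusion_counts(dots10, ref3)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0L, tn = 4L, fp = 0L, fn = 6L))

  # partner mismatch counts once, as fp
  pred <- rna_structure(6L, p = 1, q = 5, layer = "round")
  ref <- rna_structure(6L, p = 1, q = 6, layer = "round")
  cc3 <- confusion_counts(pred, ref)
  expect_equal(unlist(cc3[c("tp", "tn", "fp", "fn")]),
               c(tp = 0L, tn = 3L, fp = 2L, fn = 1L))

  expect_error(confusion_counts(dots10, rna_structure(9L)), "mismatch")
})

test_that("confusion counts always sum to the sequence length", {
  set.seed(515)
  for (case in 1:30) {
    inst <- generate_pseudoknot(plant_spec(seed = 7000L + case))
    pred <- predict_pseudoknot(inst$seq)
    cc <- confusion_counts(pred$structure, inst$structure)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, nchar(inst$seq))
    expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), unlist(
      oracle_confusion(partner_vector(pred$structure),
                       partner_vector(inst$structure))),
      ignore_attr = TRUE)
  }
})

test_that("metric formulas reproduce printed whole-dataset confusion rows", {
  rows <- list(
    list(c = list(tp = 3850, tn = 3746, fp = 1488, fn = 1606),
         m = c(0.721, 0.706, 0.713, 0.421)),
    list(c = list(tp = 5006, tn = 3331, fp = 1836, fn = 517),
         m = c(0.732, 0.906, 0.810, 0.574)),
    list(c = list(tp = 4170, tn = 4061, fp = 1154, fn = 1305),
         m = c(0.783, 0.762, 0.772, 0.540)),
    list(c = list(tp = 4342, tn = 3975, fp = 1306, fn = 1053),
         m = c(0.769, 0.805, 0.786, 0.558)))
  for (row in rows) {
    m <- compute_metrics(row$c)
    expect_equal(round(c(m$ppv, m$recall, m$f1, m$mcc), 3), row$m)
  }
})

test_that("degenerate confusion counts yield NaN metrics with warnings, and perfect ones 1", {
  m <- compute_metrics(list(tp = 7, tn = 5, fp = 0, fn = 0))
  expect_equal(c(m$ppv, m$recall, m$f1, m$mcc), c(1, 1, 1, 1))
  w <- capture_warnings(m0 <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0)))
  expect_length(w, 4L)  # PPV, recall, F1, MCC all undefined
  expect_match(w, "undefined", all = TRUE)
  expect_true(all(is.nan(unlist(m0[c("ppv", "recall", "f1", "mcc")]))))
  # symmetric counts give ppv == recall
  ms <- compute_metrics(list(tp = 10, tn = 10, fp = 3, fn = 3))
  expect_equal(ms$ppv, ms$recall)
})

test_that("MCC equals the Pearson correlation of paired-position indicators", {
  set.seed(303)
  for (case in 1:20) {
    n <- 30L
    rp <- random_ref_pred_pair(n, 5L, 3L)
    pv <- rep(NA_integer_, n); pv[rp$pred$p] <- rp$pred$q; pv[rp$pred$q] <- rp$pred$p
    rv <- rep(NA_integer_, n); rv[rp$ref$p] <- rp$ref$q; rv[rp$ref$q] <- rp$ref$p
    cc <- oracle_confusion(pv, rv)
    if ((cc$tp + cc$fp) == 0 || (cc$tp + cc$fn) == 0 ||
        (cc$tn + cc$fp) == 0 || (cc$tn + cc$fn) == 0) next
    m <- compute_metrics(cc)
    expect_equal(m$mcc, stats::cor(!is.na(pv), !is.na(rv)), tolerance = 1e-12)
  }
})

test_that("core-stem matching applies the one-coordinate slip rule", {
  ref <- list(c(5, 11), c(10, 17))
  expect_equal(core_stem_matches(list(c(5, 11), c(10, 17)), ref), 2L)
  expect_equal(core_stem_matches(list(c(5, 12), c(10, 17)), ref), 2L)
  expect_equal(core_stem_matches(list(c(1, 4), c(2, 6)), ref), 0L)
  # both coordinates off by one is not a match
  expect_equal(core_stem_matches(list(c(6, 12), c(10, 17)), ref), 1L)
  # crossed assignment still yields the maximum matching
  expect_equal(core_stem_matches(list(c(10, 17), c(5, 11)), ref), 2L)
  # each predicted pair satisfies at most one reference pair
  expect_equal(core_stem_matches(list(c(5, 11), c(5, 12)),
                                 list(c(5, 11), c(5, 11))), 2L)
  expect_equal(core_stem_matches(list(c(5, 11)), list(c(5, 11), c(10, 17))), 1L)
})

test_that("evaluation report aggregates counts and recomputes metrics", {
  insts <- lapply(1:3, function(s) generate_pseudoknot(plant_spec(seed = s)))
  preds <- lapply(insts, function(i) predict_pseudoknot(i$seq)$structure)
  refs <- lapply(insts, `[[`, "structure")
  d <- evaluate_structures(preds, refs)
  expect_equal(nrow(d), 4L)
  expect_equal(d$tp[4], sum(d$tp[1:3]))
  tot <- compute_metrics(as.list(d[4, c("tp", "tn", "fp", "fn")]))
  expect_equal(d$f1[4], tot$f1)
  # identical structures give all-1 metrics
  d2 <- evaluate_structures(refs, refs)
  expect_true(all(d2[, c("ppv", "recall", "f1", "mcc")] == 1))
})
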