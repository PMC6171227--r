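toy_split_maps <- function() {
  # one 4-px reference object; target splits it into two 2-px halves
  R <- matrix(0L, 10, 10); R[4, 4:7] <- 1L
  T_ <- matrix(0L, 10, 10); T_[4, 4:5] <- 1L; T_[4, 6:7] <- 2L
  list(R = R, T_ = T_)
}

test_that("overlap tables count pixel intersections exactly", {
  m <- random_label_map(12, 12, 3)
  ov <- overlap_sets(m, m)
  expect_identical(ov$pairs$ref, ov$pairs$tgt)
  expect_equal(ov$pairs$intersection,
               unname(ov$ref_sizes[as.character(ov$pairs$ref)]))

  disjA <- matrix(0L, 8, 8); disjA[1:2, 1:2] <- 1L
  disjB <- matrix(0L, 8, 8); disjB[6:7, 6:7] <- 1L
  expect_equal(nrow(overlap_sets(disjA, disjB)$pairs), 0)

  tm <- toy_split_maps()
  ov <- overlap_sets(tm$R, tm$T_)
  expect_equal(nrow(ov$pairs), 2)
  expect_equal(sum(ov$pairs$intersection), 4)
})

test_that("mutual-best matching is one-to-one with deterministic ties", {
  m <- random_label_map(15, 15, 4)
  ov <- overlap_sets(m, m)
  mt <- one_to_one_matches(ov)
  expect_equal(nrow(mt), length(ov$ref_labels))
  expect_identical(mt$ref, mt$tgt)

  tm <- toy_split_maps()
  mt <- one_to_one_matches(overlap_sets(tm$R, tm$T_))
  expect_equal(nrow(mt), 1)  # the split object is matched once
  expect_equal(mt$tgt, 1L)   # equal intersections -> smaller target id

  empty <- matrix(0L, 10, 10)
  expect_equal(nrow(one_to_one_matches(overlap_sets(tm$R, empty))), 0)
})

test_that("sm_score reproduces hand-computed values", {
  m <- random_label_map(20, 20, 5)
  expect_equal(sm_score(m, m, k = 0.6)$sm, 1.0)

  tm <- toy_split_maps()
  s <- sm_score(tm$R, tm$T_, k = 0.6)
  expect_equal(s$term1, 2 / 3)   # best Dice 2*2/(4+2)
  expect_equal(s$term2, 2 / 3)   # 2*1/(1+2)
  expect_equal(s$sm, 2 / 3)

  far <- matrix(0L, 10, 10); far[9:10, 9:10] <- 1L
  R1 <- matrix(0L, 10, 10); R1[1:2, 1:2] <- 1L
  expect_warning(s0 <- sm_score(R1, matrix(0L, 10, 10)), "no objects")
  expect_equal(s0$sm, 0)
  expect_equal(sm_score(R1, far)$sm, 0)
  expect_error(sm_score(matrix(0L, 10, 10), far), "no objects")
})

test_that("sm_score is invariant under relabeling and penalizes spurious objects", {
  set.seed(31)
  m <- random_label_map(24, 24, 5)
  labs <- setdiff(sort(unique(as.vector(m))), 0L)
  perm <- sample(1000, length(labs))
  m2 <- m
  for (i in seq_along(labs)) m2[m == labs[i]] <- perm[i]
  expect_equal(sm_score(m, m2)$sm, 1.0)

  spur <- m2
  free <- which(m2 == 0)[1:4]
  spur[free] <- 2000L  # an object overlapping nothing
  expect_gte(sm_score(m, m2)$sm, sm_score(m, spur)$sm)
})

test_that("per-cell scores carry the per-object Dice and their mean", {
  m <- random_label_map(16, 16, 4)
  sc <- per_cell_scores(m, m)
  expect_true(all(sc$best_dice == 1))
  tm <- toy_split_maps()
  expect_equal(per_cell_scores(tm$R, tm$T_)$best_dice, 2 / 3)
  s <- sm_score(tm$R, tm$T_)
  expect_equal(mean(per_cell_scores(tm$R, tm$T_)$best_dice), s$term1)
})

test_that("classification_eval handles perfect, chance and degenerate input", {
  tr <- matrix(rep(c(0, 1), each = 50), 10, 10)
  perfect <- classification_eval(tr, tr)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$acc, 1.0)

  flat <- classification_eval(matrix(0.5, 10, 10), tr)
  expect_equal(flat$acc, 0.5)
  expect_equal(flat$auc, 0.5)

  expect_warning(deg <- classification_eval(tr, matrix(1, 10, 10)),
                 "single class")
  expect_true(is.na(deg$auc))
  expect_equal(deg$acc, 0.5)
})

test_that("roc table spans [0,1] with 101 thresholds and agrees with pROC", {
  set.seed(32)
  prob <- matrix(runif(100), 10, 10)
  tr <- matrix(rbinom(100, 1, 0.4), 10, 10)
  ev <- classification_eval(prob, tr)
  expect_equal(nrow(ev$roc), 101)
  expect_equal(range(ev$roc$threshold), c(0, 1))
  expect_true(all(diff(ev$roc$sensitivity) <= 1e-12))
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(as.vector(tr), as.vector(prob),
                                quiet = TRUE))
    expect_equal(ev$auc, ref, tolerance = 0.02)
  }
})

test_that("tidy and glance summarize evaluation objects", {
  skip_if_not_installed("generics")
  tm <- toy_split_maps()
  s <- sm_score(tm$R, tm$T_)
  g <- generics::glance(s)
  expect_equal(g$sm, 2 / 3)
  expect_equal(g$n_matched, 1L)
  expect_equal(generics::tidy(s), s$per_reference)
  ev <- classification_eval(matrix(c(0, 1), 2, 2), matrix(c(0, 1), 2, 2))
  expect_equal(generics::glance(ev)$auc, 1)
  expect_equal(nrow(generics::tidy(ev)), 101)
})
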