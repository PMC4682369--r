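test_that("confusion metrics match an independent vector-based oracle", {
  m <- classification_metrics(confusion_matrix(tp = 10, fp = 10, tn = 10,
                                               fn = 10))
  expect_equal(m$Acc, 0.5)
  expect_equal(m$MCC, 0)

  # oracle: MCC equals the Pearson correlation of the truth/prediction
  # indicator vectors; Acc equals their agreement rate
  set.seed(14)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(4:200, 1), prob = runif(4, 0.05, 1))[, 1]
    cm <- confusion_matrix(tp = cnt[1], fp = cnt[2], tn = cnt[3],
                           fn = cnt[4])
    truth <- rep(c(TRUE, FALSE, FALSE, TRUE), cnt)
    pred <- rep(c(TRUE, TRUE, FALSE, FALSE), cnt)
    met <- classification_metrics(cm)
    expect_equal(met$Acc, mean(truth == pred), tolerance = 1e-12)
    oracle_mcc <- suppressWarnings(cor(truth, pred))
    if (is.na(oracle_mcc)) oracle_mcc <- 0
    expect_equal(met$MCC, oracle_mcc, tolerance = 1e-12)
    expect_gte(met$MCC, -1); expect_lte(met$MCC, 1)

    # swapping the class labels exchanges Sn and Sp and preserves MCC
    sw <- classification_metrics(confusion_matrix(tp = cnt[3], fp = cnt[4],
                                                  tn = cnt[1], fn = cnt[2]))
    expect_equal(sw$Sn, met$Sp); expect_equal(sw$Sp, met$Sn)
    expect_equal(sw$MCC, met$MCC, tolerance = 1e-12)
  }
  expect_equal(classification_metrics(
    confusion_matrix(tp = 5, fp = 0, tn = 5, fn = 0))$MCC, 1)
  expect_equal(classification_metrics(
    confusion_matrix(tp = 0, fp = 5, tn = 0, fn = 5))$MCC, -1)
  expect_error(classification_metrics(
    confusion_matrix(tp = 0, fp = 0, tn = 0, fn = 0)), "empty")
})

test_that("homology filtering removes fragments at or above the identity cutoff", {
  train <- c("AAAAASAAAAA", "CCCCCTCCCCC")
  test <- c("AAAAASAAAAA",  # exact duplicate
            "AAAAASAAAAW",  # 10/11 identity
            "WWWWWSWWWWW")
  expect_equal(homology_filter(test, train, 1.0), test[2:3])
  expect_equal(homology_filter(test, train, 10 / 11), test[3])
  expect_equal(homology_filter(test, character(0)), test)
  # two padding symbols at the same position count as a match
  expect_equal(homology_filter("----ASAAAAA", "----ASAAAAA", 1.0),
               character(0))
})

test_that("stratified cross-validation balances folds and brackets trivial trainers", {
  pos <- random_fragments(53, seed = 21)
  neg <- random_fragments(101, seed = 22)

  # a memorizing trainer attains accuracy 1
  memorizer <- function(train_pos, train_neg, seed) {
    all_pos <- pos  # closes over the full positive set
    function(fragments) fragments %in% all_pos
  }
  res <- cross_validate(pos, neg, memorizer, k = 5, repeats = 2, seed = 3)
  expect_equal(res$average$Acc, 1.0)

  # fold sizes differ by at most one per class
  counted <- table(res$folds$TP + res$folds$FN)
  expect_lte(diff(range(res$folds$TP + res$folds$FN)), 1)
  expect_lte(diff(range(res$folds$TN + res$folds$FP)), 1)
  expect_equal(nrow(res$folds), 10L)
  expect_equal(nrow(res$by_round), 2L)

  # no class signal: a real trainer hovers at chance
  null_pos <- random_fragments(100, seed = 23)
  null_neg <- random_fragments(100, seed = 24)
  res0 <- cross_validate(null_pos, null_neg,
                         single_hmm_trainer(test_config()), k = 5,
                         repeats = 3, seed = 4)
  expect_gte(res0$average$Acc, 0.4)
  expect_lte(res0$average$Acc, 0.6)

  expect_error(cross_validate(pos[1:3], neg, memorizer, k = 5),
               "at least k")
})

test_that("independent testing guards and degenerate classifiers behave", {
  g <- generate_windows(dataset_spec(n_pos = 60, n_neg = 400,
                                     motifs = separable_motifs(), seed = 55))
  model <- train_two_layer(g$positives, g$negatives,
                           test_config(seed = 10, min_size = 20L))
  h <- generate_windows(dataset_spec(n_pos = 60, n_neg = 400,
                                     motifs = separable_motifs(), seed = 56))
  res <- independent_test(model, h$positives, h$negatives)
  expect_equal(res$cm$TP + res$cm$FN, 60)
  expect_equal(res$cm$TN + res$cm$FP, 400)

  expect_error(independent_test(model, character(0), h$negatives),
               "non-empty")

  # an all-negative classifier has Sp = 1 and Sn = 0
  never <- model
  never$second_layer$platt <- c(-50, 0)
  res0 <- independent_test(never, h$positives, h$negatives)
  expect_equal(res0$metrics$Sp, 1)
  expect_equal(res0$metrics$Sn, 0)

  # resubstitution is at least as optimistic as cross-validation
  resub <- independent_test(model, g$positives, g$negatives)
  cv <- cross_validate(g$positives, g$negatives,
                       two_layer_trainer(test_config(min_size = 20L)),
                       k = 3, repeats = 1, seed = 9)
  expect_gte(resub$metrics$Acc + 1e-9, cv$average$Acc)
})
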