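test_that("k-means balancing returns exactly n_target distinct negatives from the pool", {
  g <- generate_windows(dataset_spec(n_pos = 0, n_neg = 400, seed = 31))
  neg <- g$negatives

  # saturation: asking for all negatives returns them unchanged
  expect_identical(kmeans_balance(neg, nrow(neg)), neg)

  bal <- kmeans_balance(neg, 50, seed = 2)
  expect_equal(nrow(bal), 50L)
  expect_false(anyDuplicated(bal$fragment) > 0)
  expect_true(all(bal$fragment %in% neg$fragment))

  expect_error(kmeans_balance(neg, 401), "exceeds")
})

test_that("bit-score featureization is fixed-order, deterministic, and zero for null-equal models", {
  g <- two_motif_dataset(61, n_pos = 120, n_neg = 600)
  cfg <- test_config(seed = 3)
  model <- train_two_layer(g$positives, g$negatives, cfg)
  frags <- g$negatives$fragment[1:10]
  F1 <- featureize(frags, model)
  expect_equal(ncol(F1), length(model$hmms))
  expect_equal(colnames(F1), unname(names(model$metadata$leaf_sizes)))
  expect_identical(F1, featureize(frags, model))

  null_hmms <- lapply(model$hmms, function(h) {
    h$model$match_emissions[] <- rep(h$model$null_model,
                                     each = h$model$length)
    h
  })
  expect_equal(unname(featureize(frags, null_hmms)),
               matrix(0, 10, length(null_hmms)), tolerance = 1e-9)
})

test_that("second-layer SVM selects by cross-validated accuracy and calibrates probabilities", {
  set.seed(8)
  pos <- matrix(rnorm(120, mean = 3), ncol = 2)
  neg <- matrix(rnorm(120, mean = -3), ncol = 2)
  layer <- train_second_layer(pos, neg, grid = data.frame(C = 1, gamma = 0.5),
                              seed = 4)
  pr_pos <- oglcnac:::second_layer_prob(layer, pos)
  pr_neg <- oglcnac:::second_layer_prob(layer, neg)
  expect_true(all(pr_pos > 0.5) && all(pr_neg < 0.5))  # separable case
  expect_true(all(pr_pos >= 0 & pr_pos <= 1))

  # probabilities are monotone in the oriented decision value
  X <- rbind(pos, neg)
  dv <- oglcnac:::svm_decision(layer, X)
  if (layer$flip) dv <- -dv
  p <- oglcnac:::second_layer_prob(layer, X)
  ord <- order(dv)
  expect_true(all(diff(p[ord]) >= 0))

  # identical class distributions: held-out accuracy near chance
  set.seed(9)
  same_pos <- matrix(rnorm(200), ncol = 1)
  same_neg <- matrix(rnorm(200), ncol = 1)
  layer0 <- train_second_layer(same_pos, same_neg,
                               grid = data.frame(C = 1, gamma = 0.5),
                               seed = 5)
  cv_acc <- max(layer0$grid_accuracy$accuracy)
  expect_gte(cv_acc, 0.4); expect_lte(cv_acc, 0.6)

  expect_error(train_second_layer(pos[0, , drop = FALSE], neg), "non-empty")
})

test_that("the full pipeline trains, degenerates gracefully, and records its configuration", {
  g <- two_motif_dataset(71, n_pos = 150, n_neg = 1200)
  cfg <- test_config(seed = 6)
  model <- train_two_layer(g$positives, g$negatives, cfg)
  expect_gte(length(model$hmms), 2L)
  expect_equal(model$metadata$n_pos, 150L)
  expect_equal(model$metadata$chi2_cutoff, 34.3)
  expect_equal(model$metadata$min_size, 30L)
  expect_equal(model$metadata$seed, 6L)

  # held-out accuracy on freshly generated data from the same spec
  h <- two_motif_dataset(72, n_pos = 150, n_neg = 1200)
  pred <- c(predict_prob(model, h$positives$fragment),
            predict_prob(model, h$negatives$fragment)) > 0.5
  truth <- rep(c(TRUE, FALSE), c(150, 1200))
  acc <- mean(pred == truth)
  expect_gt(acc, 0.8)

  # min_size above n collapses layer 1 to a single HMM but still trains
  cfg1 <- test_config(seed = 7, min_size = 1000L)
  m1 <- train_two_layer(g$positives$fragment[1:60], g$negatives$fragment,
                        cfg1)
  expect_equal(length(m1$hmms), 1L)
  expect_equal(names(m1$hmms), "OGT1")

  # identical seeds give identical models in memory
  m2 <- train_two_layer(g$positives, g$negatives, cfg)
  expect_identical(model$second_layer[c("SV", "coefs", "rho", "platt")],
                   m2$second_layer[c("SV", "coefs", "rho", "platt")])
})

test_that("site prediction labels by strict probability exceedance and reports motifs", {
  g <- generate_windows(dataset_spec(n_pos = 80, n_neg = 500,
                                     motifs = separable_motifs(), seed = 81))
  model <- train_two_layer(g$positives, g$negatives,
                           test_config(seed = 8, min_size = 20L))

  expect_equal(nrow(predict(model, "KKKKAAAKKKK")), 0L)  # no S/T

  preds <- predict(model, "MKSAPVTRDEW")
  expect_equal(nrow(preds), 2L)
  expect_true(all(preds$matched_motif != ""))
  expect_true(all(preds$probability >= 0 & preds$probability <= 1))

  # boundary rule: probability exactly at the threshold is negative
  flat <- model
  flat$second_layer$platt <- c(0, 0)  # every probability is exactly 0.5
  flat_preds <- predict(flat, "MKSAPVTRDEW")
  expect_equal(flat_preds$probability, rep(0.5, 2))
  expect_true(all(flat_preds$label == "negative"))
})

test_that("planted sites in whole proteins are recovered at low false positive rate", {
  motifs <- separable_motifs()
  g <- generate_windows(dataset_spec(n_pos = 200, n_neg = 2000,
                                     motifs = motifs, seed = 21))
  model <- train_two_layer(g$positives, g$negatives, test_config(seed = 5))
  prot <- generate_proteins(dataset_spec(n_pos = 1, n_neg = 0,
                                         motifs = motifs, seed = 77),
                            n_proteins = 15, sites_per_protein = 3)
  preds <- predict(model, prot$records)
  key <- function(id, p) paste(id, p)
  planted <- key(preds$protein_id, preds$position) %in%
    key(prot$annotations$protein_id, prot$annotations$position)
  called <- preds$label == "positive"
  expect_gte(mean(called[planted]), 0.8)
  expect_lte(mean(called[!planted]), 0.2)
})
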