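test_that("group encoding follows the five-class scheme and nulls X/-", {
  expect_equal(group_encode("DEKRA"),
               c("acidic", "acidic", "basic", "basic", "hydrophobic"))
  expect_true(all(is.na(group_encode("XX-XX"))))
  # totality: every letter maps to exactly one group
  enc <- group_encode(paste(oglcnac:::AA_LETTERS, collapse = ""))
  expect_false(anyNA(enc))
  expect_setequal(unique(enc), oglcnac:::GROUP_LEVELS)
})

test_that("contingency tables count group co-occurrence and conserve marginals", {
  frags <- rep("AAAAASAAAQA", 10)  # hydrophobic at -3, polar at +4
  tab <- contingency(frags, -3, 4)
  expect_equal(sum(tab), 10)
  expect_equal(tab["hydrophobic", "polar"], 10)
  expect_error(contingency(frags, 0, 2), "centre")
  expect_error(contingency(frags, 2, 2), "differ")

  mixed <- c(rep("AAAAASAAAAA", 50), rep("NNNNNSNNNNN", 50))
  tab2 <- contingency(mixed, -3, -2)
  expect_equal(tab2["hydrophobic", "hydrophobic"], 50)
  expect_equal(tab2["polar", "polar"], 50)
  expect_equal(sum(rowSums(tab2)), sum(colSums(tab2)))
  expect_equal(sum(tab2), 100)

  # fragments with X or - at either position are skipped
  with_null <- c(mixed, "XAAAASAAAAA", "-AAAASAAAAA")
  expect_equal(sum(contingency(with_null, -5, -2)), 100)
})

test_that("dependence statistic matches brute-force evaluation and hand cases", {
  tab <- matrix(4, 5, 5)  # perfectly independent
  expect_equal(chi_square(tab), 0)
  conc <- matrix(0, 5, 5); conc[1, 1] <- 50; conc[2, 2] <- 50
  expect_identical(chi_square(conc), 100)
  expect_error(chi_square(matrix(0, 5, 5)), "zero")

  set.seed(11)
  for (i in 1:300) {
    tab <- matrix(rpois(25, sample(0:3, 1)), 5, 5)
    if (sum(tab) == 0) tab[1, 1] <- 1
    got <- chi_square(tab)
    want <- chi_square_oracle(tab)
    expect_true(abs(got - want) <= 1e-9 * max(1, abs(want)))
    expect_equal(chi_square(t(tab)), got)  # symmetry under transpose
    expect_gte(got, 0)
  }
})

test_that("dependence scan scores all 2w(2w-1)/2 pairs and finds planted pairs", {
  frags <- random_fragments(100, seed = 2)
  scan <- dependence_scan(frags)
  expect_equal(nrow(scan), choose(10, 2))
  expect_true(all(scan$i < scan$j))

  planted <- linked_pair_dataset(7)$positives
  scan2 <- dependence_scan(planted$fragment)
  top <- scan2[which.max(scan2$chi2), ]
  expect_equal(c(top$i, top$j), c(-3, -2))
})

test_that("under the null the per-pair exceedance of the 34.3 cutoff stays at its nominal rate", {
  # cutoff 34.3 is the chi-squared 16-df upper 0.005 point; averaged over
  # seeds the fraction of pairs exceeding it should stay near 0.005
  frac <- vapply(1:50, function(s) {
    frags <- random_fragments(100, seed = 100 + s)
    mean(dependence_scan(frags)$chi2 > 34.3)
  }, numeric(1))
  expect_lte(mean(frac), 0.01)
})

test_that("split selection picks a planted position with its modal group", {
  # no dependence anywhere: all fragments identical groups per position
  expect_null(choose_split(rep("AAAAASAAAAA", 40)))

  planted <- linked_pair_dataset(3)$positives
  sp <- choose_split(planted$fragment)
  expect_true(sp$position %in% c(-3L, -2L))
  expect_gt(sp$max_chi2, 34.3)

  # modal group at the chosen position: 60% hydrophobic
  set.seed(5)
  fm <- matrix(sample(oglcnac:::AA_LETTERS, 200 * 11, TRUE), 200)
  fm[, 6] <- "S"
  fm[1:120, 3] <- "A"; fm[121:160, 3] <- "D"; fm[161:200, 3] <- "K"
  fm[1:120, 4] <- "P"; fm[121:160, 4] <- "E"; fm[161:200, 4] <- "R"
  frags <- apply(fm, 1, paste, collapse = "")  # -3 and -2 group-linked
  sp2 <- choose_split(frags)
  expect_true(sp2$position %in% c(-3L, -2L))
  expect_equal(sp2$group, "hydrophobic")
})

test_that("MDD clustering partitions fragments, respects min_size and separates planted motifs", {
  few <- random_fragments(20, seed = 1)
  tree <- mdd_cluster(few, min_size = 30)
  expect_null(tree$split_position)
  expect_equal(tree$leaf_id, "OGT1")

  for (s in 1:5) {
    g <- generate_windows(dataset_spec(n_pos = 200, n_neg = 0,
                                       motifs = separable_motifs(),
                                       seed = 300 + s))
    tr <- mdd_cluster(g$positives$fragment)
    leaves <- mdd_leaves(tr)
    members <- unname(unlist(lapply(leaves, `[[`, "members")))
    expect_equal(sort(members), seq_len(200))  # exact partition
    expect_gte(length(leaves), 2L)
    # majority motif per leaf: planted subpopulations separate cleanly
    purity <- vapply(leaves, function(l) {
      tt <- table(g$truth[l$members])
      max(tt) / sum(tt)
    }, numeric(1))
    big <- vapply(leaves, function(l) length(l$members), 1L) >= 30
    expect_true(all(purity[big] >= 0.9))
  }

  # with-branch members all carry the split group at the split position
  g <- two_motif_dataset(42, n_pos = 200, n_neg = 0)
  tr <- mdd_cluster(g$positives$fragment)
  if (!is.null(tr$split_position)) {
    frags <- attr(tr, "fragments")
    col <- tr$split_position + 6L
    groups <- unname(default_group_scheme()[
      substring(frags[tr$child_with$members], col, col)])
    expect_true(all(groups == tr$split_group))
  }

  # raising the cutoff never increases the number of leaves
  n_leaves <- function(cutoff)
    length(mdd_leaves(mdd_cluster(g$positives$fragment,
                                  chi2_cutoff = cutoff)))
  counts <- vapply(c(20, 34.3, 80, 200, 1e6), n_leaves, 1L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1L)
})
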