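fixture_npx <- function(shift = 3, n_shifted = 12, seed = 1) {
  # noise-induced FMD changes are predominantly negative (impairment):
  # the top half by magnitude coincides with the lowest signed changes
  fc <- stats::setNames(seq(-8, 0, length.out = 40), sprintf("S%02d", 1:40))
  simulate_npx(proteome_params(responder_shift = shift,
                               responder_protein_count = n_shifted),
               fc, seed = seed)
}

test_that("pairwise_change computes post - pre per subject in NPX units", {
  npx <- fixture_npx(seed = 2)
  chg <- pairwise_change(npx)
  expect_equal(dim(chg), c(40, 179))  # subjects x proteins

  # identical pre/post -> all zeros
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("P", 1:5),
                              c("A_pre", "B_pre", "A_post", "B_post")))
  m[, "A_post"] <- m[, "A_pre"]; m[, "B_post"] <- m[, "B_pre"]
  ann <- data.frame(sample = colnames(m), subject = c("A", "B", "A", "B"),
                    timepoint = c("pre", "pre", "post", "post"))
  expect_equal(max(abs(pairwise_change(m, ann))), 0)

  # post = pre + 1 on one protein -> change 1 NPX (a doubling) there
  m2 <- m; m2["P3", c("A_post", "B_post")] <- m2["P3", c("A_pre", "B_pre")] + 1
  chg2 <- pairwise_change(m2, ann)
  expect_equal(unname(chg2[, "P3"]), c(1, 1))
  expect_equal(max(abs(chg2[, -3])), 0)

  # unmatched subject errors with the id
  ann_bad <- ann; ann_bad$subject[4] <- "C"
  expect_error(pairwise_change(m, ann_bad), "B.*C|C.*B")
})

test_that("de_ttest retains by unadjusted p < threshold", {
  set.seed(3)
  # identical groups -> nothing systematically retained
  x <- matrix(rnorm(40 * 50), 40, 50)
  g <- rep(c("a", "b"), each = 20)
  de0 <- de_ttest(x, g)
  expect_lt(sum(de0$retained), 8)
  expect_true(all(de0$retained == (de0$p_value < 0.05)))

  # one protein shifted 3 units at sd 1, n = 20/20 -> retained (t ~ 9.5)
  x[g == "a", 1] <- x[g == "a", 1] + 3
  de1 <- de_ttest(x, g)
  expect_true(de1$retained[1])
  expect_equal(de1$difference[1], 3, tolerance = 0.7)

  # zero-variance rules
  z <- cbind(p1 = rep(c(0, 0), each = 4), p2 = rep(c(0, 1), each = 4))
  dez <- de_ttest(z, rep(c("a", "b"), each = 4))
  expect_equal(dez$p_value, c(1, 0))
  expect_equal(dez$retained, c(FALSE, TRUE))

  # null calibration: ~5% retained on average across replicate seeds
  rates <- vapply(1:60, function(s) {
    set.seed(s + 100)
    mean(de_ttest(matrix(rnorm(40 * 179), 40), rep(c("a", "b"), each = 20))$retained)
  }, numeric(1))
  expect_equal(mean(rates), 0.05, tolerance = 0.012)

  expect_error(de_ttest(x[1:3, ], c("a", "a", "b")), ">= 2 observations")
})

test_that("split_responders partitions deterministically with tie policy", {
  fc <- stats::setNames(seq(-2, 2, length.out = 40), sprintf("S%02d", 1:40))
  sp <- split_responders(fc, 20)
  expect_length(sp$strong, 20)
  expect_length(sp$weak, 20)
  expect_length(intersect(sp$strong, sp$weak), 0)
  # strictly increasing values: bottom 20 = strong (largest impairment)
  expect_setequal(sp$strong, sprintf("S%02d", 1:20))
  expect_setequal(sp$weak, sprintf("S%02d", 21:40))

  # all-equal values: tie rule = subject order, sizes still 20/20
  sp2 <- split_responders(stats::setNames(rep(1, 40), sprintf("S%02d", 1:40)), 20)
  expect_setequal(sp2$strong, sprintf("S%02d", 1:20))
  expect_length(sp2$weak, 20)

  expect_error(split_responders(fc[1:30], 20), "at least 40")
})

test_that("zscore_cluster normalizes rows and orders leaves like the oracle", {
  set.seed(4)
  chg <- matrix(rnorm(12 * 6), 12, 6,
                dimnames = list(NULL, paste0("P", 1:6)))
  g <- rep(c("strong", "weak"), each = 6)
  # use >2 groups for a meaningful z: split subjects into 4 pseudo-groups
  g4 <- rep(c("a", "b", "c", "d"), each = 3)
  zc <- zscore_cluster(chg, g4)
  expect_equal(unname(rowMeans(zc$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(zc$z, 1, sd)), rep(1, 6), tolerance = 1e-12)

  # z-normalization is idempotent
  z2 <- t(apply(zc$z, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(unname(z2), unname(zc$z), tolerance = 1e-12)

  # identical-profile proteins merge first (distance 0)
  chg2 <- chg
  chg2[, 2] <- chg2[, 1]
  zc2 <- zscore_cluster(chg2, g4)
  expect_equal(sort(zc2$hclust$merge[1, ]), c(-2, -1))
  expect_equal(zc2$hclust$height[1], 0)

  # group means and z computed independently; merge heights match a naive
  # average-linkage implementation on that oracle matrix
  z_oracle <- matrix(NA_real_, 6, 4)
  for (j in 1:6) {
    gm <- numeric(4)
    for (k in seq_along(unique(g4))) {
      gm[k] <- mean(chg[g4 == unique(g4)[k], j])
    }
    z_oracle[j, ] <- (gm - mean(gm)) / sd(gm)
  }
  # zc$z rows are in leaf order; realign to protein order for comparison
  expect_equal(unname(zc$z[paste0("P", 1:6), ]), z_oracle, tolerance = 1e-12)
  expect_equal(zc$hclust$height, bf_average_linkage_heights(z_oracle),
               tolerance = 1e-10)
  # the two closest proteins (brute-force argmin) are adjacent leaves and
  # form the first merge
  dm <- as.matrix(dist(z_oracle)); diag(dm) <- Inf
  closest <- sort(arrayInd(which.min(dm), dim(dm))[1, ])
  expect_setequal(-zc$hclust$merge[1, ], closest)
  pos <- match(paste0("P", closest), zc$order)
  expect_equal(abs(diff(pos)), 1)

  # single protein returned unclustered with a note
  zc1 <- zscore_cluster(chg[, 1, drop = FALSE], g4)
  expect_null(zc1$hclust)
  expect_match(zc1$note, "single")
})

test_that("pca_scores separates constructed clusters on PC1", {
  set.seed(5)
  chg <- matrix(rnorm(40 * 30), 40, 30)
  chg[1:20, 1:12] <- chg[1:20, 1:12] + 3  # group shift on 12 proteins
  pc <- pca_scores(chg)
  s1 <- sign(pc$scores[1:20, 1])
  s2 <- sign(pc$scores[21:40, 1])
  concord <- max(mean(c(s1 == 1, s2 == -1)), mean(c(s1 == -1, s2 == 1)))
  expect_gte(concord, 0.9)
  expect_lte(sum(pc$explained), 1)

  # scores invariant to protein order (up to nothing: identical)
  pc2 <- pca_scores(chg[, sample(30)])
  expect_equal(abs(pc2$scores[, 1]), abs(pc$scores[, 1]), tolerance = 1e-8)

  expect_error(pca_scores(chg[1, , drop = FALSE]), ">= 2 subjects")
})

test_that("filter_network applies the strict score threshold", {
  edges <- data.frame(node_a = c("A", "B", "C", "D"),
                      node_b = c("B", "C", "D", "E"),
                      score = c(0.5, 0.5, 0.3, 0.4))
  net <- filter_network(edges, 0.4)
  # 0.4 excluded (strict), 0.3 excluded -> chain A-B-C remains
  expect_equal(nrow(net$edges), 2)
  comp_abc <- net$components$component[match(c("A", "B", "C"),
                                             net$components$node)]
  expect_equal(length(unique(comp_abc)), 1)

  expect_equal(nrow(filter_network(transform(edges, score = 0.3), 0.4)$edges), 0)
  expect_error(filter_network(data.frame(node_a = "A", node_b = "B",
                                         score = "x")), "malformed|non-numeric")
  expect_error(filter_network(transform(edges, score = 1.5)), "\\[0, 1\\]")

  # node_set restriction
  net2 <- filter_network(edges, 0.2, node_set = c("A", "B"))
  expect_equal(nrow(net2$edges), 1)
})

test_that("run_proteomics recovers injected responder proteins", {
  npx <- fixture_npx(shift = 3, n_shifted = 12, seed = 6)
  res <- run_proteomics(npx)
  recall <- mean(npx$truth$shifted_proteins %in% res$de$protein[res$de$retained])
  expect_gte(recall, 0.95)
  # PCA separates strong vs weak responders
  sc <- res$pca$scores[, 1]
  grp <- res$group
  concord <- max(mean(sign(sc) == ifelse(grp == "strong", 1, -1)),
                 mean(sign(sc) == ifelse(grp == "strong", -1, 1)))
  expect_gte(concord, 0.9)
})
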