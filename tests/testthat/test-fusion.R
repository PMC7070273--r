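test_that("standardization hits the z-score closed forms", {
  ft <- feature_table(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a")))
  z <- standardize(ft)
  expect_equal(unname(z$features[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  # population sd: sqrt(2/3) for (1,2,3) => scores +-1.2247
  expect_equal(max(z$features), 1.2247, tolerance = 1e-4)
  # sample-sd variant
  zs <- standardize(ft, sd_type = "sample")
  expect_equal(unname(zs$features[, 1]), c(-1, 0, 1))
})

test_that("standardization is idempotent and centers exactly", {
  ft <- random_ft(20, 4, seed = 5)
  z <- standardize(ft)
  expect_lt(max(abs(colMeans(z$features))), 1e-12)
  expect_equal(standardize(z)$features, z$features, tolerance = 1e-12)
  const <- feature_table(cbind(ft$features, k1 = 1))
  expect_error(standardize(const), "k1")
})

test_that("the e-tongue weighting factor reproduces 16/9 and its limits", {
  expect_equal(compute_etongue_weight(), 16 / 9)
  sym <- fusion_spec("weighted",
                     sensory_weights = c(appearance = 0.2, aroma = 0.3,
                                         taste = 0.3, flavor = 0.2))
  expect_equal(compute_etongue_weight(sym, 10, 10), 1)
  rat <- fusion_spec("weighted",
                     sensory_weights = c(appearance = 0.2, aroma = 0.2,
                                         taste = 0.4, flavor = 0.2))
  expect_equal(compute_etongue_weight(rat, 12, 12), 2)
  zero <- fusion_spec("weighted",
                      sensory_weights = c(appearance = 0.4, aroma = 0,
                                          taste = 0.4, flavor = 0.2))
  expect_error(compute_etongue_weight(zero), "aroma")
  # explicit override wins
  expect_equal(compute_etongue_weight(fusion_spec("weighted", weight = 3)), 3)
})

test_that("fusion concatenates 18 + 24 standardized columns", {
  tiny <- cache_fixture("tiny_noisy", tiny_dataset(2, 0.05, seed = 11))
  direct <- fuse(tiny$etongue, tiny$enose, fusion_spec("direct"))
  weighted <- fuse(tiny$etongue, tiny$enose, fusion_spec("weighted"))
  expect_equal(ncol(direct$features), 42)
  expect_identical(colnames(direct$features),
                   c(etongue_feature_names(), enose_feature_names()))
  # weighting touches the e-tongue block only
  expect_equal(weighted$features[, 19:42], direct$features[, 19:42])
  expect_equal(weighted$features[, 1:18], direct$features[, 1:18] * 16 / 9)
  # W = 1 collapses weighted onto direct
  w1 <- fuse(tiny$etongue, tiny$enose, fusion_spec("weighted", weight = 1))
  expect_equal(w1$features, direct$features)
  expect_equal(direct$age_years, tiny$etongue$age_years)
})

test_that("fusion rejects mismatched sample sets, listing the differences", {
  tiny <- cache_fixture("tiny_noisy", tiny_dataset(2, 0.05, seed = 11))
  clipped <- flavorfuse:::ft_subset(tiny$enose, -1)
  missing_id <- setdiff(tiny$etongue$sample_id, clipped$sample_id)
  expect_error(fuse(tiny$etongue, clipped, fusion_spec("direct")),
               missing_id, fixed = TRUE)
})

test_that("fused row order follows the e-tongue table regardless of e-nose order", {
  tiny <- cache_fixture("tiny_noisy", tiny_dataset(2, 0.05, seed = 11))
  shuffled <- flavorfuse:::ft_subset(tiny$enose,
                                     rev(seq_along(tiny$enose$sample_id)))
  expect_equal(fuse(tiny$etongue, shuffled, fusion_spec("direct")),
               fuse(tiny$etongue, tiny$enose, fusion_spec("direct")))
})

test_that("pearson matrix matches the direct covariance formula", {
  ft <- random_ft(5, 4, seed = 8)
  r <- pearson_matrix(ft)
  x <- ft$features
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    oracle[i, j] <- sum(xi * xj) /
      (nrow(x) * sd(x[, i]) * sd(x[, j]) * (nrow(x) - 1) / nrow(x))
  }
  expect_equal(unname(r), oracle, tolerance = 1e-10)
  expect_equal(diag(r), setNames(rep(1, 4), colnames(x)))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("pearson matrix flags duplicates, negations and constants", {
  x <- random_ft(10, 2, seed = 2)$features
  ft <- feature_table(cbind(x, dup = x[, 1], neg = -x[, 2]))
  r <- pearson_matrix(ft)
  expect_equal(r["f1", "dup"], 1)
  expect_equal(r["f2", "neg"], -1)
  expect_error(pearson_matrix(feature_table(cbind(x, k = 5))), "k")
  expect_error(pearson_matrix(flavorfuse:::ft_subset(ft, 1:2)), "3 samples")
})

test_that("VIF elimination leaves uncorrelated designs untouched", {
  # columns mutually orthogonal and orthogonal to the intercept: VIF exactly 1
  x <- qr.Q(qr(cbind(1, random_ft(12, 4, seed = 3)$features)))[, -1]
  colnames(x) <- paste0("f", 1:4)
  res <- vif_eliminate(feature_table(x), threshold = 10)
  expect_equal(nrow(res$audit$elimination_order), 0)
  expect_equal(unname(res$audit$final_vifs), rep(1, 4), tolerance = 1e-8)
})

test_that("an exactly duplicated column is removed first, larger index wins", {
  x <- random_ft(15, 3, seed = 4)$features
  ft <- feature_table(cbind(x, f1_dup = x[, 1]))
  res <- vif_eliminate(ft, threshold = 10)
  expect_equal(res$audit$elimination_order$feature[1], "f1_dup")
  expect_equal(res$audit$elimination_order$vif_at_removal[1], Inf)
  expect_true("f1" %in% res$audit$surviving_features)
  expect_error(vif_eliminate(ft, threshold = 1), "exceed 1")
})

test_that("elimination sequence matches a step-recomputing OLS oracle", {
  set.seed(21)
  n <- 40
  a <- rnorm(n); b <- rnorm(n)
  x <- cbind(f1 = a, f2 = b, f3 = a + b + rnorm(n, 0, 0.05),
             f4 = rnorm(n), f5 = a - 0.5 * b + rnorm(n, 0, 0.08))
  ft <- feature_table(x)
  res <- vif_eliminate(ft, threshold = 10)

  # oracle: explicit normal-equations VIFs, recomputed at every step
  oracle_vif <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      y <- m[, j]; z <- cbind(1, m[, -j, drop = FALSE])
      beta <- solve(t(z) %*% z, t(z) %*% y)
      r2 <- 1 - sum((y - z %*% beta)^2) / sum((y - mean(y))^2)
      1 / (1 - r2)
    }, numeric(1))
  }
  m <- x
  removed <- character(0)
  repeat {
    v <- oracle_vif(m)
    if (max(v) < 10) break
    worst <- max(which(v == max(v)))
    removed <- c(removed, colnames(m)[worst])
    m <- m[, -worst, drop = FALSE]
  }
  expect_identical(res$audit$elimination_order$feature, removed)
  expect_identical(res$audit$surviving_features, colnames(m))
})

test_that("VIF elimination is idempotent and bounded by the threshold", {
  tiny <- cache_fixture("tiny_noisy4", tiny_dataset(4, 0.05, seed = 11))
  fused <- fuse(tiny$etongue, tiny$enose, fusion_spec("direct"))
  res <- vif_eliminate(fused, threshold = 10)
  expect_lt(max(res$audit$final_vifs), 10)
  again <- vif_eliminate(res$table, threshold = 10)
  expect_equal(nrow(again$audit$elimination_order), 0)
  expect_identical(again$audit$surviving_features,
                   res$audit$surviving_features)
  # partition property: removed and surviving cover the original features
  expect_setequal(c(res$audit$elimination_order$feature,
                    res$audit$surviving_features),
                  colnames(fused$features))
})
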