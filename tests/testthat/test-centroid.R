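test_that("centroid fitting standardizes and averages as hand-computed", {
  # 5-gene toy with hand-computable centroids
  X <- matrix(c(1, 2, 3, 4, 5,
                2, 3, 4, 5, 6,
                7, 8, 9, 10, 11,
                8, 9, 10, 11, 12), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  labels <- c("R", "R", "NR", "NR")
  m <- fit_nearest_centroid(expression_matrix(X, "lognorm"), labels,
                            paste0("g", 1:5))
  mu <- rowMeans(X); sd <- apply(X, 1, sd)
  Z <- (X - mu) / sd
  expect_equal(m$centroid_pos, rowMeans(Z[, 3:4]))
  expect_equal(m$centroid_neg, rowMeans(Z[, 1:2]))

  # identical training data in both classes -> identical centroids
  X2 <- cbind(X[, 1:2], X[, 1:2])
  colnames(X2) <- paste0("s", 1:4)
  X2 <- X2 + matrix(c(0, 0.1), 5, 4, byrow = TRUE)[, c(1, 2, 1, 2)] * 0
  m2 <- fit_nearest_centroid(expression_matrix(X2, "lognorm"), labels,
                             paste0("g", 1:5))
  expect_equal(m2$centroid_pos, m2$centroid_neg)

  # difference confined to one gene
  X3 <- X2; X3["g3", 3:4] <- X3["g3", 3:4] + 5
  m3 <- fit_nearest_centroid(expression_matrix(X3, "lognorm"), labels,
                             paste0("g", 1:5))
  d <- m3$centroid_pos - m3$centroid_neg
  expect_true(abs(d["g3"]) > 0)
  expect_equal(unname(d[c("g1", "g2", "g4", "g5")]), rep(0, 4))

  # absent genes are dropped with a warning; < 3 usable is an error
  expect_warning(fit_nearest_centroid(expression_matrix(X, "lognorm"),
                                      labels, c(paste0("g", 1:5), "nope")),
                 "absent")
  expect_error(suppressWarnings(
    fit_nearest_centroid(expression_matrix(X, "lognorm"), labels,
                         c("g1", "g2", "zz"))), "fewer than 3")
})

test_that("prediction scores equal signed centroid distance differences", {
  withr::with_seed(20, {
    X <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
    labels <- rep(c("NR", "R"), 15)
    X[, labels == "NR"] <- X[, labels == "NR"] + 1
    m <- fit_nearest_centroid(expression_matrix(X, "lognorm"), labels,
                              paste0("g", 1:5))
    # independent distance oracle
    x <- X[, 7]
    v <- (x - m$scale$mean) / m$scale$sd
    oracle <- sqrt(sum((v - m$centroid_neg)^2)) -
      sqrt(sum((v - m$centroid_pos)^2))
    expect_equal(prediction_score(m, x), oracle, tolerance = 1e-12)

    # a sample at the positive centroid scores +||c_neg - c_pos||
    x_pos <- m$scale$mean + m$scale$sd * m$centroid_pos
    expect_equal(prediction_score(m, x_pos),
                 sqrt(sum((m$centroid_neg - m$centroid_pos)^2)),
                 tolerance = 1e-12)
    # equidistant sample scores 0
    x_mid <- m$scale$mean + m$scale$sd * (m$centroid_pos + m$centroid_neg) / 2
    expect_equal(prediction_score(m, x_mid), 0, tolerance = 1e-12)
  })
})

test_that("Wilson intervals are correct, contained and well-covered", {
  ci <- wilson_ci(7, 7)
  expect_equal(unname(round(ci, 4)), c(0.6457, 1))
  expect_equal(unname(wilson_ci(0, 12)[1]), 0)

  # the interval always contains the point estimate
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(1:50, 1); k <- sample(0:n, 1)
      ci <- wilson_ci(k, n)
      expect_true(ci[1] <= k / n + 1e-12 && k / n <= ci[2] + 1e-12)
    }
  })

  # empirical coverage at p = 0.3, n = 30 over 10,000 draws
  withr::with_seed(22, {
    k <- rbinom(10000, 30, 0.3)
    lo <- vapply(k, function(x) wilson_ci(x, 30)[1], 0)
    hi <- vapply(k, function(x) wilson_ci(x, 30)[2], 0)
    cover <- mean(lo <= 0.3 & 0.3 <= hi)
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.97)
  })
  expect_error(wilson_ci(0, 0), "n must be")
})

test_that("Welch ROC p-values match hand computation and are affine-invariant", {
  # textbook two-sample computation
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  z <- c(a, b)
  labels <- rep(c("NR", "R"), each = 10)
  t_stat <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
  df <- (var(a) / 10 + var(b) / 10)^2 /
    ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  p_hand <- 2 * pt(-abs(t_stat), df)
  expect_equal(roc_pvalue_welch(z, labels), p_hand, tolerance = 1e-12)

  # affine transforms leave p unchanged
  expect_equal(roc_pvalue_welch(3 * z + 2, labels),
               roc_pvalue_welch(z, labels), tolerance = 1e-12)

  # identical multisets -> p = 1; both-constant equal means -> 1
  expect_equal(roc_pvalue_welch(c(a, a), labels), 1, tolerance = 1e-12)
  expect_equal(roc_pvalue_welch(rep(2, 20), labels), 1)
  expect_error(roc_pvalue_welch(z[1:3], c("NR", "R", "R")), ">= 2 samples")
})

test_that("multiple random validation separates a separable cohort perfectly", {
  co <- separable_cohort()
  rep <- multiple_random_validation(co$expr, co$labels, rownames(co$expr),
                                    n_rep = 50, seed = 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$sens, 1)
  expect_equal(rep$spec, 1)
  expect_lt(rep$p_roc, 1e-6)
  expect_true(rep$all_held_out)
  expect_true(all(rep$z[co$labels == "NR"] > 0))
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  bulk <- fixture_bulk()
  sc <- fixture_sc()
  rep <- multiple_random_validation(bulk$expr, bulk$sample_meta$response,
                                    sc$truth$planted_genes$resistance,
                                    n_rep = 30, seed = 2, n_boot = 0)
  bf <- auc_bruteforce(rep$z, rep$labels == "NR")
  expect_equal(rep$auc, bf, tolerance = 1e-12)

  # and on noisy scores with ties
  withr::with_seed(23, {
    z <- sample(c(1, 2, 2, 3, 4), 60, TRUE)
    pos <- sample(c(TRUE, FALSE), 60, TRUE)
    expect_equal(auc_midrank(z, pos), auc_bruteforce(z, pos),
                 tolerance = 1e-12)
  })
})

test_that("validation reports are seed-stable and role-symmetric", {
  co <- separable_cohort(n_per_class = 15)
  r1 <- multiple_random_validation(co$expr, co$labels, rownames(co$expr),
                                   n_rep = 40, seed = 9, n_boot = 0)
  r2 <- multiple_random_validation(co$expr, co$labels, rownames(co$expr),
                                   n_rep = 40, seed = 9, n_boot = 0)
  expect_identical(r1$z, r2$z)
  expect_identical(r1$auc, r2$auc)

  # swapping class roles negates z; the same z under swapped positive class
  # gives the complementary AUC
  r3 <- multiple_random_validation(co$expr, co$labels, rownames(co$expr),
                                   n_rep = 40, seed = 9, n_boot = 0,
                                   class_pos = "R", class_neg = "NR")
  expect_equal(unname(r3$z), -unname(r1$z), tolerance = 1e-10)
  expect_equal(auc_midrank(r1$z, r1$labels == "R"), 1 - r1$auc,
               tolerance = 1e-12)

  # AUC varies little across seeds on a separable cohort
  bulk <- fixture_bulk(); scf <- fixture_sc()
  aucs <- vapply(1:4, function(s) {
    panel_auc(bulk$expr, bulk$sample_meta$response,
              scf$truth$planted_genes$resistance, n_rep = 100, seed = s)
  }, 0)
  expect_lt(max(aucs) - min(aucs), 0.02)

  tiny <- separable_cohort(n_per_class = 1)
  expect_error(multiple_random_validation(tiny$expr, tiny$labels,
                                          rownames(tiny$expr), seed = 1),
               ">= 2 samples")
})

test_that("logistic conversion recovers slopes and handles degeneracy", {
  withr::with_seed(24, {
    z <- rnorm(500)
    y <- rbinom(500, 1, plogis(-0.5 + 1.5 * z))
    labels <- ifelse(y == 1, "NR", "R")
    rp <- score_to_probability(z, labels)
    expect_equal(rp$slope, 1.5, tolerance = 0.2)
    expect_false(rp$separated)
    expect_true(all(diff(rp$probability[order(z)]) >= -1e-12))

    # constant score -> slope 0, probability = prevalence
    rp0 <- score_to_probability(rep(1, 100), rep(c("NR", "R"), 50))
    expect_equal(rp0$slope, 0)
    expect_equal(unique(rp0$probability), 0.5)

    # label flip negates the slope
    rp_f <- score_to_probability(z, ifelse(labels == "NR", "R", "NR"),
                                 class_pos = "NR")
    expect_equal(rp_f$slope, -rp$slope, tolerance = 1e-6)

    # complete separation is flagged and clipped
    zs <- c(rnorm(20, -5), rnorm(20, 5))
    ls <- rep(c("R", "NR"), each = 20)
    rp_s <- score_to_probability(zs, ls)
    expect_true(rp_s$separated)
    expect_lte(abs(rp_s$slope), 20)
  })
  expect_error(score_to_probability(1:5, rep("NR", 5)), "both classes")
})
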