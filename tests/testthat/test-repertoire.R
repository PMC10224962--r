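test_that("per-type summaries reproduce the generating moments", {
  z <- synthesis_spec("single", f0_mean_dist = c(700, 0),
                      f0_range_dist = c(100, 0), f0_min_dist = c(650, 0),
                      f0_max_dist = c(750, 0), q25_dist = c(600, 0),
                      q50_dist = c(900, 0), q75_dist = c(1800, 0),
                      duration_dist = c(0.2, 0), am_rate_dist = c(20, 0),
                      fm_rate_dist = c(5, 0))
  zt <- sample_feature_table(list(single = z), n_per_type = 6, seed = 2)
  s <- summarize_repertoire(zt)
  expect_true(all(s$sd == 0))
  expect_equal(s$mean[s$parameter == "f0_mean"], 700)
  expect_equal(unique(s$call_type), "single")
  expect_true(!is.null(attr(s, "wide")))

  big <- sample_feature_table(default_specs()["clucking"],
                              n_per_type = 10000, seed = 6)
  sb <- summarize_repertoire(big)
  expect_lt(abs(sb$mean[sb$parameter == "duration"] - 0.09),
            3 * 0.02 / sqrt(10000))
  lone <- zt[1, ]
  expect_warning(s1 <- summarize_repertoire(lone), "< 2 calls")
  expect_true(all(is.na(s1$sd)))
})

test_that("standardised PCA conserves trace and yields orthonormal loadings", {
  tab <- sample_feature_table(default_specs(), n_per_type = 30, seed = 4)
  m <- fit_pca(tab)
  p <- length(m$features_used)
  expect_equal(sum(m$eigenvalues), p, tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_equal(crossprod(m$loadings), diag(p), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(m$eigenvalues[m$retained] > 1))
  # lossless reconstruction from all components
  X <- as.matrix(tab[order(tab$call_id), m$features_used])
  Z <- scale(X, center = m$center, scale = m$scale)
  expect_equal(m$scores %*% t(m$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("an equicorrelated factor inflates the leading eigenvalue as 1+(p-1)rho", {
  set.seed(42)
  p <- 6; rho <- 0.5; n <- 4000
  shared <- rnorm(n)
  X <- sqrt(rho) * matrix(shared, n, p) +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  tab <- data.frame(call_id = sprintf("c%04d", 1:n), call_type = "single", X)
  m <- suppressWarnings(fit_pca(tab))
  expect_equal(m$eigenvalues[1], 1 + (p - 1) * rho, tolerance = 0.05)
})

test_that("constant feature columns are dropped with a warning", {
  tab <- null_table(k = 2, n_per = 10, p = 3)
  tab$f3 <- 5
  expect_warning(m <- fit_pca(tab), "zero-variance")
  expect_equal(length(m$features_used), 2)
})

test_that("LOO classification separates separable data and matches a brute-force oracle", {
  sep <- separated_table(k = 2, n_per = 10)
  expect_equal(classify_loo(sep)$rate, 1.0)

  # chance-level behaviour on unstructured data
  nul <- null_table(k = 8, n_per = 20)
  r <- classify_loo(nul)$rate
  expect_gt(r, 0.02)
  expect_lt(r, 0.30)

  # brute-force oracle on a 20-call instance: refit everything from scratch
  # per fold with independent code (formula interface, manual scaling)
  small <- separated_table(k = 2, n_per = 5, gap = 2, seed = 15)
  small <- rbind(small, separated_table(k = 2, n_per = 5, gap = 2, seed = 16))
  small$call_id <- sprintf("c%03d", seq_len(nrow(small)))
  small <- small[order(small$call_id), ]
  fcols <- paste0("f", 1:4)
  oracle_preds <- vapply(seq_len(nrow(small)), function(i) {
    tr <- small[-i, ]; te <- small[i, ]
    mu <- colMeans(tr[fcols]); sg <- sapply(tr[fcols], sd)
    Ztr <- scale(as.matrix(tr[fcols]), mu, sg)
    pc <- prcomp(Ztr, center = FALSE, scale. = FALSE)
    keep <- which(pc$sdev^2 > 1)
    if (!length(keep)) keep <- 1L
    str <- as.data.frame(pc$x[, keep, drop = FALSE])
    ste <- as.data.frame(scale(as.matrix(te[fcols]), mu, sg) %*%
                           pc$rotation[, keep, drop = FALSE])
    names(ste) <- names(str)
    str$g <- factor(tr$call_type)
    fit <- MASS::lda(g ~ ., data = str, prior = c(0.5, 0.5))
    as.character(predict(fit, ste)$class)
  }, character(1))
  got <- classify_loo(small, mode = "refit")
  expect_equal(got$predictions, oracle_preds)
  expect_equal(got$rate, mean(oracle_preds == small$call_type))
})

test_that("global-PCA mode reproduces the one-shot lda(CV = TRUE) shortcut", {
  tab <- sample_feature_table(default_specs(), n_per_type = 10, seed = 23)
  g <- classify_loo(tab, mode = "global")
  m <- suppressWarnings(fit_pca(tab))
  lab <- factor(tab$call_type[order(tab$call_id)])
  cv <- MASS::lda(m$scores[, m$retained, drop = FALSE], grouping = lab,
                  prior = rep(1 / 8, 8), CV = TRUE)
  expect_equal(g$rate, mean(as.character(cv$class) == as.character(lab)))
})

test_that("the permutation null is centred on chance and the p-value uses add-one", {
  # p-value floor on perfectly separated clusters
  sep <- separated_table(k = 2, n_per = 10)
  pr <- suppressWarnings(permutation_test(sep, n_permutations = 99, seed = 3))
  expect_equal(pr$observed_ccr, 1.0)
  expect_equal(pr$p_value, 1 / 100)
  expect_equal(pr$p_value,
               (1 + sum(pr$null_ccrs >= pr$observed_ccr)) /
                 (1 + pr$n_permutations))
  expect_equal(pr$chance_expectation, mean(pr$null_ccrs))
  expect_gt(pr$p_value, 0)
  expect_lte(pr$p_value, 1)

  # null centring at 1/k for balanced classes
  for (k in c(2, 4)) {
    tab <- null_table(k = k, n_per = 12, p = 4, seed = 50 + k)
    pk <- permutation_test(tab, n_permutations = 150, seed = 60 + k)
    expect_lt(abs(pk$chance_expectation - 1 / k),
              3 * sd(pk$null_ccrs) / sqrt(150), label = paste("k =", k))
  }
})

test_that("row order never changes the analysis (canonicalised by call_id)", {
  tab <- sample_feature_table(default_specs()[c("clucking", "terror",
                                                "short")],
                              n_per_type = 8, seed = 9)
  shuf <- tab[sample.int(nrow(tab)), ]
  a <- permutation_test(tab, n_permutations = 20, seed = 5) |>
    suppressWarnings()
  b <- permutation_test(shuf, n_permutations = 20, seed = 5) |>
    suppressWarnings()
  expect_identical(a$null_ccrs, b$null_ccrs)
  expect_identical(a$observed_ccr, b$observed_ccr)
  expect_identical(classify_loo(tab)$rate, classify_loo(shuf)$rate)
})
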