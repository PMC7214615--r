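test_that("ICC(2,1) reproduces the ANOVA decomposition", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(icc_2_1(x, y), aov_icc(x, y), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- a + rnorm(length(a), sd = 0.5)
    expect_equal(icc_2_1(a, b), aov_icc(a, b), tolerance = 1e-10)
  }
  # perfect agreement
  z <- c(3, 1, 4, 1, 5)
  expect_equal(icc_2_1(z, z), 1)
  # independent measurements: ICC near zero at large n
  set.seed(8)
  expect_lt(abs(icc_2_1(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(icc_2_1(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(icc_2_1(1:2, 1:2), "3 subject")
})

test_that("stability filter retains by ICC threshold and flags degeneracy", {
  set.seed(12)
  n <- 12
  t1 <- data.frame(stable = rnorm(n), noisy = rnorm(n), flat = rep(1, n))
  t2 <- t1
  t2$noisy <- rnorm(n)              # re-segmentation destroys this feature
  t2$stable <- t1$stable + rnorm(n, sd = 0.01)
  rownames(t1) <- rownames(t2) <- sprintf("P%02d", 1:n)
  rep <- stability_filter(t1, t2, threshold = 0.8)
  expect_s3_class(rep, "stability_report")
  expect_true(rep$retained[rep$feature == "stable"])
  expect_false(rep$retained[rep$feature == "noisy"])
  expect_true(rep$degenerate[rep$feature == "flat"])
  expect_false(rep$retained[rep$feature == "flat"])
  # retention is exactly icc >= threshold
  expect_equal(rep$retained, !rep$degenerate & rep$icc >= 0.8)
  # raising the threshold never grows the retained set
  rep2 <- stability_filter(t1, t2, threshold = 0.9)
  expect_true(all(rep$feature[rep2$retained] %in% rep$feature[rep$retained]))
  expect_error(stability_filter(t1[1:2, ], t2[1:2, ]), "3 overlapping")
})

test_that("redundancy filter keeps the more stable member of correlated pairs", {
  set.seed(3)
  n <- 40
  base <- rnorm(n)
  tab <- data.frame(A = base + rnorm(n, sd = 0.1))
  tab$B <- tab$A                       # perfect duplicate
  tab$C <- rnorm(n)                    # independent
  rownames(tab) <- sprintf("P%02d", 1:n)
  iccs <- c(A = 0.9, B = 0.85, C = 0.7)
  kept <- redundancy_filter(tab, iccs, r_threshold = 0.6)
  expect_setequal(kept, c("A", "C"))
  # mutually uncorrelated features all survive
  set.seed(6)
  ind <- as.data.frame(matrix(rnorm(200 * 4), 200))
  colnames(ind) <- LETTERS[1:4]
  expect_setequal(redundancy_filter(ind, c(A = .9, B = .8, C = .7, D = .6)),
                  LETTERS[1:4])
})

test_that("correlation chains drop the middle feature and bound pairwise |r|", {
  # construct A~B ~ 0.7, B~C ~ 0.7, A~C ~ 0.2 with ICC order A > B > C
  set.seed(31)
  n <- 4000
  u <- rnorm(n); v <- rnorm(n); w <- rnorm(n)
  A <- u
  B <- 0.7 * u + 0.714 * v
  C <- 0.2 * u + 0.784 * v + 0.587 * w
  tab <- data.frame(A, B, C)
  stopifnot(abs(cor(A, B)) > 0.6, abs(cor(B, C)) > 0.6,
            abs(cor(A, C)) < 0.6)
  kept <- redundancy_filter(tab, c(A = 0.95, B = 0.9, C = 0.85), 0.6)
  expect_setequal(kept, c("A", "C"))
  # the output always satisfies the pairwise bound (checked exhaustively)
  cm <- abs(cor(tab[kept]))
  expect_lte(max(cm[upper.tri(cm)]), 0.6)
})

test_that("LASSO signatures select the separating feature and score linearly", {
  set.seed(23)
  n <- 60
  labels <- rep(c(0L, 1L), each = n / 2)
  hits <- 0
  for (s in 1:5) {
    tab <- as.data.frame(matrix(rnorm(n * 10), n))
    colnames(tab) <- paste0("f", 1:10)
    tab$f1 <- labels * 3 + rnorm(n, sd = 0.2)   # near-perfect separator
    rownames(tab) <- sprintf("P%02d", 1:n)
    sig <- fit_habitat_signature(tab, labels, cv_folds = 5, seed = s,
                                 habitat = "toy")
    if ("f1" %in% sig$features) hits <- hits + 1
    expect_gte(sig$training_auc, 0.95)
  }
  expect_gte(hits, 4)
  # scoring is the stored affine map: a known shift in one raw feature
  # moves the score by coef * shift / sd
  tab <- as.data.frame(matrix(rnorm(n * 5), n))
  colnames(tab) <- paste0("f", 1:5)
  tab$f2 <- labels * 2 + rnorm(n)
  rownames(tab) <- sprintf("P%02d", 1:n)
  sig <- fit_habitat_signature(tab, labels, cv_folds = 5, seed = 1)
  expect_gt(length(sig$features), 0)
  f <- sig$features[1]
  v <- tab[1, , drop = FALSE]
  v2 <- v; v2[[f]] <- v2[[f]] + 1.5
  delta <- signature_score(sig, v2) - signature_score(sig, v)
  k <- match(f, sig$features)
  expect_equal(delta, unname(sig$coefficients[k] * 1.5 / sig$scale[k]),
               tolerance = 1e-10)
  expect_error(signature_score(sig, v[, setdiff(colnames(v), f),
                                      drop = FALSE]),
               "missing feature")
  # training AUC is reproduced from the stored training scores
  expect_equal(brute_auc(signature_score(sig, tab), labels),
               sig$training_auc, tolerance = 1e-12)
})

test_that("an empty signature scores every patient at the intercept", {
  sig <- structure(list(habitat = "h", features = character(0),
                        coefficients = numeric(0), intercept = 0.37,
                        center = numeric(0), scale = numeric(0),
                        lambda = Inf, empty = TRUE, training_auc = 0.5),
                   class = "habitat_signature")
  tab <- data.frame(a = rnorm(5), b = rnorm(5))
  expect_equal(signature_score(sig, tab), rep(0.37, 5))
})

test_that("informative features are selected more often than noise", {
  set.seed(77)
  n <- 60
  freq <- setNames(numeric(53), c(paste0("inf", 1:3), paste0("noise", 1:50)))
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    X <- matrix(rnorm(n * 53), n)
    colnames(X) <- names(freq)
    X[, 1:3] <- X[, 1:3] + 1.2 * labels
    tab <- as.data.frame(X)
    rownames(tab) <- sprintf("P%02d", 1:n)
    sig <- fit_habitat_signature(tab, labels, cv_folds = 5, seed = s)
    freq[sig$features] <- freq[sig$features] + 1
  }
  expect_gt(mean(freq[1:3]), mean(freq[-(1:3)]))
  expect_gte(mean(freq[1:3]), 0.3 * n_seeds)
})
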