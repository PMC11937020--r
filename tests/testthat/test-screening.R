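test_that("univariate gaussian LASSO matches the soft-threshold closed form", {
  set.seed(5)
  n <- 60
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(sum((x - mean(x))^2) / n)  # mean 0, 1/n-variance 1
  y <- 0.8 * x + rnorm(n, 0, 0.5)
  r <- lasso_screen(data.frame(x = x), y, k_folds = 10, seed = 1,
                    family = "gaussian")
  bhat <- sum(x * (y - mean(y))) / sum(x^2)            # OLS on centred data
  for (lam in c(r$lambda_min, r$lambda_1se)) {
    soft <- sign(bhat) * max(abs(bhat) - lam, 0)
    got <- as.numeric(glmnet::coef.glmnet(r$glmnet_cv, s = lam))[2]
    expect_equal(got, soft, tolerance = 1e-3)
  }
})

test_that("selection at the deviance-minimising penalty recovers planted signal", {
  hits <- 0
  for (s in 1:25) {
    ft <- simulate_feature_table(n_per_group = 6,
                                 groups = c("control", "stress"), seed = s)
    r <- suppressWarnings(
      lasso_screen(ft, factor(ft$group), k_folds = 10, seed = s))
    if (all(c("I0", "CPS") %in% r$selected_features$lambda_min)) hits <- hits + 1
  }
  expect_gte(hits, 21)   # >= ~85% on this short run; acceptance uses 100 seeds
})

test_that("the 1-SE rule mostly selects nothing under the null", {
  empty <- 0
  for (s in 1:40) {
    ft <- simulate_feature_table(n_per_group = 8, groups = c("a", "b"),
                                 i0_mult = c(a = 1, b = 1),
                                 cps_mult = c(a = 1, b = 1), seed = 7000 + s)
    r <- suppressWarnings(
      lasso_screen(ft, factor(ft$group), k_folds = 10, seed = s))
    if (length(r$selected_features$lambda_1se) == 0) empty <- empty + 1
  }
  expect_gte(empty / 40, 0.70)   # measured null rate ~0.8 for the 1-SE rule
})

test_that("screening results respect the penalty-path invariants", {
  ft <- simulate_feature_table(n_per_group = 6,
                               groups = c("control", "stress"), seed = 3)
  r <- suppressWarnings(lasso_screen(ft, factor(ft$group), seed = 3))
  expect_gte(r$lambda_1se, r$lambda_min)
  expect_true(all(r$selected_features$lambda_1se %in%
                    r$selected_features$lambda_min))
  # at the largest penalty of the path all coefficients vanish
  b_top <- as.matrix(glmnet::coef.glmnet(r$glmnet_cv,
                                         s = max(r$lambda_path)))
  expect_true(all(b_top[-1, 1] == 0))
})

test_that("degenerate screening inputs are handled", {
  ft <- simulate_feature_table(n_per_group = 4,
                               groups = c("control", "stress"), seed = 2)
  expect_error(suppressWarnings(
    lasso_screen(ft, factor(rep("one", nrow(ft))))), "two classes")
  ft$B <- 1  # constant feature
  expect_warning(r <- lasso_screen(ft, factor(ft$group), seed = 1),
                 "constant feature")
  expect_false("B" %in% r$coefficients$lambda_min$feature)
})

test_that("PCA stratification behaves on reference geometries", {
  # two perfectly correlated features: PC1 carries all the variance
  x <- data.frame(f1 = 1:10, f2 = 2 * (1:10) + 3)
  p <- pca_stratify(x)
  expect_equal(p$explained_variance[1], 1)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  expect_error(pca_stratify(data.frame(f1 = rep(1, 5), f2 = 1:5)),
               "zero-variance")
  expect_error(pca_stratify(data.frame(f1 = 1:5)), ">= 2 features")
})

test_that("planted two-group separation shows up on PC1", {
  ft <- simulate_feature_table(n_per_group = 6,
                               groups = c("control", "stress"), seed = 11)
  p <- pca_stratify(ft, select = c("I0", "CPS"))
  pc1 <- p$scores$PC1
  grp <- ft$group
  between <- abs(mean(pc1[grp == "control"]) - mean(pc1[grp == "stress"]))
  within <- max(tapply(pc1, grp, stats::sd))
  expect_gt(between, within)
})

test_that("pooled t-test reproduces hand-computed replicate comparisons", {
  # pooled-variance arithmetic on four replicates per group
  tt <- group_ttest(c(128, 256, 128, 128), c(512, 512, 512, 512))
  expect_equal(tt$t, -11)
  expect_equal(tt$df, 6)
  expect_lt(tt$p, 0.05)
  # antisymmetry under swapping the groups
  rev <- group_ttest(c(512, 512, 512, 512), c(128, 256, 128, 128))
  expect_equal(rev$t, 11)
  expect_equal(rev$p, tt$p)
})

test_that("degenerate t-test inputs follow the stated conventions", {
  same <- group_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  diff <- group_ttest(c(2, 2, 2), c(3, 3, 3))
  expect_identical(diff$t, -Inf)
  expect_identical(diff$p, 0)
  expect_error(group_ttest(1, c(1, 2)), ">= 2 values")
  # Welch flag produces the unpooled df
  w <- group_ttest(c(1, 2, 3, 4), c(10, 30, 50), var_equal = FALSE)
  expect_lt(w$df, 5)
})
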