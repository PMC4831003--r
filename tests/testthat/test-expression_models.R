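test_that("expression targets are log levels over the maximum", {
  e <- expression_table(c("a", "b", "c"), c(0, 2^5 - 1, 2^10 - 1))
  p <- expression_target(e)
  expect_equal(unname(p), c(0, 0.5, 1))
  expect_error(expression_target(expression_table("a", 0)), "zero")
})

test_that("the zero logistic model predicts 0.5 and is monotone", {
  m0 <- structure(list(beta0 = 0, beta = c(0, 0), lambda = 0,
                       iterations = 0L), class = "logistic_model")
  expect_equal(predict(m0, matrix(rnorm(10), 5, 2)), rep(0.5, 5))
  m1 <- structure(list(beta0 = -1, beta = c(2, -1), lambda = 0,
                       iterations = 0L), class = "logistic_model")
  x <- cbind(seq(0, 1, 0.1), 0.5)
  expect_true(all(diff(predict(m1, x)) > 0))
})

test_that("fractional logistic fit recovers planted coefficients", {
  set.seed(42)
  n <- 5000L; K <- 10L
  X <- matrix(runif(n * K), n, K)
  beta <- c(2, -1.5, 1, -2, 0.8, -0.6, 1.2, -1, 0.5, -1.8)
  p <- plogis(-0.5 + as.vector(X %*% beta) + rnorm(n, sd = 0.3))
  fit <- fit_logistic(X, p)
  expect_equal(sum(sign(fit$beta) == sign(beta)), 10L)
  expect_lt(sqrt(mean((fit$beta - beta)^2)), 0.1)
  # feature reordering with matching coefficient reordering is invariant
  ord <- sample(K)
  fit2 <- fit_logistic(X[, ord], p)
  expect_equal(fit2$beta, fit$beta[ord], tolerance = 1e-6)
})

test_that("the unpenalized fit matches quasibinomial glm", {
  set.seed(17)
  X <- matrix(runif(400 * 3), 400, 3)
  p <- plogis(0.3 + as.vector(X %*% c(1, -2, 0.5)) + rnorm(400, sd = 0.4))
  fit <- fit_logistic(X, p, lambda = 0)
  g <- suppressWarnings(glm(p ~ X, family = quasibinomial()))
  expect_equal(c(fit$beta0, fit$beta), unname(coef(g)), tolerance = 1e-7)
  expect_error(fit_logistic(X[1:3, ], p[1:3]), "more genes")
})

test_that("a linear autoencoder attains the PCA optimum on rank-2 data", {
  set.seed(18)
  n <- 300L; d <- 40L
  basis <- matrix(rnorm(2 * d), 2, d)
  S <- plogis(matrix(rnorm(n * 2), n, 2) %*% basis)  # values in [0, 1]
  # project S onto an exactly rank-2 affine subspace
  ctr <- colMeans(S)
  Sc <- sweep(S, 2, ctr)
  pc <- prcomp(Sc, rank. = 2)
  S2 <- sweep(pc$x %*% t(pc$rotation), 2, ctr, `+`)
  ae <- fit_autoencoder(S2, latent = 2, seed = 1, activation = "linear",
                        maxit = 2000)
  expect_gte(ae$explained_variance, 0.999)
})

test_that("a full-width autoencoder reconstructs its input", {
  set.seed(19)
  S <- matrix(runif(200 * 12), 200, 12)
  ae <- fit_autoencoder(S, latent = 12, seed = 1, activation = "linear",
                        maxit = 2000)
  expect_gte(ae$explained_variance, 0.999)
  expect_lt(max(abs(reconstruct(ae, S) - S)), 0.05)
})

test_that("autoencoder training is deterministic and seed-stable", {
  set.seed(20)
  S <- plogis(matrix(rnorm(400 * 30), 400, 30))
  a1 <- fit_autoencoder(S, latent = 2, seed = 7)
  a1b <- fit_autoencoder(S, latent = 2, seed = 7)
  expect_identical(a1$W1, a1b$W1)
  a2 <- fit_autoencoder(S, latent = 2, seed = 8)
  expect_lt(abs(a1$explained_variance - a2$explained_variance), 0.01)
  expect_error(fit_autoencoder(matrix(0.5, 50, 10), latent = 2, seed = 1),
               "constant")
})

test_that("the expression net learns a noiseless monotone target", {
  set.seed(21)
  n <- 1500L; d <- 30L
  lat <- matrix(rnorm(n * 2), n, 2)
  S <- plogis(lat %*% matrix(rnorm(2 * d), 2, d))
  y <- 3 * plogis(2 * lat[, 1]) + 1  # noiseless monotone in coordinate 1
  ae <- fit_autoencoder(S, latent = 2, seed = 2)
  expect_warning(net <- fit_expression_net(ae, S, y, seed = 3, lambda = 0),
                 "scaled")
  expect_gte(net$metrics$spearman, 0.95)
})

test_that("label-shuffled targets carry no signal", {
  set.seed(22)
  n <- 3000L; d <- 20L
  lat <- matrix(rnorm(n * 2), n, 2)
  S <- plogis(lat %*% matrix(rnorm(2 * d), 2, d))
  y <- sample(3 * plogis(2 * lat[, 1]) + rnorm(n, sd = 0.1))
  ae <- fit_autoencoder(S, latent = 2, seed = 2, maxit = 200)
  suppressWarnings(net <- fit_expression_net(ae, S, y, seed = 3))
  expect_lt(abs(net$metrics$spearman), 0.05)
})

test_that("AUC follows the rank statistic and its invariances", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(23)
  s <- rnorm(200)
  l <- runif(200) < plogis(s)
  a1 <- auc(s, l)
  # invariant under strictly monotone transforms
  expect_equal(auc(exp(s), l), a1)
  expect_equal(auc(rank(s), l), a1)
  # cross-check against an independent ROC implementation
  a2 <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(auc(s, rep(TRUE, 200)), "single class")
})

test_that("the rank-sum statistic matches brute-force ranks and wilcox.test", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$W, 3)  # ranks 1 + 2
  set.seed(24)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  rs2 <- rank_sum_test(x, y)
  r <- rank(c(x, y))
  expect_equal(rs2$W, sum(r[1:30]))
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  # R's statistic is the Mann-Whitney U: W = U + n1 (n1 + 1) / 2
  expect_equal(rs2$W, unname(wt$statistic) + 30 * 31 / 2)
  expect_equal(rs2$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("chi-squared on a 2x2 table matches the hand formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  cs <- chisq_2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cs$statistic, sum((tab - E)^2 / E))
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(cs$df, 1)
})

test_that("metrics bundles correlations, AUC and the rank-sum test", {
  set.seed(25)
  truth <- rnorm(100, 5, 2)
  pred <- truth + rnorm(100)
  det <- truth > 5
  m <- metrics(pred, truth, detected = det,
               contingency = matrix(c(30, 10, 10, 50), 2, 2))
  expect_equal(m$pearson, cor(pred, truth))
  expect_equal(m$auc, auc(pred, det))
  expect_equal(m$wilcoxon$W, rank_sum_test(pred[det], pred[!det])$W)
  expect_equal(m$chisq$df, 1)
})
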