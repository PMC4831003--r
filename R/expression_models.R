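# Expression predictors: a fractional-target logistic model from measured
# peak heights, and an autoencoder-initialized neural network from the 334
# DNA-inferred signature values; plus the evaluation statistics.

#' Fractional expression targets
#'
#' The probability-scale target for the logistic model is each gene's log
#' level divided by the maximal log level observed, so targets lie in
#' `[0, 1]` with the most expressed gene at 1.
#'
#' @param table an [expression_table()].
#' @return Named numeric vector of targets in `[0, 1]`.
#' @export
expression_target <- function(table) {
  m <- max(table$log_level)
  if (m == 0) stop("all genes have zero expression; targets undefined")
  setNames(table$log_level / m, table$gene_id)
}

#' Fit the fractional-target logistic model
#'
#' Minimizes Bernoulli cross-entropy with fractional targets (the
#' quasi-likelihood extension of logistic regression, identical to ordinary
#' logistic regression when targets are 0/1) with a small L2 penalty on the
#' slopes for numerical stability, by Newton iterations.
#'
#' @param X genes x K matrix of features (e.g. peak heights in 200-bp
#'   windows).
#' @param p targets in `[0, 1]` (see [expression_target()]).
#' @param lambda L2 penalty on slopes (default 1e-4; the intercept is not
#'   penalized).
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return A `logistic_model`: list with `beta0`, `beta`, `lambda`,
#'   `iterations`.
#' @export
fit_logistic <- function(X, p, lambda = 1e-4, max_iter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(p), all(p >= 0 & p <= 1), ncol(X) >= 1L)
  if (nrow(X) <= ncol(X)) stop("need more genes than features")
  Xt <- cbind(1, X)
  k <- ncol(Xt)
  pen <- c(0, rep(lambda, k - 1L))
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xt %*% beta)
    mu <- plogis(eta)
    g <- as.vector(crossprod(Xt, mu - p)) + pen * beta
    if (sqrt(sum(g^2)) < tol) {
      out <- list(beta0 = beta[1L], beta = beta[-1L], lambda = lambda,
                  iterations = it - 1L)
      class(out) <- "logistic_model"
      return(out)
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xt * w, Xt) + diag(pen, k)
    beta <- beta - solve(H, g)
  }
  stop("logistic fit did not converge in ", max_iter,
       " iterations (possible separation); consider increasing lambda")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model:", length(x$beta), "features; beta0 =",
      signif(x$beta0, 4), "\n")
  invisible(x)
}

#' Predict from a logistic model
#'
#' @param object a `logistic_model`.
#' @param newdata genes x K feature matrix.
#' @param ... unused.
#' @return Predicted probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  plogis(object$beta0 + as.vector(as.matrix(newdata) %*% object$beta))
}

# --- autoencoder ------------------------------------------------------------

act_fun <- function(z, activation) {
  if (activation == "sigmoid") plogis(z) else z
}

ae_unpack <- function(par, d, k) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * k)], d, k); i <- i + d * k
  b1 <- par[i + seq_len(k)]; i <- i + k
  W2 <- matrix(par[i + seq_len(k * d)], k, d); i <- i + k * d
  b2 <- par[i + seq_len(d)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Fit a bottleneck autoencoder to signature profiles
#'
#' Trains a single-hidden-layer autoencoder (334 -> `latent` -> 334 by
#' default; sigmoid hidden units, linear output) that compresses the
#' position-specific signature levels into a small number of coordinates.
#' Optimization is deterministic given the seed (L-BFGS on analytic
#' gradients).
#'
#' @param S genes x positions matrix with values in `[0, 1]`.
#' @param latent bottleneck width (default 2).
#' @param seed integer seed for the weight initialization (mandatory).
#' @param activation hidden activation, `"sigmoid"` (default) or
#'   `"linear"`.
#' @param maxit optimizer iteration cap (default 500).
#' @return An `autoencoder_model`: weights (`W1`, `b1`, `W2`, `b2`),
#'   `activation`, `latent`, `seed`, and `explained_variance`
#'   (1 - SSE / total centred sum of squares).
#' @export
fit_autoencoder <- function(S, latent = 2L, seed,
                            activation = c("sigmoid", "linear"),
                            maxit = 500L) {
  activation <- match.arg(activation)
  S <- as.matrix(S)
  d <- ncol(S); n <- nrow(S); k <- as.integer(latent)
  center <- colMeans(S)
  X <- sweep(S, 2L, center)  # centring markedly improves conditioning
  ss_total <- sum(X^2)
  if (ss_total == 0) stop("constant input: explained variance undefined")
  obj <- function(par) {
    w <- ae_unpack(par, d, k)
    H <- act_fun(sweep(X %*% w$W1, 2L, w$b1, `+`), activation)
    Xhat <- sweep(H %*% w$W2, 2L, w$b2, `+`)
    0.5 * sum((Xhat - X)^2) / n
  }
  grad <- function(par) {
    w <- ae_unpack(par, d, k)
    Z1 <- sweep(X %*% w$W1, 2L, w$b1, `+`)
    H <- act_fun(Z1, activation)
    Xhat <- sweep(H %*% w$W2, 2L, w$b2, `+`)
    R <- (Xhat - X) / n
    dH <- R %*% t(w$W2)
    dZ1 <- if (activation == "sigmoid") dH * H * (1 - H) else dH
    c(as.vector(crossprod(X, dZ1)), colSums(dZ1),
      as.vector(crossprod(H, R)), colSums(R))
  }
  set.seed(seed)
  par0 <- c(rnorm(d * k, sd = 1 / sqrt(d)), numeric(k),
            rnorm(k * d, sd = 1 / sqrt(k)), numeric(d))
  fit <- optim(par0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e2, lmm = 20))
  w <- ae_unpack(fit$par, d, k)
  H <- act_fun(sweep(X %*% w$W1, 2L, w$b1, `+`), activation)
  Xhat <- sweep(H %*% w$W2, 2L, w$b2, `+`)
  out <- c(w, list(center = center, activation = activation, latent = k,
                   seed = seed,
                   explained_variance = 1 - sum((Xhat - X)^2) / ss_total))
  class(out) <- "autoencoder_model"
  out
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat("autoencoder_model:", nrow(x$W1), "->", x$latent, "->", nrow(x$W1),
      "(", x$activation, "); explained variance",
      signif(x$explained_variance, 4), "\n")
  invisible(x)
}

#' Encode signatures into the bottleneck coordinates
#'
#' @param ae an `autoencoder_model`.
#' @param S genes x positions matrix.
#' @return genes x latent matrix of coordinates.
#' @export
encode <- function(ae, S) {
  X <- sweep(as.matrix(S), 2L, ae$center)
  act_fun(sweep(X %*% ae$W1, 2L, ae$b1, `+`), ae$activation)
}

#' Reconstruct signatures from the autoencoder
#'
#' @param ae an `autoencoder_model`.
#' @param S genes x positions matrix.
#' @return genes x positions reconstruction.
#' @export
reconstruct <- function(ae, S) {
  sweep(encode(ae, S) %*% ae$W2, 2L, ae$b2 + ae$center, `+`)
}

# --- expression network -----------------------------------------------------

#' Fit the expression network from sequence signatures
#'
#' A neural network (positions -> latent -> 1, linear output) whose hidden
#' layer is initialized from the autoencoder's encoder; the output layer is
#' initialized by least squares on the encoded training coordinates. Genes
#' are split at random into training and validation sets (default 10,000 /
#' 3,000, scaled proportionally with a warning when fewer genes are
#' supplied) and validation metrics are reported.
#'
#' @param ae an `autoencoder_model` (provides the initial encoder weights).
#' @param S genes x positions signature matrix.
#' @param y log expression levels (`log2(FPKM + 1)`), aligned with `S`.
#' @param split `c(n_train, n_validate)`.
#' @param seed seed controlling the random split.
#' @param detected logical detection flag used for the validation AUC;
#'   defaults to `y > 1` (i.e. FPKM > 1).
#' @param lambda L2 penalty on the weight matrices (biases unpenalized;
#'   default 1e-3) guarding against overfitting the ~2 x positions
#'   encoder parameters on moderate gene counts.
#' @param maxit optimizer iteration cap.
#' @return An `expression_net`: weights, `train_idx`, `val_idx`, and
#'   `metrics` (validation pearson, spearman, auc).
#' @export
fit_expression_net <- function(ae, S, y, split = c(10000L, 3000L), seed,
                               detected = y > 1, lambda = 1e-3,
                               maxit = 500L) {
  S <- as.matrix(S)
  n <- nrow(S); d <- ncol(S); k <- ae$latent
  stopifnot(length(y) == n)
  if (sum(split) > n) {
    frac <- split / sum(split)
    split <- c(max(2L, floor(frac[1L] * n)), 0L)
    split[2L] <- n - split[1L]
    warning("fewer genes than requested split; scaled to ",
            split[1L], " train / ", split[2L], " validate")
  }
  set.seed(seed)
  perm <- sample.int(n)
  train <- perm[seq_len(split[1L])]
  val <- perm[split[1L] + seq_len(split[2L])]
  Xtr <- S[train, , drop = FALSE]
  ytr <- y[train]
  activation <- ae$activation
  obj_grad <- function(par, value) {
    W1 <- matrix(par[seq_len(d * k)], d, k)
    b1 <- par[d * k + seq_len(k)]
    w2 <- par[d * k + k + seq_len(k)]
    b2 <- par[d * k + 2L * k + 1L]
    Z1 <- sweep(Xtr %*% W1, 2L, b1, `+`)
    H <- act_fun(Z1, activation)
    yhat <- as.vector(H %*% w2) + b2
    r <- (yhat - ytr) / length(ytr)
    if (value) {
      return(0.5 * sum(r * (yhat - ytr)) +
               0.5 * lambda * (sum(W1^2) + sum(w2^2)))
    }
    dH <- tcrossprod(r, w2)
    dZ1 <- if (activation == "sigmoid") dH * H * (1 - H) else dH
    c(as.vector(crossprod(Xtr, dZ1)) + lambda * W1, colSums(dZ1),
      as.vector(crossprod(H, r)) + lambda * w2, sum(r))
  }
  Htr <- encode(ae, Xtr)
  ls <- tryCatch(stats::lsfit(Htr, ytr), error = function(e) NULL)
  w2_0 <- if (is.null(ls)) numeric(k) else ls$coefficients[-1L]
  b2_0 <- if (is.null(ls)) mean(ytr) else ls$coefficients[1L]
  # the net takes raw signatures; fold the autoencoder's centring into b1
  b1_0 <- ae$b1 - as.vector(ae$center %*% ae$W1)
  par0 <- c(as.vector(ae$W1), b1_0, w2_0, b2_0)
  fit <- optim(par0, function(p) obj_grad(p, TRUE),
               function(p) obj_grad(p, FALSE),
               method = "L-BFGS-B", control = list(maxit = maxit))
  W1 <- matrix(fit$par[seq_len(d * k)], d, k)
  b1 <- fit$par[d * k + seq_len(k)]
  w2 <- fit$par[d * k + k + seq_len(k)]
  b2 <- fit$par[d * k + 2L * k + 1L]
  net <- structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                        activation = activation, train_idx = train,
                        val_idx = val, seed = seed),
                   class = "expression_net")
  pv <- predict(net, S[val, , drop = FALSE])
  net$metrics <- list(
    pearson = cor(pv, y[val]),
    spearman = cor(pv, y[val], method = "spearman"),
    auc = if (length(unique(detected[val])) == 2L) auc(pv, detected[val])
          else NA_real_
  )
  net
}

#' @export
print.expression_net <- function(x, ...) {
  cat("expression_net:", nrow(x$W1), "->", length(x$w2), "-> 1 (",
      x$activation, "); validation r =", signif(x$metrics$pearson, 3),
      ", rho =", signif(x$metrics$spearman, 3),
      ", AUC =", signif(x$metrics$auc, 3), "\n")
  invisible(x)
}

#' Predict log expression from signatures
#'
#' @param object an `expression_net`.
#' @param newdata genes x positions matrix.
#' @param ... unused.
#' @return Predicted log expression levels.
#' @export
predict.expression_net <- function(object, newdata, ...) {
  H <- act_fun(sweep(as.matrix(newdata) %*% object$W1, 2L, object$b1, `+`),
               object$activation)
  as.vector(H %*% object$w2) + object$b2
}

# --- evaluation statistics --------------------------------------------------

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney form with midrank tie correction:
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of
#' the positive class.
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) truth.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0 || n0 == 0) stop("AUC undefined: truth has a single class")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilcoxon rank-sum test (rank-sum convention)
#'
#' Reports `W` as the sum of the combined-sample ranks of `x` (so for
#' groups {1,2} vs {3,4}, W = 3) with a two-sided normal-approximation
#' p-value including the tie correction.
#'
#' @param x,y numeric samples.
#' @return List with `W`, `p_value`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y)); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - mu) / sqrt(sig2)
  list(W = W, p_value = 2 * pnorm(-abs(z)), n_x = n1, n_y = n2)
}

#' Chi-squared test of a 2x2 contingency table
#'
#' Pearson chi-squared with df = 1 and no continuity correction.
#'
#' @param tab 2x2 count matrix.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_2x2 <- function(tab) {
  ct <- chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Standard evaluation metrics for expression predictions
#'
#' @param pred numeric predictions.
#' @param truth measured values on the same scale.
#' @param detected logical detection flags (for the AUC and the rank-sum
#'   comparison of detected vs not-detected predictions); optional.
#' @param contingency optional 2x2 table for the chi-squared test.
#' @return List with pearson, spearman, and (when computable) auc,
#'   wilcoxon, chisq components.
#' @export
metrics <- function(pred, truth, detected = NULL, contingency = NULL) {
  stopifnot(length(pred) == length(truth))
  out <- list(pearson = cor(pred, truth),
              spearman = cor(pred, truth, method = "spearman"))
  if (!is.null(detected)) {
    out$auc <- auc(pred, detected)
    out$wilcoxon <- rank_sum_test(pred[detected], pred[!detected])
  }
  if (!is.null(contingency)) out$chisq <- chisq_2x2(contingency)
  out
}
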