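# Two-state HMM over 6-bp segments: peak (M) and dip (d) states, 6-mer
# emission spectra, cooperative transitions, forward-backward posteriors.
#
# All recursions use per-step scaling so that T = 334 windows (and far
# longer sequences) never underflow. State order is M = 1, d = 2.

#' HMM model constructor
#'
#' @param pi initial distribution over (M, d).
#' @param A 2x2 transition matrix, rows (from) x columns (to), rows sum 1.
#' @param spectrum a `kmer_spectrum` providing the emission distributions
#'   (`p_peak` for state M, `p_dip` for state d), all entries > 0.
#' @return An `hmm_model` object.
#' @export
hmm_model <- function(pi, A, spectrum) {
  pi <- as.numeric(pi)
  A <- matrix(as.numeric(A), 2L, 2L, dimnames = list(c("M", "d"), c("M", "d")))
  stopifnot(length(pi) == 2L, abs(sum(pi) - 1) < 1e-9,
            all(abs(rowSums(A) - 1) < 1e-12), all(A >= 0), all(pi >= 0))
  if (any(spectrum$p_peak <= 0) || any(spectrum$p_dip <= 0)) {
    stop("emission probabilities must be strictly positive")
  }
  structure(list(pi = setNames(pi, c("M", "d")), A = A, spectrum = spectrum),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("hmm_model: pi(M) =", signif(x$pi[1], 4),
      "; A[M->M] =", signif(x$A[1, 1], 4),
      "; A[d->d] =", signif(x$A[2, 2], 4), "\n")
  invisible(x)
}

#' Estimate transitions and initial distribution from peak labels
#'
#' The cooperative persistence of H3K27ac peaks is estimated from ChIP-based
#' per-segment peak labels: `A[M->M]` is the fraction of peak segments whose
#' next segment (within the same window) is also a peak, `A[d->d]`
#' analogously, and the initial distribution is the empirical marginal state
#' frequency (or the stationary distribution of `A`).
#'
#' @param state_calls logical matrix (windows x segments), TRUE = peak. When
#'   starting from heights, threshold first (e.g. `heights > 0.5`).
#' @param pi_method `"empirical"` marginal (default) or `"stationary"`.
#' @return List with `A` (2x2) and `pi` (length 2), state order (M, d).
#' @export
estimate_transitions <- function(state_calls,
                                 pi_method = c("empirical", "stationary")) {
  pi_method <- match.arg(pi_method)
  s <- as.matrix(state_calls)
  if (!any(s)) {
    stop("no peak segments in state_calls; lower the peak-label threshold")
  }
  if (!any(!s)) stop("no dip segments in state_calls")
  cur <- s[, -ncol(s), drop = FALSE]
  nxt <- s[, -1L, drop = FALSE]
  a_mm <- sum(cur & nxt) / sum(cur)
  a_dd <- sum(!cur & !nxt) / sum(!cur)
  A <- matrix(c(a_mm, 1 - a_mm, 1 - a_dd, a_dd), 2L, 2L, byrow = TRUE,
              dimnames = list(c("M", "d"), c("M", "d")))
  pi <- if (pi_method == "empirical") {
    c(M = mean(s), d = 1 - mean(s))
  } else {
    stationary_distribution(A)
  }
  list(A = A, pi = pi)
}

stationary_distribution <- function(A) {
  # left eigenvector for a 2-state chain in closed form
  p <- A[2, 1] / (A[1, 2] + A[2, 1])
  c(M = p, d = 1 - p)
}

# Emission probabilities for a vector of segments: T x 2 matrix.
# N-containing segments emit uniformly (1/4096) from both states, so they
# carry transition information only.
emission_probs <- function(model, segments) {
  idx <- kmer_index(segments)
  e <- cbind(M = unname(model$spectrum$p_peak)[idx],
             d = unname(model$spectrum$p_dip)[idx])
  e[is.na(idx), ] <- 1 / N_KMERS
  e
}

#' Scaled forward recursion
#'
#' @param model an [hmm_model()].
#' @param segments character vector of 6-mers (one window, any T >= 1).
#' @return List with `alpha` (T x 2 matrix, each row scaled to sum 1),
#'   `scale` (the per-step normalizers), and `loglik` (= sum(log(scale))).
#' @export
forward <- function(model, segments) {
  e <- emission_probs(model, segments)
  T_ <- nrow(e)
  alpha <- matrix(0, T_, 2L, dimnames = list(NULL, c("M", "d")))
  scale <- numeric(T_)
  a <- model$pi * e[1L, ]
  scale[1L] <- sum(a)
  stopifnot(scale[1L] > 0)
  alpha[1L, ] <- a / scale[1L]
  if (T_ > 1L) {
    for (t in 2:T_) {
      a <- as.vector(alpha[t - 1L, ] %*% model$A) * e[t, ]
      scale[t] <- sum(a)
      stopifnot(scale[t] > 0)
      alpha[t, ] <- a / scale[t]
    }
  }
  list(alpha = alpha, scale = scale, loglik = sum(log(scale)))
}

#' Scaled backward recursion
#'
#' Uses the forward pass's scale factors so that
#' `rowSums(alpha * beta) == 1` at every step.
#'
#' @param model an [hmm_model()].
#' @param segments character vector of 6-mers.
#' @param scale optional per-step normalizers from [forward()]; computed
#'   internally when missing.
#' @return T x 2 matrix `beta` (scaled; last row is 1, 1).
#' @export
backward <- function(model, segments, scale = NULL) {
  e <- emission_probs(model, segments)
  T_ <- nrow(e)
  if (is.null(scale)) scale <- forward(model, segments)$scale
  beta <- matrix(0, T_, 2L, dimnames = list(NULL, c("M", "d")))
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      beta[t, ] <- as.vector(model$A %*% (e[t + 1L, ] * beta[t + 1L, ])) /
        scale[t + 1L]
    }
  }
  beta
}

#' Posterior state probabilities (the sequence signature)
#'
#' Combines the forward and backward passes into the per-segment posterior
#' probability that the segment lies in an H3K27ac peak, normalized over
#' both state configurations:
#' `gamma_i(M) = alpha_i(M) beta_i(M) / sum_s alpha_i(s) beta_i(s)`.
#'
#' @param model an [hmm_model()].
#' @param segments character vector of 6-mers.
#' @param gene_id optional identifier stored on the result.
#' @return A `signature_profile`: list with `gene_id`, `gamma` (posterior
#'   P(M) per segment), `band` (see [band()]), and `loglik`.
#' @export
posterior <- function(model, segments, gene_id = NA_character_) {
  fw <- forward(model, segments)
  beta <- backward(model, segments, scale = fw$scale)
  ab <- fw$alpha * beta
  denom <- rowSums(ab)
  # with consistent scaling the denominator is invariant across positions
  stopifnot(all(abs(denom - denom[1L]) < 1e-9))
  gamma <- unname(ab[, 1L] / denom)
  structure(list(gene_id = gene_id, gamma = gamma, band = band(gamma),
                 loglik = fw$loglik),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("signature_profile:", x$gene_id, "T =", length(x$gamma),
      "; mean gamma(M) =", signif(mean(x$gamma), 4), "\n")
  invisible(x)
}

#' Posterior signatures for all windows (batch forward-backward)
#'
#' Vectorized across windows: equivalent to calling [posterior()] on each
#' row of `windows$segments` but orders of magnitude faster.
#'
#' @param model an [hmm_model()].
#' @param windows a `tss_windows` object.
#' @return Numeric matrix (genes x segments) of posterior peak
#'   probabilities, rownames = gene ids.
#' @export
signature_profiles <- function(model, windows) {
  segs <- windows$segments
  n <- nrow(segs)
  T_ <- ncol(segs)
  idx <- matrix(kmer_index(as.vector(segs)), n, T_)
  pm <- unname(model$spectrum$p_peak)
  pd <- unname(model$spectrum$p_dip)
  EM <- matrix(pm[idx], n, T_)
  ED <- matrix(pd[idx], n, T_)
  EM[is.na(idx)] <- 1 / N_KMERS
  ED[is.na(idx)] <- 1 / N_KMERS
  A <- model$A
  AM <- matrix(0, n, T_)  # scaled alpha, state M
  AD <- matrix(0, n, T_)
  SC <- matrix(0, n, T_)
  am <- model$pi[1L] * EM[, 1L]
  ad <- model$pi[2L] * ED[, 1L]
  s <- am + ad
  AM[, 1L] <- am / s; AD[, 1L] <- ad / s; SC[, 1L] <- s
  for (t in 2:T_) {
    am <- (AM[, t - 1L] * A[1L, 1L] + AD[, t - 1L] * A[2L, 1L]) * EM[, t]
    ad <- (AM[, t - 1L] * A[1L, 2L] + AD[, t - 1L] * A[2L, 2L]) * ED[, t]
    s <- am + ad
    AM[, t] <- am / s; AD[, t] <- ad / s; SC[, t] <- s
  }
  BM <- matrix(0, n, T_)
  BD <- matrix(0, n, T_)
  BM[, T_] <- 1; BD[, T_] <- 1
  for (t in (T_ - 1L):1L) {
    um <- EM[, t + 1L] * BM[, t + 1L]
    ud <- ED[, t + 1L] * BD[, t + 1L]
    BM[, t] <- (A[1L, 1L] * um + A[1L, 2L] * ud) / SC[, t + 1L]
    BD[, t] <- (A[2L, 1L] * um + A[2L, 2L] * ud) / SC[, t + 1L]
  }
  num <- AM * BM
  gamma <- num / (num + AD * BD)
  rownames(gamma) <- rownames(segs)
  gamma
}

#' Band a posterior probability
#'
#' Signature bands follow the reported thresholds: very high (> 0.9), high
#' (0.5, 0.9], medium (0.1, 0.5], low (<= 0.1).
#'
#' @param gamma_value numeric vector of posteriors in `[0, 1]`.
#' @return Character vector in
#'   `{"very_high", "high", "medium", "low"}`.
#' @export
band <- function(gamma_value) {
  if (any(gamma_value < 0 | gamma_value > 1)) {
    stop("posterior values must lie in [0, 1]")
  }
  as.character(cut(gamma_value, breaks = c(-Inf, 0.1, 0.5, 0.9, Inf),
                   labels = c("low", "medium", "high", "very_high")))
}
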