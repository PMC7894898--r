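# Independent dense-algebra oracles for the score-test machinery, a
# brute-force TMM reference, and small simulation utilities. These are
# deliberately naive implementations (explicit n x n matrices, generic
# solve()) used only to cross-check the O(n p) production code paths.

dense_sigma <- function(v_diag, sigma_b2, batch) {
  B <- stats::model.matrix(~ 0 + factor(batch))
  diag(v_diag) + sigma_b2 * tcrossprod(B)
}

dense_sigma_inv <- function(v_diag, sigma_b2, batch) {
  solve(dense_sigma(v_diag, sigma_b2, batch))
}

dense_P <- function(v_diag, sigma_b2, batch) {
  Si <- dense_sigma_inv(v_diag, sigma_b2, batch)
  one <- rep(1, length(v_diag))
  Si - Si %*% one %*% t(one) %*% Si / as.numeric(t(one) %*% Si %*% one)
}

dense_gb <- function(group_indicator, batch) {
  stats::model.matrix(~ 0 + factor(batch)) * as.numeric(group_indicator)
}

dense_E <- function(v_diag, sigma_b2, batch, group_indicator, weights = NULL) {
  G <- dense_gb(group_indicator, batch)
  if (!is.null(weights)) G <- G * weights
  P <- dense_P(v_diag, sigma_b2, batch)
  t(G) %*% P %*% G
}

dense_T <- function(y, mu0, phi_diag, batch, group_indicator, tau = 1,
                    weights = NULL) {
  G <- dense_gb(group_indicator, batch)
  Phi <- diag(phi_diag)
  W <- if (is.null(weights)) diag(length(y)) else diag(weights)
  r <- y - mu0
  as.numeric(t(r) %*% Phi %*% W %*% G %*% t(G) %*% W %*% Phi %*% r) / tau
}

# random small test instance for the linear-algebra oracles
random_instance <- function(n, p, seed) {
  set.seed(seed)
  batch <- sample(rep(seq_len(p), length.out = n))
  list(
    batch = batch,
    v_diag = runif(n, 0.2, 3),
    sigma_b2 = runif(1, 0, 1),
    g = rbinom(n, 1, 0.5),
    w = ifelse(rbinom(n, 1, 0.3) == 1, runif(n, 0.05, 0.9), 1)
  )
}

# Monte Carlo tail of sum xi_i chisq_1 and its binomial standard error
mc_mixchisq_tail <- function(xi, t, n_draws, seed) {
  set.seed(seed)
  q <- colSums(matrix(stats::rchisq(length(xi) * n_draws, df = 1) * xi,
                      nrow = length(xi)))
  p <- mean(q >= t)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Brute-force TMM normalization factors (trimmed mean of M-values against
# the cell whose upper quartile is closest to the mean upper quartile),
# independent of the production implementation.
brute_tmm <- function(cm, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(cm)
  uq <- apply(cm, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(cm)), function(j) {
    if (j == ref) return(1)
    no <- cm[, j] / lib[j]
    nr <- cm[, ref] / lib[ref]
    keep <- no > 0 & nr > 0
    if (!any(keep)) return(1)
    M <- log2(no[keep] / nr[keep])
    A <- 0.5 * log2(no[keep] * nr[keep])
    # asymptotic (delta-method) variance of M
    v <- (lib[j] - cm[keep, j]) / (lib[j] * cm[keep, j]) +
         (lib[ref] - cm[keep, ref]) / (lib[ref] * cm[keep, ref])
    if (max(abs(M)) < 1e-6) return(1)
    # rank-based double trimming as in the published algorithm
    nk <- length(M)
    loM <- floor(nk * logratio_trim) + 1; hiM <- nk + 1 - loM
    loA <- floor(nk * abs_trim) + 1;      hiA <- nk + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
             rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# O(n^2) pairwise-concordance AUC oracle with half credit for ties
pairwise_auc <- function(padj, truth) {
  score <- -padj
  pos <- score[as.logical(truth)]
  neg <- score[!as.logical(truth)]
  tot <- 0
  for (sp in pos) tot <- tot + sum(sp > neg) + 0.5 * sum(sp == neg)
  tot / (length(pos) * length(neg))
}

# textbook BH step-up, computed independently of stats::p.adjust
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
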