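#' Zero-truncated Poisson rate estimate
#'
#' Solves the defining equation of the truncated-Poisson mean,
#' \eqn{\hat\lambda / (1 - e^{-\hat\lambda}) = \bar y}, where `ybar_nonzero`
#' is the sample mean of the nonzero counts. The method-of-moments and
#' maximum-likelihood estimates coincide and are obtained by bracketed
#' root-finding polished with Newton steps to residual below 1e-10.
#'
#' @param ybar_nonzero Mean of the nonzero counts; must be >= 1.
#' @return The rate estimate `lambda_hat` (1e-10 in the boundary case
#'   `ybar_nonzero = 1`).
#' @export
#' @examples
#' trpois_lambda(2 / (1 - exp(-2)))  # recovers lambda = 2
trpois_lambda <- function(ybar_nonzero) {
  if (!is.finite(ybar_nonzero) || ybar_nonzero < 1)
    stop("a zero-truncated Poisson mean cannot be below 1")
  if (ybar_nonzero == 1) return(1e-10)
  f <- function(l) l / (1 - exp(-l)) - ybar_nonzero
  lam <- stats::uniroot(f, c(1e-12, ybar_nonzero + 1),
                        tol = .Machine$double.eps^0.75)$root
  for (i in 1:5) {
    e <- exp(-lam)
    res <- lam / (1 - e) - ybar_nonzero
    if (abs(res) < 1e-12) break
    grad <- (1 - e - lam * e) / (1 - e)^2
    lam <- lam - res / grad
  }
  lam
}

#' Truncated-Poisson observational weights for one batch
#'
#' Nonzero counts get weight 1; zero counts get
#' \eqn{w = n_1 e^{-\hat\lambda} / (n_0 (1 - e^{-\hat\lambda}))}, where
#' `n_1`/`n_0` count the nonzero/zero observations in the batch and
#' \eqn{\hat\lambda} solves the truncated-mean equation. The value is
#' clipped into (0, 1]; the unclipped value satisfies
#' \eqn{w n_0 / (w n_0 + n_1) = e^{-\hat\lambda}}.
#'
#' @param y_batch Counts for one gene restricted to one batch.
#' @return Weight vector aligned with `y_batch`.
#' @export
trpois_weights <- function(y_batch) {
  w <- rep(1, length(y_batch))
  zero <- y_batch == 0
  n0 <- sum(zero); n1 <- length(y_batch) - n0
  if (n1 == 0L) {
    warning("all counts zero in batch; weights left at 1")
    return(w)
  }
  if (n0 == 0L) return(w)
  lam <- trpois_lambda(mean(y_batch[zero == FALSE]))
  e <- exp(-lam)
  w0 <- n1 * e / (n0 * (1 - e))
  w[zero] <- min(max(w0, 1e-300), 1)
  w
}

#' EM fit of the zero-inflated Poisson
#'
#' Standard EM for the two-component mixture of a point mass at zero
#' (probability `pi`) and a Poisson(`lambda`): the E-step assigns each zero
#' count its posterior probability of belonging to the point mass; the
#' M-step updates `pi` as the mean responsibility and `lambda` as the
#' responsibility-weighted Poisson mean. The ZIP log-likelihood is monotone
#' non-decreasing across iterations. Only the zero count, nonzero count and
#' nonzero sum enter the updates, so the iteration cost is O(1) per step.
#'
#' @param y_batch Counts (at least one nonzero).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @return A list of class `"scmmst_zifit"`: `pi_hat`, `lambda_hat`, `n0`,
#'   `n1`, `loglik` (trace), `converged`.
#' @export
zipois_fit <- function(y_batch, max_iter = 200L, tol = 1e-8) {
  n <- length(y_batch)
  zero <- y_batch == 0
  n0 <- sum(zero); n1 <- n - n0
  if (n1 == 0L) stop("all counts zero: zero-inflated Poisson is not identifiable")
  S <- sum(y_batch)
  if (n0 == 0L) {
    return(structure(list(pi_hat = 0, lambda_hat = S / n, n0 = n0, n1 = n1,
                          loglik = numeric(0), converged = TRUE),
                     class = "scmmst_zifit"))
  }
  lam <- S / n1                       # truncated-sample mean as start
  pi0 <- 0.5 * n0 / n
  # ZIP log-likelihood, the sum(log y!) constant dropped
  ll <- function(pi0, lam)
    n0 * log(pi0 + (1 - pi0) * exp(-lam)) +
      n1 * (log(1 - pi0) - lam) + S * log(lam)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: responsibility of a zero count for the point mass
    z <- pi0 / (pi0 + (1 - pi0) * exp(-lam))
    # M-step
    pi_new <- n0 * z / n
    lam_new <- S / (n - n0 * z)
    loglik <- c(loglik, ll(pi_new, lam_new))
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) {
      pi0 <- pi_new; lam <- lam_new
      converged <- TRUE
      break
    }
    pi0 <- pi_new; lam <- lam_new
  }
  structure(list(pi_hat = pi0, lambda_hat = lam, n0 = n0, n1 = n1,
                 loglik = loglik, converged = converged),
            class = "scmmst_zifit")
}

#' Observational weight under a zero-inflated model
#'
#' The weight is the conditional probability that a count belongs to the
#' conventional (non-point-mass) component:
#' \eqn{w = (1-\hat\pi) f(y;\hat\theta) / f_{ZI}(y;\hat\theta,\hat\pi)},
#' which is 1 for every nonzero count and
#' \eqn{(1-\hat\pi) f(0) / (\hat\pi + (1-\hat\pi) f(0))} at zero.
#'
#' @param y Count (scalar or vector).
#' @param fit A fit with elements `pi_hat` and either `lambda_hat`
#'   (Poisson) or `mu_hat`/`theta_hat` (negative binomial).
#' @param family `"poisson"` or `"nb"`.
#' @return Weights in (0, 1].
#' @export
zero_inflated_weight <- function(y, fit, family = c("poisson", "nb")) {
  family <- match.arg(family)
  f0 <- if (family == "poisson") exp(-fit$lambda_hat)
        else (fit$theta_hat / (fit$theta_hat + fit$mu_hat))^fit$theta_hat
  w0 <- (1 - fit$pi_hat) * f0 / (fit$pi_hat + (1 - fit$pi_hat) * f0)
  ifelse(y > 0, 1, pmin(pmax(w0, 1e-300), 1))
}

#' Moment estimation of the zero-truncated negative binomial
#'
#' Solves the first two moment equations of the zero-truncated NB for the
#' mean `mu` and dispersion `theta`: writing `p0 = (theta/(theta+mu))^theta`
#' for the natural zero probability, the truncated moments satisfy
#' `m1 = mu/(1-p0)` and `m2/m1 = 1 + mu (theta+1)/theta`. The second
#' equation gives `mu` as a function of `theta`, reducing the system to a
#' bracketed one-dimensional root search in `log(theta)`. When the moment
#' system has no admissible root, truncated-NB maximum likelihood
#' (Nelder-Mead on `(log mu, log theta)`) is used as fallback. `theta_hat`
#' is clamped to \[0.01, 1e4\] and a low-confidence flag is set when
#' `theta_hat < 2` (the moment estimator is known to be unstable there) or
#' when a clamp is hit.
#'
#' @param y_batch Counts with at least two distinct nonzero values.
#' @return List with `mu_hat`, `theta_hat`, `low_confidence`, `method`
#'   (`"moments"` or `"ml"`).
#' @export
trnb_fit <- function(y_batch) {
  yz <- y_batch[y_batch > 0]
  if (length(unique(yz)) < 2L)
    stop("degenerate sample: need at least two distinct nonzero values")
  m1 <- mean(yz); m2 <- mean(yz^2)
  ratio <- m2 / m1 - 1
  mu_of <- function(th) th * ratio / (th + 1)
  g <- function(lth) {
    th <- exp(lth)
    mu <- mu_of(th)
    p0 <- (th / (th + mu))^th
    mu / (1 - p0) - m1
  }
  lo <- log(0.01); hi <- log(1e4)
  sol <- NULL
  glo <- tryCatch(g(lo), error = function(e) NA)
  ghi <- tryCatch(g(hi), error = function(e) NA)
  if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0) {
    lth <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    sol <- list(mu_hat = mu_of(exp(lth)), theta_hat = exp(lth),
                method = "moments")
  }
  if (is.null(sol)) {
    nll <- function(par) {
      mu <- exp(par[1]); th <- exp(par[2])
      p0 <- (th / (th + mu))^th
      -sum(stats::dnbinom(yz, mu = mu, size = th, log = TRUE)) +
        length(yz) * log1p(-p0)
    }
    opt <- stats::optim(c(log(m1), log(2)), nll, method = "Nelder-Mead",
                        control = list(maxit = 500))
    sol <- list(mu_hat = exp(opt$par[1]), theta_hat = exp(opt$par[2]),
                method = "ml")
  }
  clamped <- sol$theta_hat < 0.01 || sol$theta_hat > 1e4
  sol$theta_hat <- min(max(sol$theta_hat, 0.01), 1e4)
  sol$low_confidence <- clamped || sol$theta_hat < 2
  sol
}

#' Truncated-NB observational weights for one gene
#'
#' Fits the zero-truncated NB per batch, pools the dispersion as the
#' harmonic mean of the per-batch `theta_hat` (batches whose fit fails are
#' excluded from the pooling), re-solves each batch mean from its truncated
#' first-moment equation at the common dispersion, and assigns zero counts
#' the weight \eqn{w = n_1 p_0 / (n_0 (1 - p_0))} with
#' \eqn{p_0 = (\hat\theta/(\hat\theta+\hat\mu))^{\hat\theta}}, clipped into
#' (0, 1]. Nonzero counts get 1; batches whose fit fails keep weight 1 with
#' a warning.
#'
#' @param cm_gene Counts for one gene across all cells.
#' @param design Cell design (batch labels).
#' @return Weight vector aligned with `cm_gene`.
#' @export
trnb_weights <- function(cm_gene, design) {
  batch <- .batch_factor(design)
  w <- rep(1, length(cm_gene))
  fits <- lapply(levels(batch), function(lv) {
    yb <- cm_gene[batch == lv]
    tryCatch(trnb_fit(yb), error = function(e) NULL)
  })
  thetas <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$theta_hat,
                   numeric(1))
  ok <- is.finite(thetas)
  if (!any(ok)) {
    warning("truncated-NB fit failed in every batch; weights left at 1")
    return(w)
  }
  theta_common <- length(thetas[ok]) / sum(1 / thetas[ok])
  for (j in seq_along(levels(batch))) {
    sel <- batch == levels(batch)[j]
    yb <- cm_gene[sel]
    n0 <- sum(yb == 0); n1 <- sum(yb > 0)
    if (n0 == 0L) next
    if (is.null(fits[[j]])) {
      warning("truncated-NB fit failed in batch ", levels(batch)[j],
              "; weights left at 1")
      next
    }
    m1 <- mean(yb[yb > 0])
    mu <- .trnb_mu_at_theta(m1, theta_common)
    p0 <- (theta_common / (theta_common + mu))^theta_common
    w0 <- n1 * p0 / (n0 * (1 - p0))
    w[sel & cm_gene == 0] <- min(max(w0, 1e-300), 1)
  }
  w
}

# solve m1 = mu / (1 - p0(mu, theta)) for mu at fixed theta; the right side
# is increasing in mu with limit value m1 at mu -> 0+ ... use bracketing on
# log mu (truncated mean > mu, so the root lies below m1)
.trnb_mu_at_theta <- function(m1, theta) {
  f <- function(lmu) {
    mu <- exp(lmu)
    p0 <- (theta / (theta + mu))^theta
    mu / (1 - p0) - m1
  }
  hi <- log(m1)
  lo <- log(m1) - 30
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || flo > 0) return(m1 * 1e-8)
  if (fhi < 0) return(m1)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Zero-inflated NB regression weights for one gene
#'
#' Gene-wise ZiNB regression fitted by EM across all cells: the NB mean
#' follows `log mu = intercept + batch (+ offset)`, the zero-inflation
#' probability follows `logit pi = intercept + batch` (batch as fixed
#' effects, no group effects), and the dispersion `theta` is gene-level.
#' The E-step assigns each zero count its posterior probability of arising
#' from the point mass; M-steps are a weighted NB GLM, a profile update of
#' `theta`, and a fractional-response logistic regression. Weights are the
#' posterior probabilities of the NB component: 1 at nonzero counts by
#' construction.
#'
#' @param y_gene Counts for one gene across all cells.
#' @param design Cell design with >= 2 batches.
#' @param offset Optional per-cell offset for the NB mean model.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return Weight vector with attributes `converged`, `theta_hat`,
#'   `loglik` (trace).
#' @export
zinb_regression_weights <- function(y_gene, design, offset = NULL,
                                    max_iter = 100L, tol = 1e-8) {
  batch <- .batch_factor(design)
  n <- length(y_gene)
  if (all(y_gene == 0)) stop("all-zero gene: ZiNB regression is not estimable")
  zero <- y_gene == 0
  if (!any(zero)) {
    w <- rep(1, n)
    attr(w, "converged") <- TRUE
    return(w)
  }
  X <- stats::model.matrix(~ batch)
  o <- if (is.null(offset)) numeric(n) else offset
  z <- ifelse(zero, 0.5, 0)          # responsibility for the point mass
  theta <- 1
  pi_i <- rep(mean(zero) / 2, n)
  loglik <- numeric(0)
  converged <- FALSE
  mu <- pmax(y_gene, 0.5)            # placeholder before first M-step
  for (it in seq_len(max_iter)) {
    # M-step, NB mean model weighted by the NB-component responsibilities
    fit_mu <- suppressWarnings(stats::glm.fit(
      X, y_gene, weights = 1 - z, offset = o,
      family = MASS::negative.binomial(theta = theta),
      mustart = mu))
    mu <- pmax(fit_mu$fitted.values, 1e-8)
    # M-step, profile dispersion with the same case weights
    opt <- stats::optimize(.nb_profile_loglik, c(log(1e-3), log(1e5)),
                           y = y_gene, mu = mu, w = 1 - z,
                           maximum = TRUE, tol = 1e-6)
    theta <- exp(opt$maximum)
    # M-step, zero model on the fractional responsibilities
    fit_pi <- suppressWarnings(stats::glm.fit(
      X, z, family = stats::quasibinomial()))
    pi_i <- pmin(pmax(fit_pi$fitted.values, 1e-10), 1 - 1e-10)
    # E-step
    f0 <- stats::dnbinom(0, mu = mu, size = theta)
    z_new <- ifelse(zero, pi_i / (pi_i + (1 - pi_i) * f0), 0)
    ll <- sum(log(pi_i[zero] + (1 - pi_i[zero]) * f0[zero])) +
      sum(log1p(-pi_i[!zero])) +
      sum(stats::dnbinom(y_gene[!zero], mu = mu[!zero], size = theta,
                         log = TRUE))
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) < tol * (1 + abs(ll))) {
      z <- z_new
      converged <- TRUE
      break
    }
    z <- z_new
  }
  w <- ifelse(zero, pmin(pmax(1 - z, 1e-300), 1), 1)
  attr(w, "converged") <- converged
  attr(w, "theta_hat") <- theta
  attr(w, "loglik") <- loglik
  w
}

#' Observational weight matrix for a count matrix
#'
#' Dispatches one of the weighting schemes over all genes. The scalar
#' schemes (`trpois`, `zipois`, `trnb`) estimate their parameters within
#' each batch separately, under the null of no group effects (group labels
#' are never consulted); `zinb` fits the gene-wise ZiNB regression with
#' batch fixed effects on all cells. Per-gene failures never abort the run:
#' the affected gene keeps weight 1 everywhere and a warning is collected.
#'
#' @param cm Count matrix (genes x cells).
#' @param design Cell design.
#' @param method One of `"none"`, `"trpois"`, `"zipois"`, `"trnb"`,
#'   `"zinb"`.
#' @param offset Optional per-cell offset (used by `zinb` only).
#' @return An object of class `"scmmst_weights"`: list with the weight
#'   matrix `w` (entries in (0, 1], exactly 1 at nonzero counts), `method`,
#'   and `failures` (character vector of gene ids that fell back to 1).
#' @export
compute_weights <- function(cm, design,
                            method = c("none", "trpois", "zipois", "trnb",
                                       "zinb"),
                            offset = NULL) {
  method <- match.arg(method)
  cm <- validate_counts(cm)
  batch <- .batch_factor(design)
  if (ncol(cm) != length(batch))
    stop("design does not match the number of cells")
  w <- matrix(1, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  failures <- character(0)
  if (method != "none") {
    bsplit <- split(seq_len(ncol(cm)), batch)
    for (gi in seq_len(nrow(cm))) {
      y <- cm[gi, ]
      if (!any(y == 0)) next
      row_w <- tryCatch({
        switch(method,
          trpois = .per_batch_weights(y, bsplit, trpois_weights),
          zipois = .per_batch_weights(y, bsplit, function(yb) {
            fit <- zipois_fit(yb)
            zero_inflated_weight(yb, fit, "poisson")
          }),
          trnb = trnb_weights(y, design),
          zinb = as.vector(zinb_regression_weights(y, design, offset = offset))
        )
      }, error = function(e) NULL)
      if (is.null(row_w)) {
        failures <- c(failures, rownames(cm)[gi])
      } else {
        w[gi, ] <- row_w
      }
    }
    if (length(failures))
      warning(length(failures), " gene(s) fell back to weight 1: ",
              paste(utils::head(failures, 5), collapse = ", "),
              if (length(failures) > 5) ", ..." else "")
  }
  structure(list(w = w, method = method, failures = failures),
            class = "scmmst_weights")
}

.per_batch_weights <- function(y, bsplit, fun) {
  w <- rep(1, length(y))
  for (idx in bsplit) {
    yb <- y[idx]
    if (!any(yb == 0)) next
    w[idx] <- withCallingHandlers(
      tryCatch(fun(yb), error = function(e) rep(1, length(yb))),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  w
}

#' @export
print.scmmst_weights <- function(x, ...) {
  cat("Observational weights (", x$method, "): ", nrow(x$w), " genes x ",
      ncol(x$w), " cells\n", sep = "")
  zw <- x$w[x$w < 1]
  if (length(zw))
    cat("  downweighted entries:", length(zw),
        " mean:", format(mean(zw), digits = 4), "\n")
  if (length(x$failures))
    cat("  genes fallen back to weight 1:", length(x$failures), "\n")
  invisible(x)
}

#' Write a weight matrix to TSV
#'
#' @param wm A `"scmmst_weights"` object (or bare matrix).
#' @param path Output file.
#' @export
write_weights <- function(wm, path) {
  w <- if (inherits(wm, "scmmst_weights")) wm$w else wm
  df <- data.frame(gene_id = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
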