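#' Fit the reduced null GLMM with a batch random intercept
#'
#' Fits, for a single gene, the null model
#' \deqn{g(\mu_{0i}) = \alpha + B_i b (+ o_i), \qquad b \sim N(0, \sigma_b^2 I_p),}
#' where `B` is the batch dummy matrix and `o` an optional per-cell offset,
#' by penalized quasi-likelihood: iteratively reweighted working responses
#' combined with a one-dimensional REML profile over \eqn{\sigma_b^2},
#' exploiting the single-grouping-factor structure for closed-form
#' per-batch solves. Observational weights, when supplied, multiply the
#' IRLS working weights (weighted GLMM). For the negative binomial family
#' with unknown `theta`, the PQL fit is alternated with profile maximum
#' likelihood for `theta` given the fitted means (weighted likelihood, with
#' the observational weights as case weights).
#'
#' @param y Non-negative response vector (counts for the log-link families).
#' @param design A cell design: data frame with a `batch` column (factor or
#'   coercible; at least 2 levels), as returned by [cell_design()].
#' @param family Family string or [family_spec()] object.
#' @param weights Optional observational weights in (0, 1]; values below
#'   1e-8 are floored at 1e-8 to keep the IRLS systems well-posed.
#' @param offset Optional per-cell offset on the link scale.
#' @param fix_sigma_b2 Optional fixed value for the batch variance
#'   component; when given, the REML profile step is skipped.
#' @param control List of control values: `tol` (relative-change
#'   convergence tolerance, default 1e-6), `maxit` (outer iterations,
#'   default 100), `theta_alternations` (default 10).
#' @return An object of class `"scmmst_null"` with components `alpha_hat`,
#'   `b_hat` (per-batch BLUPs), `sigma_b2_hat`, `mu0_hat`, `eta`,
#'   `theta_hat` (NB only), `tau_hat`, `v_diag`, `phi_diag`, `converged`,
#'   `n_iter`, plus the inputs needed by downstream methods. Non-convergence
#'   is reported through `converged = FALSE`, not as an error.
#' @export
#' @examples
#' sim <- simulate_null_dataset(n_genes = 1, n_cells = 200, family = "poisson",
#'                              mu_pi = 20, seed = 1)
#' fit <- fit_null_glmm(sim$counts[1, ], sim$design, "poisson")
#' coef(fit)
fit_null_glmm <- function(y, design, family, weights = NULL, offset = NULL,
                          fix_sigma_b2 = NULL, control = list()) {
  ctrl <- utils::modifyList(
    list(tol = 1e-6, maxit = 100L, theta_alternations = 10L), control)
  fam <- family_spec(family)
  batch <- .batch_factor(design)
  n <- length(y)
  if (nlevels(batch) < 2L)
    stop("the null GLMM requires at least 2 batch levels")
  if (length(batch) != n)
    stop("length of 'y' does not match the design")
  if (any(!is.finite(y)) || any(y < 0))
    stop("'y' must be finite and non-negative")
  if (fam$link == "log" && all(y == 0))
    stop("all-zero response: null model is not estimable")
  if (!is.null(weights)) {
    if (length(weights) != n || any(!is.finite(weights)) ||
        any(weights <= 0) || any(weights > 1))
      stop("'weights' must lie in (0, 1]")
    weights <- pmax(weights, 1e-8)
    # relative precisions: a uniform weight vector must reproduce the
    # unweighted fit exactly
    weights <- weights / max(weights)
  }
  if (!is.null(offset) && length(offset) != n)
    stop("'offset' must match the length of 'y'")

  if (fam$family == "nb" && is.null(fam$theta)) {
    fit <- .fit_null_nb_profile(y, batch, fam, weights, offset,
                                fix_sigma_b2, ctrl)
  } else {
    theta <- fam$theta
    fit <- .pql_fit(y, batch, fam, theta, weights, offset, fix_sigma_b2, ctrl)
    fit$theta_hat <- theta
  }

  vd <- variance_diag(fit$mu0_hat, fam, theta = fit$theta_hat)
  fit$v_diag <- vd$v_diag
  fit$phi_diag <- vd$phi_diag
  fit$family <- fam
  fit$weights <- weights
  fit$offset <- offset
  fit$batch <- batch
  fit$y <- y
  fit$tau_hat <- if (fam$quasi) estimate_quasi_dispersion(fit, y, fam) else 1
  class(fit) <- "scmmst_null"
  fit
}

.batch_factor <- function(design) {
  if (is.data.frame(design)) {
    if (is.null(design$batch)) stop("design must contain a 'batch' column")
    factor(design$batch)
  } else {
    factor(design)
  }
}

# One PQL fit at fixed theta. Working linear mixed model solved in closed
# form per batch: with diagonal working weights W and Sigma = W^-1 +
# sigma2 Z Z', Woodbury gives Sigma^-1 x = W x - W Z diag(c) Z' W x with
# c_j = sigma2 / (1 + sigma2 * s_j), s_j the per-batch sum of W. All REML
# profile quantities reduce to the per-batch sums of W, Wz and Wz^2.
.pql_fit <- function(y, batch, fam, theta, weights, offset, fix_sigma_b2,
                     ctrl) {
  n <- length(y)
  p <- nlevels(batch)
  bi <- as.integer(batch)
  o <- if (is.null(offset)) numeric(n) else offset
  wobs <- if (is.null(weights)) rep(1, n) else weights
  base <- .base_family(fam, theta = theta)
  linkinv <- base$linkinv
  mu.eta <- base$mu.eta
  varfun <- base$variance

  # initial values: intercept at the link of the (weighted) mean
  if (fam$link == "log") {
    alpha <- log(sum(wobs * y) / sum(wobs * exp(o)) + 1e-8)
  } else {
    m <- min(max(stats::weighted.mean(y, wobs), 1e-4), 1 - 1e-4)
    alpha <- stats::qlogis(m)
  }
  b <- numeric(p)
  sigma2 <- if (is.null(fix_sigma_b2)) 0.1 else fix_sigma_b2
  eta <- alpha + b[bi] + o

  lo <- log(1e-8); hi <- log(1e3)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- linkinv(eta)
    me <- mu.eta(eta)
    z <- (eta - o) + (y - mu) / me
    W <- wobs * me^2 / varfun(mu)
    W <- pmax(W, 1e-12)

    s <- as.vector(rowsum(W, bi))
    t1 <- as.vector(rowsum(W * z, bi))
    Sw <- sum(W); Swz <- sum(W * z); Swzz <- sum(W * z^2)
    slogW <- sum(log(W))

    reml <- function(ls) {
      s2 <- exp(ls)
      cj <- s2 / (1 + s2 * s)
      A11 <- Sw - sum(cj * s^2)
      A1z <- Swz - sum(cj * s * t1)
      Azz <- Swzz - sum(cj * t1^2)
      rSr <- Azz - A1z^2 / A11
      (-slogW + sum(log1p(s2 * s))) + log(A11) + rSr
    }
    if (is.null(fix_sigma_b2)) {
      opt <- stats::optimize(reml, c(lo, hi), tol = 1e-6)
      sigma2_new <- exp(opt$minimum)
      if (sigma2_new <= 2e-8) sigma2_new <- 0
    } else {
      sigma2_new <- fix_sigma_b2
    }

    cj <- if (sigma2_new > 0) sigma2_new / (1 + sigma2_new * s) else numeric(p)
    if (sigma2_new > 0) {
      A11 <- Sw - sum(cj * s^2)
      A1z <- Swz - sum(cj * s * t1)
    } else {
      A11 <- Sw; A1z <- Swz
    }
    alpha_new <- A1z / A11
    b_new <- if (sigma2_new > 0) cj * (t1 - s * alpha_new) else numeric(p)

    delta <- max(abs(alpha_new - alpha), abs(b_new - b),
                 abs(sigma2_new - sigma2)) /
             (1 + max(abs(alpha), abs(b), sigma2))
    alpha <- alpha_new; b <- b_new; sigma2 <- sigma2_new
    eta <- alpha + b[bi] + o
    if (delta < ctrl$tol) { converged <- TRUE; break }
    if (iter >= ctrl$maxit) break
  }

  mu0 <- linkinv(eta)
  list(alpha_hat = alpha,
       b_hat = stats::setNames(b, levels(batch)),
       sigma_b2_hat = sigma2,
       mu0_hat = mu0,
       eta = eta,
       converged = converged,
       n_iter = iter)
}

# weighted NB log-likelihood in theta given mu (lgamma(y+1) term dropped)
.nb_profile_loglik <- function(ltheta, y, mu, w) {
  th <- exp(ltheta)
  sum(w * (lgamma(y + th) - lgamma(th) + th * log(th / (th + mu)) +
             y * log(mu / (th + mu))))
}

# alternate PQL fit <-> profile ML for theta
.fit_null_nb_profile <- function(y, batch, fam, weights, offset,
                                 fix_sigma_b2, ctrl) {
  wobs <- if (is.null(weights)) rep(1, length(y)) else weights
  m <- stats::weighted.mean(y, wobs)
  v <- stats::weighted.mean((y - m)^2, wobs)
  theta <- min(max(m^2 / max(v - m, m / 10), 0.01), 100)
  lo <- log(1e-3); hi <- log(1e5)
  fit <- NULL
  for (k in seq_len(ctrl$theta_alternations)) {
    fit <- .pql_fit(y, batch, fam, theta, weights, offset, fix_sigma_b2, ctrl)
    opt <- stats::optimize(.nb_profile_loglik, c(lo, hi), y = y,
                           mu = fit$mu0_hat, w = wobs,
                           maximum = TRUE, tol = 1e-6)
    theta_new <- exp(opt$maximum)
    done <- abs(log(theta_new) - log(theta)) < 1e-4
    theta <- theta_new
    if (done) break
  }
  fit <- .pql_fit(y, batch, fam, theta, weights, offset, fix_sigma_b2, ctrl)
  fit$theta_hat <- theta
  fit
}

#' @export
print.scmmst_null <- function(x, ...) {
  cat("Null GLMM fit (", x$family$family, " family, ", x$family$link,
      " link)\n", sep = "")
  cat("  alpha:", format(x$alpha_hat, digits = 5),
      "  sigma_b2:", format(x$sigma_b2_hat, digits = 5), "\n")
  if (!is.null(x$theta_hat))
    cat("  theta:", format(x$theta_hat, digits = 5), "\n")
  if (x$tau_hat != 1)
    cat("  tau:", format(x$tau_hat, digits = 5), "\n")
  cat("  batch BLUPs:", paste(format(x$b_hat, digits = 3), collapse = " "),
      "\n")
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' @export
coef.scmmst_null <- function(object, ...) {
  c("(Intercept)" = object$alpha_hat, object$b_hat)
}

#' @export
fitted.scmmst_null <- function(object, ...) object$mu0_hat

#' @export
residuals.scmmst_null <- function(object,
                                  type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$mu0_hat
  if (type == "pearson") {
    base <- .base_family(object$family, theta = object$theta_hat)
    r <- r / sqrt(base$variance(object$mu0_hat))
  }
  r
}
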