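#' Family specification for mixed-model score tests
#'
#' Builds a family descriptor for the count (or binary) distributions the
#' score tests support. Count families use the log link, binary families the
#' logit link. The negative binomial dispersion `theta` may be left `NULL`,
#' in which case [fit_null_glmm()] estimates it by profile maximum
#' likelihood alternated with the mixed-model fit.
#'
#' @param family One of `"poisson"`, `"quasipoisson"`, `"nb"`, `"binomial"`,
#'   `"quasibinomial"`.
#' @param theta Negative binomial dispersion (size) parameter; only used and
#'   only allowed when `family = "nb"`. Must be positive if given.
#' @return An object of class `"scmmst_family"`: a list with elements
#'   `family`, `link`, `theta` and `quasi` (logical; whether the dispersion
#'   `tau` is estimated from the residual deviance rather than fixed at 1).
#' @export
#' @examples
#' family_spec("nb", theta = 2)
#' family_spec("quasipoisson")
family_spec <- function(family = c("poisson", "quasipoisson", "nb",
                                   "binomial", "quasibinomial"),
                        theta = NULL) {
  if (inherits(family, "scmmst_family")) return(family)
  family <- match.arg(family)
  if (!is.null(theta)) {
    if (family != "nb")
      stop("'theta' is only meaningful for family = \"nb\"")
    if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
        theta <= 0)
      stop("'theta' must be a single positive number")
  }
  structure(list(
    family = family,
    link = if (family %in% c("binomial", "quasibinomial")) "logit" else "log",
    theta = theta,
    quasi = family %in% c("quasipoisson", "quasibinomial")
  ), class = "scmmst_family")
}

#' @export
print.scmmst_family <- function(x, ...) {
  cat("scmmst family: ", x$family, " (", x$link, " link)", sep = "")
  if (!is.null(x$theta)) cat(", theta =", format(x$theta))
  cat("\n")
  invisible(x)
}

# base-R family object used for IRLS working quantities; theta only needed
# for the nb variance function
.base_family <- function(fam, theta = NULL) {
  switch(fam$family,
    poisson = ,
    quasipoisson = stats::poisson(),
    nb = MASS::negative.binomial(theta = if (is.null(theta)) fam$theta else theta),
    binomial = ,
    quasibinomial = stats::binomial()
  )
}

#' Diagonal variance and dispersion-shrinkage terms of the null model
#'
#' For the fitted null means `mu0`, returns the diagonal of
#' \eqn{\hat V = diag\{(g'(\hat\mu_{0i}))^2 \widehat{Var}(y_i)\}} and of the
#' matrix \eqn{\hat\Phi} entering the score statistic. On the log link,
#' `v_diag` is `1/mu` for (quasi-)Poisson and `1/mu + 1/theta` for the
#' negative binomial; on the logit link it is `1/(mu*(1-mu))`. `phi_diag` is
#' `1/(1 + mu/theta)` for the negative binomial and exactly 1 otherwise.
#'
#' @param mu0 Vector of fitted null means, strictly positive (and < 1 for
#'   binomial families).
#' @param family A family string or [family_spec()] object; `theta` must be
#'   set for `"nb"`.
#' @param theta Optional override of the NB dispersion.
#' @return A list with numeric vectors `v_diag` and `phi_diag`.
#' @export
#' @examples
#' variance_diag(4, "poisson")              # v = 0.25, phi = 1
#' variance_diag(4, family_spec("nb", 2))   # v = 0.75, phi = 1/3
variance_diag <- function(mu0, family, theta = NULL) {
  fam <- family_spec(family, theta = if (is.character(family)) theta else NULL)
  if (!is.null(theta)) fam$theta <- theta
  if (any(!is.finite(mu0)) || any(mu0 <= 0))
    stop("'mu0' must be strictly positive and finite")
  switch(fam$family,
    poisson = ,
    quasipoisson = list(v_diag = 1 / mu0, phi_diag = rep(1, length(mu0))),
    nb = {
      if (is.null(fam$theta)) stop("NB family requires 'theta'")
      list(v_diag = 1 / mu0 + 1 / fam$theta,
           phi_diag = 1 / (1 + mu0 / fam$theta))
    },
    binomial = ,
    quasibinomial = {
      if (any(mu0 >= 1)) stop("binomial 'mu0' must lie in (0, 1)")
      list(v_diag = 1 / (mu0 * (1 - mu0)), phi_diag = rep(1, length(mu0)))
    }
  )
}

#' Quasi-likelihood dispersion estimate
#'
#' Estimates the quasi dispersion `tau` as the residual deviance of the
#' fitted null model divided by its degrees of freedom (taken as `n - 1`,
#' one fixed intercept; shrunken random effects are not counted). For the
#' non-quasi families tau is 1 by definition.
#'
#' @param fit A fitted null model from [fit_null_glmm()].
#' @param y The count (or proportion) vector the model was fitted to.
#' @param family Family string or [family_spec()] object.
#' @return The scalar dispersion estimate `tau_hat`.
#' @export
estimate_quasi_dispersion <- function(fit, y, family) {
  fam <- family_spec(family)
  if (!fam$quasi) return(1)
  n <- length(y)
  if (n <= 1L) stop("need n > 1 to estimate a quasi dispersion")
  base <- .base_family(fam)
  w <- if (is.null(fit$weights)) rep(1, n) else fit$weights
  dev <- sum(base$dev.resids(y, fit$mu0_hat, w))
  tau <- dev / (n - 1)
  if (!is.finite(tau) || tau <= 0)
    stop("non-positive quasi dispersion estimate")
  tau
}
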