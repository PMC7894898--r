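#' Simulate multi-batch single-cell counts from the GLMM generator
#'
#' Generates, gene by gene, counts from the generalized linear mixed model
#' with a batch random intercept and logit-linked dropout:
#' \deqn{\eta_i = \mu_0 + g_i \beta_{batch(i)} + b_{batch(i)}, \qquad
#'       b \sim N(0, \sigma_b^2 I_p),}
#' with \eqn{y_i \sim Poisson(e^{\eta_i})} or
#' \eqn{NB(e^{\eta_i}, \theta)}; a per-count Bernoulli indicator
#' \eqn{z_i} with keep probability
#' \eqn{logit^{-1}(\mu_\pi + b_{batch(i)})} zeroes the count when
#' \eqn{z_i = 0} (larger `mu_pi` means fewer excess zeros). Differentially
#' expressed genes — the first `floor(de_prop * n_genes)` genes, a
#' deterministic bookkeeping choice — draw per-batch group effects
#' \eqn{\beta \sim N(\beta_0 1_p, \sigma_\beta^2 I_p)}; all other genes
#' have \eqn{\beta = 0}. Cells are dealt round-robin across the
#' batch-by-group grid so every batch contains both groups.
#'
#' By default the dropout logit reuses the same batch effects `b` as the
#' count model (the displayed dropout probability shares `b`);
#' `dropout_batch = "independent"` redraws them.
#'
#' @param n_genes Number of genes.
#' @param n_cells Number of cells (default 250).
#' @param n_batches Number of batches p (default 5).
#' @param family `"poisson"` or `"nb"`.
#' @param theta NB dispersion (default 1; ignored for Poisson).
#' @param mu0 Intercept of the count model on the log scale (default 5).
#' @param sigma_b2 Batch variance component (default 0.25).
#' @param sigma_beta2 Variance of the per-batch group effects (default 0).
#' @param beta0 Baseline group effect (default 0).
#' @param mu_pi Intercept of the dropout logit (default 0).
#' @param de_prop Proportion of DE genes (default 0.1).
#' @param dropout_batch `"shared"` (default) or `"independent"` batch
#'   effects in the dropout logit.
#' @param seed Integer seed; the generator is fully reproducible from it
#'   (per-gene substreams are derived from it, so truth bookkeeping is
#'   stable under any gene-wise execution order).
#' @return A list of class `"scmmst_sim"`: `counts` (genes x cells integer
#'   matrix), `design` (cell design), `truth` (list: `is_de`, `beta_draws`,
#'   `b_draws`, `dropout_mask`), `params`.
#' @export
#' @examples
#' sim <- simulate_dataset(n_genes = 50, seed = 1)
#' table(sim$truth$is_de)
simulate_dataset <- function(n_genes, n_cells = 250L, n_batches = 5L,
                             family = c("nb", "poisson"), theta = 1,
                             mu0 = 5, sigma_b2 = 0.25, sigma_beta2 = 0,
                             beta0 = 0, mu_pi = 0, de_prop = 0.1,
                             dropout_batch = c("shared", "independent"),
                             seed = NULL) {
  family <- match.arg(family)
  dropout_batch <- match.arg(dropout_batch)
  stopifnot(n_genes >= 1, n_cells >= 2, n_batches >= 2,
            sigma_b2 >= 0, sigma_beta2 >= 0, theta > 0,
            de_prop >= 0, de_prop <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- as.integer(n_batches)

  combo <- (seq_len(n_cells) - 1L) %% (2L * p)
  batch <- combo %% p + 1L
  group <- combo %/% p + 1L
  design <- cell_design(batch = paste0("b", batch),
                        group = paste0("g", group))
  g_ind <- as.integer(group == 2L)

  n_de <- floor(de_prop * n_genes)
  is_de <- seq_len(n_genes) <= n_de
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)

  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                   design$cell_id))
  mask <- matrix(1L, n_genes, n_cells)
  b_draws <- matrix(0, n_genes, p)
  beta_draws <- matrix(NA_real_, n_genes, p)

  for (gi in seq_len(n_genes)) {
    set.seed(gene_seeds[gi])
    b <- stats::rnorm(p, 0, sqrt(sigma_b2))
    beta <- if (is_de[gi])
      stats::rnorm(p, beta0, sqrt(sigma_beta2)) else numeric(p)
    eta <- mu0 + g_ind * beta[batch] + b[batch]
    y <- if (family == "poisson") stats::rpois(n_cells, exp(eta))
         else stats::rnbinom(n_cells, mu = exp(eta), size = theta)
    b_drop <- if (dropout_batch == "shared") b
              else stats::rnorm(p, 0, sqrt(sigma_b2))
    keep <- stats::rbinom(n_cells, 1L, stats::plogis(mu_pi + b_drop[batch]))
    counts[gi, ] <- y * keep
    mask[gi, ] <- keep
    b_draws[gi, ] <- b
    if (is_de[gi]) beta_draws[gi, ] <- beta
  }

  structure(list(
    counts = counts,
    design = design,
    truth = list(is_de = is_de, beta_draws = beta_draws, b_draws = b_draws,
                 dropout_mask = mask),
    params = list(n_genes = n_genes, n_cells = n_cells, n_batches = p,
                  family = family, theta = theta, mu0 = mu0,
                  sigma_b2 = sigma_b2, sigma_beta2 = sigma_beta2,
                  beta0 = beta0, mu_pi = mu_pi, de_prop = de_prop,
                  dropout_batch = dropout_batch, seed = seed)
  ), class = "scmmst_sim")
}

#' Simulate a null dataset (no group effects)
#'
#' Same generator as [simulate_dataset()] with all group effects forced to
#' zero; passing nonzero effect parameters is an error so null calibration
#' studies cannot silently contain signal.
#'
#' @inheritParams simulate_dataset
#' @return A `"scmmst_sim"` object whose truth is all-null.
#' @export
simulate_null_dataset <- function(n_genes, n_cells = 250L, n_batches = 5L,
                                  family = c("nb", "poisson"), theta = 1,
                                  mu0 = 5, sigma_b2 = 0.25, mu_pi = 0,
                                  beta0 = 0, sigma_beta2 = 0, de_prop = 0,
                                  dropout_batch = c("shared", "independent"),
                                  seed = NULL) {
  if (beta0 != 0 || sigma_beta2 != 0 || de_prop != 0)
    stop("a null dataset must have beta0 = sigma_beta2 = de_prop = 0")
  simulate_dataset(n_genes = n_genes, n_cells = n_cells,
                   n_batches = n_batches, family = family, theta = theta,
                   mu0 = mu0, sigma_b2 = sigma_b2, sigma_beta2 = 0,
                   beta0 = 0, mu_pi = mu_pi, de_prop = 0,
                   dropout_batch = dropout_batch, seed = seed)
}

#' @export
print.scmmst_sim <- function(x, ...) {
  p <- x$params
  cat("Simulated scRNA-seq dataset: ", p$n_genes, " genes x ", p$n_cells,
      " cells, ", p$n_batches, " batches (", p$family, ")\n", sep = "")
  cat("  DE genes:", sum(x$truth$is_de),
      " zero fraction:", format(mean(x$counts == 0), digits = 3), "\n")
  invisible(x)
}
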