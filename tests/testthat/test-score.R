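test_that("score statistic matches the worked dense example", {
  # r = (1,-1,2,0), g = (1,1,0,0), batches (1,2,1,2), Phi = I, tau = 1:
  # G_B' r = (1, -1), T = 2
  d <- cell_design(batch = c("b1", "b2", "b1", "b2"),
                   group = c("g1", "g1", "g2", "g2"))
  fit <- list(mu0_hat = c(0, 2, 0, 2), phi_diag = rep(1, 4), tau_hat = 1)
  y <- c(1, 1, 2, 2)                     # residuals (1,-1,2,0)
  g <- c(1, 1, 0, 0)
  expect_equal(score_statistic(y, fit, d, g), 2)
  expect_equal(score_statistic(y, fit, d, rep(0, 4)), 0)
  # identity weights change nothing
  expect_equal(score_statistic(y, fit, d, g, weights = rep(1, 4)), 2)
})

test_that("fast Sigma-inverse and E agree with dense linear algebra", {
  for (seed in 1:8) {
    inst <- random_instance(n = sample(10:50, 1), p = sample(2:5, 1), seed)
    proj <- null_projection(inst$v_diag, inst$sigma_b2, inst$batch)
    Si <- dense_sigma_inv(inst$v_diag, inst$sigma_b2, inst$batch)
    x <- rnorm(length(inst$v_diag))
    expect_equal(as.vector(proj$sigma_inv(x)), as.vector(Si %*% x),
                 tolerance = 1e-8)
    expect_equal(proj$one_sigma_inv_one, sum(Si), tolerance = 1e-8)

    fit <- list(v_diag = inst$v_diag, sigma_b2_hat = inst$sigma_b2)
    E <- e_matrix(fit, inst$batch, inst$g)
    expect_equal(E, unname(dense_E(inst$v_diag, inst$sigma_b2, inst$batch,
                                   inst$g)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    Ew <- e_matrix(fit, inst$batch, inst$g, weights = inst$w)
    expect_equal(Ew, unname(dense_E(inst$v_diag, inst$sigma_b2, inst$batch,
                                    inst$g, weights = inst$w)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # unit weights give E exactly
    expect_equal(e_matrix(fit, inst$batch, inst$g, weights = rep(1, length(inst$g))),
                 E)
    # trace equals the eigenvalue sum
    xi <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(diag(E)), sum(xi), tolerance = 1e-10)
  }
})

test_that("sigma_b2 = 0 degenerates to the diagonal covariance", {
  inst <- random_instance(30, 3, 99)
  proj <- null_projection(inst$v_diag, 0, inst$batch)
  x <- rnorm(30)
  expect_equal(as.vector(proj$sigma_inv(x)), x / inst$v_diag)
})

test_that("mixture chi-square tail matches closed forms and Monte Carlo", {
  expect_equal(mixture_chisq_pvalue(1, qchisq(0.95, 1))$p_value, 0.05,
               tolerance = 1e-4)
  # 0.5 * chisq_2 has survival exp(-t)
  expect_equal(mixture_chisq_pvalue(c(0.5, 0.5), log(20))$p_value, 0.05,
               tolerance = 1e-4)
  expect_equal(mixture_chisq_pvalue(c(1, 2, 3), 0)$p_value, 1)
  expect_warning(p0 <- mixture_chisq_pvalue(numeric(0), 1), "eigenvalues")
  expect_equal(p0$p_value, 1)

  # Monte Carlo cross-check over random eigenvalue sets
  for (seed in 1:10) {
    set.seed(seed)
    xi <- runif(sample(2:5, 1), 0.1, 4)
    t0 <- sum(xi) * runif(1, 0.8, 2.5)
    mc <- mc_mixchisq_tail(xi, t0, 2e5, seed + 1000)
    pv <- mixture_chisq_pvalue(xi, t0)
    expect_lt(abs(pv$p_value - mc$p), 3 * mc$se + 1e-12)
  }
})

test_that("quasi dispersion scales the statistic but not the eigenvalues", {
  d <- cell_design(batch = rep(c("b1", "b2"), 10),
                   group = rep(c("g1", "g2"), each = 10))
  set.seed(3)
  y <- rpois(20, 5)
  fit <- list(mu0_hat = rep(5, 20), phi_diag = rep(1, 20), tau_hat = 1)
  g <- as.integer(d$group == "g2")
  t1 <- score_statistic(y, fit, d, g)
  for (cc in c(0.5, 2, 7)) {
    fit$tau_hat <- cc
    expect_equal(score_statistic(y, fit, d, g), t1 / cc)
  }
})

test_that("per-gene testing degrades gracefully and stays calibrated", {
  d <- cell_design(batch = rep(paste0("b", 1:3), length.out = 60),
                   group = rep(c("g1", "g2"), 30))
  g <- as.integer(d$group == "g2")

  # all-zero gene: p = 1 with the failure flag set, no error raised
  r0 <- test_gene(rep(0, 60), d, g, "poisson")
  expect_true(r0$failed)
  expect_equal(r0$p_value, 1)

  # constant nonzero gene: residuals vanish, T ~ 0, p ~ 1
  rc <- test_gene(rep(7, 60), d, g, "poisson")
  expect_false(rc$failed)
  expect_lt(rc$statistic, 1e-6)
  expect_gt(rc$p_value, 0.999)
})

test_that("null NB data yield conservative rejection rates", {
  # no dropout: the unweighted NB test on its own generating model
  sim <- simulate_null_dataset(n_genes = 400, n_cells = 250, family = "nb",
                               theta = 1, mu_pi = 20, seed = 31)
  fit <- scmmst(sim$counts, sim$design, target = "g2", family = "nb",
                weights = "none")
  rate <- pcer(fit$results$p_value, 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), stepup_bh(p))
})

test_that("result tables are deterministic and order-equivariant", {
  sim <- simulate_null_dataset(n_genes = 25, n_cells = 100, n_batches = 2,
                               family = "poisson", mu0 = 2, mu_pi = 0,
                               seed = 41)
  f1 <- scmmst(sim$counts, sim$design, target = "g2", family = "poisson",
               weights = "zipois")
  f2 <- scmmst(sim$counts, sim$design, target = "g2", family = "poisson",
               weights = "zipois")
  expect_identical(f1$results, f2$results)

  perm <- sample(nrow(sim$counts))
  f3 <- scmmst(sim$counts[perm, ], sim$design, target = "g2",
               family = "poisson", weights = "zipois")
  expect_equal(f3$results[order(match(f3$results$gene_id, f1$results$gene_id)),
                          c("statistic", "p_value", "p_adj")],
               f1$results[, c("statistic", "p_value", "p_adj")],
               ignore_attr = TRUE)

  expect_error(scmmst(sim$counts, sim$design, target = "nope",
                      family = "poisson"),
               "available: g1, g2")

  # parallel execution reproduces the serial result exactly
  f4 <- scmmst(sim$counts, sim$design, target = "g2", family = "poisson",
               weights = "zipois", threads = 2)
  expect_identical(f4$results, f1$results)
})
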