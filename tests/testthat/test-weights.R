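test_that("truncated-Poisson solver inverts the truncated-mean equation", {
  expect_equal(trpois_lambda(2 / (1 - exp(-2))), 2, tolerance = 1e-6)
  expect_equal(trpois_lambda(1 / (1 - exp(-1))), 1, tolerance = 1e-6)
  expect_lt(trpois_lambda(1), 1e-9)
  expect_error(trpois_lambda(0.9), "below 1")
  # residual on the spec grid of truncated means
  for (ybar in c(1.01, 1.1, 2, 5, 50)) {
    lam <- trpois_lambda(ybar)
    expect_lt(abs(lam / (1 - exp(-lam)) - ybar), 1e-8)
  }
})

test_that("truncated-Poisson weights satisfy formula and truncation identity", {
  # lambda = ln 2 makes the truncated mean ln2/0.5; build a sample with
  # that exact nonzero mean, 10 zeros, 10 nonzeros
  lam <- log(2)
  ybar <- lam / (1 - exp(-lam))
  y <- c(rep(0, 10), rep(ybar, 10))        # weights only use the mean
  w <- trpois_weights(y)
  expect_equal(unique(w[y > 0]), 1)
  expect_equal(unique(w[y == 0]), 10 * 0.5 / (10 * 0.5), tolerance = 1e-8)

  expect_equal(trpois_weights(c(1, 2, 3)), rep(1, 3))   # no zeros
  expect_warning(w0 <- trpois_weights(c(0, 0, 0)), "all counts zero")
  expect_equal(w0, rep(1, 3))

  # derivation identity w*n0/(w*n0 + n1) = exp(-lambda) before clipping
  set.seed(11)
  for (r in 1:20) {
    y <- rpois(200, runif(1, 1, 6))
    if (!any(y == 0) || all(y == 0)) next
    n0 <- sum(y == 0); n1 <- sum(y > 0)
    lam <- trpois_lambda(mean(y[y > 0]))
    w0 <- n1 * exp(-lam) / (n0 * (1 - exp(-lam)))
    expect_lt(abs(w0 * n0 / (w0 * n0 + n1) - exp(-lam)), 1e-10)
  }
})

test_that("ZIP EM recovers parameters and increases the likelihood", {
  y <- c(1, 2, 3)                            # no zeros
  f <- zipois_fit(y)
  expect_equal(f$pi_hat, 0)
  expect_equal(f$lambda_hat, 2)

  set.seed(12)
  y <- ifelse(rbinom(10000, 1, 0.3) == 1, 0L, rpois(10000, 5))
  f <- zipois_fit(y)
  expect_true(f$converged)
  expect_lt(abs(f$pi_hat - 0.3), 0.03)
  expect_lt(abs(f$lambda_hat - 5), 0.1)
  expect_true(all(diff(f$loglik) > -1e-10))  # EM monotonicity

  expect_error(zipois_fit(c(0, 0, 0)), "not identifiable")
})

test_that("zero-inflated weights are the component posterior", {
  fit <- list(pi_hat = 0, lambda_hat = 3)
  expect_equal(zero_inflated_weight(c(0, 1, 7), fit), rep(1, 3))

  fit <- list(pi_hat = 0.5, lambda_hat = log(2))   # f(0) = 0.5
  expect_equal(zero_inflated_weight(0, fit), (0.5 * 0.5) / (0.5 + 0.5 * 0.5))
  expect_equal(zero_inflated_weight(3, fit), 1)

  fit <- list(pi_hat = 0.4, lambda_hat = 500)      # f(0) ~ 0
  expect_lt(zero_inflated_weight(0, fit), 1e-100)

  fit_nb <- list(pi_hat = 0.5, mu_hat = 2, theta_hat = 1)  # f(0) = 1/3
  expect_equal(zero_inflated_weight(0, fit_nb, "nb"),
               (0.5 / 3) / (0.5 + 0.5 / 3))
})

test_that("truncated-NB moment fit recovers simulated parameters", {
  set.seed(13)
  y <- rnbinom(30000, mu = 10, size = 5)
  y <- y[y > 0][1:10000]
  f <- trnb_fit(y)
  expect_lt(abs(f$mu_hat - 10) / 10, 0.05)
  expect_lt(abs(f$theta_hat - 5) / 5, 0.25)
  expect_false(f$low_confidence)

  # small-dispersion estimates are flagged as low confidence
  set.seed(14)
  y2 <- rnbinom(5000, mu = 5, size = 0.5)
  f2 <- trnb_fit(y2[y2 > 0])
  expect_lt(f2$theta_hat, 2)
  expect_true(f2$low_confidence)

  # near-Poisson data pushes theta to the upper clamp, flagged
  set.seed(15)
  y3 <- rpois(5000, 8)
  f3 <- trnb_fit(y3)
  expect_true(f3$theta_hat >= 1e3 || f3$low_confidence)

  expect_error(trnb_fit(c(0, 4, 4, 4)), "degenerate")
})

test_that("truncated-NB gene weights pool dispersion harmonically", {
  # harmonic mean of (1, 3) is 1.5
  expect_equal(2 / (1 / 1 + 1 / 3), 1.5)
  set.seed(16)
  d <- cell_design(batch = rep(c("b1", "b2"), each = 300),
                   group = rep("g1", 600))
  y <- c(rnbinom(300, mu = 8, size = 3), rnbinom(300, mu = 20, size = 3))
  w <- trnb_weights(y, d)
  expect_true(all(w[y > 0] == 1))
  expect_true(all(w > 0 & w <= 1))
  # zeros in the high-mean batch are less surprising under NB than the
  # low-mean batch only if p0 differs; weights are per batch constant
  expect_lte(length(unique(w[y == 0 & d$batch == "b1"])), 1)

  # batch without zeros keeps weight 1
  y2 <- c(rnbinom(300, mu = 8, size = 3), rnbinom(300, mu = 30, size = 30) + 1)
  w2 <- trnb_weights(y2, d)
  expect_true(all(w2[301:600] == 1))
})

test_that("ZiNB regression weights approximate the true posterior", {
  set.seed(17)
  n <- 5000
  d <- cell_design(batch = rep(paste0("b", 1:5), length.out = n),
                   group = rep("g1", n))
  mu_b <- c(3, 6, 10, 15, 25)[as.integer(d$batch)]
  drop <- rbinom(n, 1, 0.4)
  y <- ifelse(drop == 1, 0L, rnbinom(n, mu = mu_b, size = 2))
  w <- zinb_regression_weights(y, d)
  expect_true(all(w[y > 0] == 1))
  expect_true(all(diff(attr(w, "loglik")) > -1e-10 * abs(attr(w, "loglik")[-1])))
  f0 <- dnbinom(0, mu = mu_b, size = 2)
  post_nb <- (0.6 * f0) / (0.4 + 0.6 * f0)       # true P(NB | y = 0)
  zero <- y == 0
  expect_lt(mean(abs(w[zero] - post_nb[zero])), 0.05)

  # gene with no zeros short-circuits to all ones
  yz <- rnbinom(n, mu = 50, size = 20) + 1L
  expect_equal(as.vector(zinb_regression_weights(yz, d)), rep(1, n))
  expect_error(zinb_regression_weights(rep(0L, n), d), "all-zero")
})

test_that("weight dispatch obeys the hard invariants for every method", {
  set.seed(18)
  sim <- simulate_null_dataset(n_genes = 12, n_cells = 150, n_batches = 3,
                               family = "nb", theta = 2, mu0 = 2.5,
                               mu_pi = 0, seed = 18)
  for (m in c("none", "trpois", "zipois", "trnb", "zinb")) {
    wm <- suppressWarnings(compute_weights(sim$counts, sim$design, method = m))
    expect_true(all(wm$w > 0 & wm$w <= 1), info = m)
    expect_true(all(wm$w[sim$counts > 0] == 1), info = m)
    if (m == "none") expect_true(all(wm$w == 1))
  }

  # no zeros at all: every method returns all ones
  cm1 <- matrix(rpois(5 * 150, 50) + 1L, 5, 150)
  dimnames(cm1) <- list(paste0("g", 1:5), sim$design$cell_id)
  for (m in c("trpois", "zipois", "trnb", "zinb")) {
    wm <- compute_weights(cm1, sim$design, method = m)
    expect_true(all(wm$w == 1), info = m)
  }
})

test_that("TrPois and ZiPois downweight zeros in near agreement", {
  set.seed(19)
  sim <- simulate_null_dataset(n_genes = 40, n_cells = 250, family = "poisson",
                               mu0 = 1.5, mu_pi = 0, seed = 19)
  wt <- compute_weights(sim$counts, sim$design, method = "trpois")
  wz <- compute_weights(sim$counts, sim$design, method = "zipois")
  zero <- sim$counts == 0
  rho <- cor(wt$w[zero], wz$w[zero], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("weight matrices export to TSV", {
  sim <- simulate_null_dataset(n_genes = 3, n_cells = 40, n_batches = 2,
                               family = "poisson", mu0 = 1, mu_pi = 0,
                               seed = 20)
  wm <- compute_weights(sim$counts, sim$design, method = "trpois")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(wm, path)
  back <- read.delim(path)
  expect_equal(dim(back), c(3, 41))
  expect_equal(back$gene_id, rownames(sim$counts))
})
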