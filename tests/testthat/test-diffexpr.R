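make_groups <- function(nt, nc) c(rep("stress", nt), rep("control", nc))

test_that("two-group contrast returns difference of means and pooled variance", {
  m <- rbind(g1 = c(4, 4, 2, 2), g2 = c(3, 5, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  fit <- fit_contrasts(m, make_groups(2, 2), c("stress", "control"))
  expect_equal(unname(fit$log2fc), c(2, 2))
  # pooled: ((3-4)^2+(5-4)^2+(1-2)^2+(3-2)^2)/2 = 2
  expect_equal(unname(fit$residual_var), c(0, 2))
  expect_equal(fit$residual_df, 2)

  # permuting sample order changes nothing
  perm <- c(3, 1, 4, 2)
  fit2 <- fit_contrasts(m[, perm], make_groups(2, 2)[perm], c("stress", "control"))
  expect_equal(fit2, fit)

  expect_error(
    fit_contrasts(m[, 1:3], c("stress", "stress", "control"), c("stress", "control")),
    ">= 2 samples")
})

test_that("moderation hyperparameters are recovered and scale correctly", {
  set.seed(11)
  d0 <- 4; s02 <- 0.05; d <- 4
  sigma2 <- s02 * d0 / rchisq(20000, d0)
  s2 <- sigma2 * rchisq(20000, d) / d
  mp <- estimate_moderation(s2, d)
  expect_lt(abs(mp$prior_df - d0) / d0, 0.15)
  expect_lt(abs(mp$prior_var - s02) / s02, 0.10)

  # same moment method as the reference empirical-Bayes fit
  fd <- limma::fitFDist(s2, df1 = d)
  expect_equal(mp$prior_df, fd$df2, tolerance = 1e-8)
  expect_equal(mp$prior_var, fd$scale, tolerance = 1e-8)

  # doubling every variance doubles prior_var, leaves prior_df unchanged
  mp2 <- estimate_moderation(2 * s2, d)
  expect_equal(mp2$prior_df, mp$prior_df, tolerance = 1e-8)
  expect_equal(mp2$prior_var, 2 * mp$prior_var, tolerance = 1e-8)

  # no spread at all -> infinite prior df; the prior variance is the
  # digamma-corrected geometric mean (unbiased under chi-square sampling)
  mp3 <- estimate_moderation(rep(0.3, 100), 4)
  expect_identical(mp3$prior_df, Inf)
  expect_equal(mp3$prior_var, exp(log(0.3) - digamma(2) + log(2)),
               tolerance = 1e-10)

  expect_error(estimate_moderation(rep(0, 50), 4), "zero")
})

test_that("moderated t has the stated limits and shrinkage behavior", {
  set.seed(12)
  s2 <- rchisq(50, 4) / 40
  lfc <- rnorm(50)
  params0 <- structure(list(prior_df = 0, prior_var = 1),
                       class = "moderation_params")
  mod0 <- moderated_statistics(lfc, s2, 4, 3, 3, params0)
  # prior_df = 0 reduces to the ordinary pooled two-sample t
  expect_equal(mod0$t, lfc / sqrt(s2 * (1 / 3 + 1 / 3)))
  expect_equal(mod0$p_value, 2 * pt(-abs(mod0$t), df = 4))

  paramsInf <- structure(list(prior_df = Inf, prior_var = 0.1),
                         class = "moderation_params")
  modI <- moderated_statistics(lfc, s2, 4, 3, 3, paramsInf)
  expect_equal(modI$t, lfc / sqrt(0.1 * (2 / 3)))
  expect_equal(modI$p_value, 2 * pnorm(-abs(modI$t)))

  # zero effect -> t = 0, p = 1
  z <- moderated_statistics(0, 0.2, 4, 3, 3, paramsInf)
  expect_equal(z$t, 0)
  expect_equal(z$p_value, 1)

  # posterior variance lies between the residual and prior variances
  params <- structure(list(prior_df = 4, prior_var = 0.1),
                      class = "moderation_params")
  post <- (4 * 0.1 + 4 * s2) / 8
  expect_true(all(post >= pmin(s2, 0.1) & post <= pmax(s2, 0.1)))
  # monotone in |log2fc| at fixed variance
  tt <- moderated_statistics(c(0.5, 1, 2), rep(0.2, 3), 4, 3, 3, params)$t
  expect_true(all(diff(tt) > 0))
})

test_that("moderated pipeline agrees with the reference implementation", {
  set.seed(13)
  gene_sd <- sqrt(0.25 * 4 / rchisq(200, 4))  # heterogeneous true variances
  m <- matrix(rnorm(200 * 6, mean = 7, sd = gene_sd), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  m[1:10, 4:6] <- m[1:10, 4:6] + 2
  grp <- make_groups(3, 3)
  deg <- run_deg(m, grp, c("stress", "control"))
  design <- cbind(1, grp == "stress")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(deg$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(deg$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(deg$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(14)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # label invariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("DEG calling applies both gates with strict inequalities", {
  tab <- data.frame(gene = paste0("gene", 1:5),
                    log2fc = c(2, 0.5, -1.5, 3, 1.0),
                    fdr = c(0.01, 0.01, 0.2, 0.04, 0.01))
  # |lfc| = 1.0 fails the strict > 1 rule; gene3 fails the FDR gate
  expect_equal(call_degs(tab), c("gene1", "gene4"))
  expect_equal(call_degs(tab[0, ]), character(0))
})

test_that("the DEG test is calibrated and BH controls family-wise null error", {
  sim <- simulate_multistudy(null_sim_config(4000, seed = 21))
  d1 <- sim$datasets[[1]]
  grp <- stats::setNames(d1$sample_info$condition, d1$sample_info$sample)
  deg <- run_deg(d1$matrix, grp, c("stress", "control"))
  expect_gt(mean(deg$p_value < 0.05), 0.035)
  expect_lt(mean(deg$p_value < 0.05), 0.065)
  expect_true(all(deg$fdr >= deg$p_value))
  expect_true(all(deg$is_deg == (abs(deg$log2fc) > 1 & deg$fdr < 0.05)))
})
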