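test_that("inverse-normal combination has the stated closed forms", {
  # single study: identity
  one <- combine_inverse_normal(0.04, +1)
  expect_equal(one$z, qnorm(1 - 0.02))
  expect_equal(one$p, 0.04)

  # two studies, one-sided p = 0.05 each, same direction
  two <- combine_inverse_normal(c(0.1, 0.1), c(1, 1))
  expect_equal(two$z, 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-10)
  expect_equal(two$z, 2.3263, tolerance = 1e-4)
  expect_equal(pnorm(-two$z), 0.0100, tolerance = 1e-3)

  # equal evidence in opposite directions cancels
  opp <- combine_inverse_normal(c(0.1, 0.1), c(1, -1))
  expect_equal(opp$z, 0)
  expect_equal(opp$p, 1)

  # k identical studies scale z by sqrt(k)
  for (k in c(2, 4, 9)) {
    zk <- combine_inverse_normal(rep(0.1, k), rep(1, k))$z
    expect_equal(zk, sqrt(k) * qnorm(0.95), tolerance = 1e-10)
  }

  # adding an uninformative study (p = 1 two-sided, z = 0) dilutes |z|
  base <- combine_inverse_normal(c(0.01, 0.02), c(1, 1))$z
  diluted <- combine_inverse_normal(c(0.01, 0.02, 1), c(1, 1, 0))$z
  expect_lt(abs(diluted), abs(base))

  expect_warning(combine_inverse_normal(0, 1), "clamped")
  expect_error(combine_inverse_normal(c(0.1, 0.2), c(1, 1), c(1, -1)),
               "positive")
  expect_error(combine_inverse_normal(0.1, 2), "directions")
})

test_that("fixed-effect pooling follows inverse-variance arithmetic", {
  # identical studies average to themselves with variance v/k
  same <- combine_effect_sizes(rep(1.5, 4), rep(0.2, 4))
  expect_equal(same$pooled, 1.5)
  expect_equal(same$pooled_var, 0.05)

  two <- combine_effect_sizes(c(1.0, 2.0), c(0.5, 1.0))
  expect_equal(two$pooled, 4 / 3)

  # a study with huge variance barely moves the estimate
  lim <- combine_effect_sizes(c(1.0, 50), c(0.1, 1e8))
  expect_equal(lim$pooled, 1.0, tolerance = 1e-4)

  expect_error(combine_effect_sizes(c(1, 2), c(0.5, 0)), "positive")
  expect_error(combine_effect_sizes(1, 0.5), ">= 2")
})

test_that("fixed-effect pooling matches an independent meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(30)
  d <- rnorm(5); v <- runif(5, 0.1, 1)
  mine <- combine_effect_sizes(d, v)
  ref <- metafor::rma(yi = d, vi = v, method = "FE")
  expect_equal(mine$pooled, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(mine$p, as.numeric(ref$pval), tolerance = 1e-8)
})

toy_deg <- function(genes, p, lfc, n = 6L) {
  tab <- data.frame(gene = genes, log2fc = lfc, p_value = p)
  attr(tab, "n_treatment") <- n / 2
  attr(tab, "n_control") <- n / 2
  tab
}

test_that("common-responsive calling needs two or more stress types", {
  genes <- c("gA", "gB", "gC")
  studies <- list(
    list(stress = "Fe", study = "fe1",
         deg = toy_deg(genes, c(1e-8, 1e-8, 0.9), c(2, 2, 0))),
    list(stress = "Zn", study = "zn1",
         deg = toy_deg(genes, c(1e-8, 0.8, 0.9), c(2, 0.1, 0))),
    list(stress = "Cu", study = "cu1",
         deg = toy_deg(genes, c(0.7, 0.9, 0.9), c(0, 0, 0)))
  )
  meta <- meta_combine(studies)
  expect_named(meta, c("Fe", "Zn", "Cu"))
  # gA significant under Fe and Zn -> included; gB only Fe -> excluded
  common <- call_common_responsive(meta)
  expect_equal(common, "gA", ignore_attr = TRUE)
  counts <- attr(common, "n_stress_passing")
  expect_equal(unname(counts["gA"]), 2L)
  expect_equal(unname(counts["gB"]), 1L)
  one_stress <- structure(unclass(meta)[1], class = "meta_result")
  expect_error(call_common_responsive(one_stress, p_threshold = 0.05),
               ">= 2 stress types")
})

test_that("single-study meta reproduces the study's evidence", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(31)
  p <- runif(20); lfc <- rnorm(20)
  studies <- list(list(stress = "Fe", study = "fe1", deg = toy_deg(genes, p, lfc)))
  meta <- meta_combine(studies)
  expect_equal(meta$Fe$combined_p, p, tolerance = 1e-10)
  expect_equal(sign(meta$Fe$combined_z), sign(lfc))
  expect_true(all(meta$Fe$n_studies == 1))
})

test_that("null combined p-values are uniform", {
  sim <- simulate_multistudy(null_sim_config(2000, seed = 33,
                                             studies_per_stress = 3L))
  meta <- meta_combine(deg_studies(sim))
  for (s in names(meta)) {
    ks <- suppressWarnings(stats::ks.test(meta[[s]]$combined_p, "punif"))
    expect_lt(unname(ks$statistic), 1.358 / sqrt(2000))
  }
})
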