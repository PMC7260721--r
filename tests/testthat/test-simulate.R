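test_that("identical seeds give bit-identical simulations", {
  cfg <- simulate_config(n_genes = 300, seed = 7,
                         n_mutant_specific = c(gpa1 = 20L, agb1 = 15L),
                         planted_intersection = c(gpa1 = 2L, agb1 = 2L))
  s1 <- simulate_multistudy(cfg)
  s2 <- simulate_multistudy(cfg)
  expect_identical(s1, s2)
  g1 <- simulate_grn(cfg)
  g2 <- simulate_grn(cfg)
  expect_identical(g1, g2)
})

test_that("configuration errors name the offending field", {
  expect_error(simulate_config(samples_per_group = 1), "samples_per_group")
  expect_error(simulate_config(frac_common_responsive = 1.2),
               "frac_common_responsive")
  expect_error(simulate_config(prior_accuracy = 1.5), "prior_accuracy")
  expect_error(simulate_config(noise_sd = 0), "noise_sd")
  expect_error(
    simulate_config(n_mutant_specific = c(gpa1 = 10L, agb1 = 10L),
                    planted_intersection = c(gpa1 = 11L, agb1 = 2L)),
    "planted_intersection\\[gpa1\\]")
  expect_error(
    simulate_config(planted_intersection = c(gpa1 = 200L, agb1 = 25L),
                    n_mutant_specific = c(gpa1 = 500L, agb1 = 120L)),
    "common-responsive pool")
})

test_that("ground-truth set algebra is internally consistent", {
  sim <- simulate_multistudy(simulate_config(seed = 5))
  truth <- sim$truth
  counts <- table(unlist(truth$responsive_sets))
  expect_setequal(truth$common_responsive, names(counts)[counts >= 2])
  # planted intersections realized exactly
  for (g in names(truth$mutant_sets)) {
    expect_equal(length(intersect(truth$mutant_sets[[g]],
                                  truth$common_responsive)),
                 truth$planted_intersections[[g]])
  }
  # cluster labels cover exactly the common set
  expect_setequal(names(truth$cluster_labels), truth$common_responsive)
})

test_that("planted effects are direction-consistent across studies", {
  sim <- simulate_multistudy(simulate_config(n_genes = 500, seed = 6,
    n_mutant_specific = c(gpa1 = 30L, agb1 = 20L),
    planted_intersection = c(gpa1 = 3L, agb1 = 3L)))
  s <- sim$truth$responsive_sets[[1]][1:10]
  stress <- names(sim$truth$responsive_sets)[1]
  eff <- sim$truth$effects[[stress]][s]
  for (d in sim$datasets) {
    if (d$stress != stress) next
    trt <- d$sample_info$condition == "stress"
    diff <- rowMeans(d$matrix[s, trt]) - rowMeans(d$matrix[s, !trt])
    # observed difference tracks the planted signed effect (|effect| ~ 2,
    # sampling sd ~ 0.2)
    expect_true(all(sign(diff) == sign(eff)))
    expect_lt(max(abs(diff - eff)), 1)
  }
})

test_that("regulatory layer honors its limiting cases", {
  cfg <- simulate_config(seed = 10, prior_accuracy = 1)
  grn <- simulate_grn(cfg)
  # perfect priors place zero mass off the true edges
  truth_key <- paste(grn$truth$true_edges$tf, grn$truth$true_edges$target)
  pri <- grn$priors
  for (j in colnames(pri)) {
    on <- paste(rownames(pri)[pri[, j] > 0], j)
    has_parent <- any(j == grn$truth$true_edges$target)
    if (has_parent) expect_true(all(on %in% truth_key))
  }
  expect_true(all(grn$truth$true_edges$tf %in% grn$tfs))

  # noiseless single-parent targets are exact multiples of their TF
  cfg0 <- simulate_config(seed = 11, grn_noise_sd = 0, targets_per_tf = 1L)
  g0 <- simulate_grn(cfg0)
  e <- g0$truth$true_edges
  single <- names(table(e$target))[table(e$target) == 1]
  for (tg in single[1:5]) {
    row <- e[e$target == tg, ]
    expect_equal(g0$matrix[tg, ], row$coefficient * g0$matrix[row$tf, ],
                 tolerance = 1e-12)
  }
})

test_that("simulated output round-trips through the exchange formats", {
  cfg <- simulate_config(n_genes = 100, seed = 12,
                         n_mutant_specific = c(gpa1 = 10L, agb1 = 8L),
                         planted_intersection = c(gpa1 = 1L, agb1 = 1L))
  sim <- simulate_multistudy(cfg)
  tmp <- withr::local_tempdir()
  write_simulation(sim, tmp, grn = simulate_grn(cfg))
  back <- read_datasets(tmp)
  expect_equal(names(back$datasets), names(sim$datasets))
  expect_equal(back$datasets[[1]]$matrix, sim$datasets[[1]]$matrix,
               tolerance = 1e-12)
  expect_equal(back$sample_sheet$sample, sim$sample_sheet$sample)
  sets <- read_gmt(file.path(tmp, "planted_sets.gmt"))
  expect_setequal(sets$common_responsive, sim$truth$common_responsive)
  expect_true(file.exists(file.path(tmp, "ground_truth.json")))
  pri <- read_prior_matrix(file.path(tmp, "grn_priors.tsv"))
  expect_equal(dim(pri), c(cfg$n_tfs, cfg$n_tfs * cfg$targets_per_tf))
})
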