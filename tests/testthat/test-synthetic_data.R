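test_that("synth_config validates its invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(rock_fraction = 1.2), "rock_fraction")
  expect_error(synth_config(n_taxa = 1), "n_taxa")
  expect_error(synth_config(depth_mean = 0), "depth_mean")
  expect_error(synth_config(clumping = -1), "clumping")
  expect_error(synth_config(assembly_mode = "bogus"))
})

test_that("gen_tree: smallest tree, determinism, metric symmetry", {
  t2 <- gen_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)
  expect_identical(ape::write.tree(gen_tree(50, seed = 7)),
                   ape::write.tree(gen_tree(50, seed = 7)))
  tr <- gen_tree(50, seed = 7)
  expect_true(all(tr$edge.length > 0))
  D <- cophenetic_matrix(tr)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(gen_tree(1, seed = 1), ">= 2")
})

test_that("gen_soil_grid honours rock fraction, depth targets, clumping", {
  # extremes
  g0 <- gen_soil_grid(synth_config(rock_fraction = 0, seed = 2))
  expect_true(all(g0$depths > 0))
  expect_equal(delineate_patches(g0)$n_patches, 1L)
  g1 <- gen_soil_grid(synth_config(rock_fraction = 1, seed = 2))
  expect_true(all(g1$depths == 0))
  expect_equal(delineate_patches(g1)$n_patches, 0L)
  # realized rock fraction within +-0.05 at 26 x 26
  for (rf in c(0.25, 0.5)) {
    g <- gen_soil_grid(synth_config(rock_fraction = rf, seed = 4))
    expect_lt(abs(mean(g$depths == 0) - rf), 0.05)
  }
  # depth mean/CV near the lognormal targets (one large grid)
  big <- gen_soil_grid(synth_config(n_rows = 60, n_cols = 60,
                                    rock_fraction = 0.2, seed = 5))
  d <- big$depths[big$depths > 0]
  expect_equal(mean(d), 24.27, tolerance = 0.1)
  expect_equal(sd(d) / mean(d), 0.53, tolerance = 0.15)
  # clumping aggregates rock -> strictly fewer patches at the same seed
  smooth <- gen_soil_grid(synth_config(rock_fraction = 0.5, clumping = 2,
                                       seed = 3))
  rough <- gen_soil_grid(synth_config(rock_fraction = 0.5, clumping = 0,
                                      seed = 3))
  expect_lt(delineate_patches(smooth)$n_patches,
            delineate_patches(rough)$n_patches)
})

test_that("gen_resource_samples: coverage, determinism, CV = 0 degeneracy", {
  cfg <- synth_config(seed = 6)
  pm <- delineate_patches(gen_soil_grid(cfg))
  s1 <- gen_resource_samples(pm, cfg, seed = 10)
  s2 <- gen_resource_samples(pm, cfg, seed = 10)
  expect_identical(s1, s2)
  expect_setequal(unique(s1$patch_id), seq_len(pm$n_patches))
  expect_true(all(table(s1$patch_id) == cfg$quadrats_per_patch))
  # zero noise CV -> identical records and downstream CV 0
  cfg0 <- synth_config(depth_cv = 0, swc_cv = 0, tc_cv = 0, tn_cv = 0,
                       seed = 6)
  s0 <- gen_resource_samples(pm, cfg0, seed = 10)
  expect_equal(unique(s0$SWC_pct), 17.17)
  cv0 <- heterogeneity_cv(s0, 1)
  expect_true(all(cv0[c("Sd_cm", "SWC_pct", "TC_gkg", "TN_gkg")] == 0))
})

test_that("sampled SWC recovers its lognormal targets (Monte Carlo)", {
  cfg <- synth_config(quadrats_per_patch = 1000, seed = 9)
  pm <- delineate_patches(soil_grid(matrix(5, 2, 2), 0.39))
  s <- gen_resource_samples(pm, cfg, seed = 9)
  expect_lt(abs(mean(s$SWC_pct) / 17.17 - 1), 0.05)
  expect_lt(abs((sd(s$SWC_pct) / mean(s$SWC_pct)) / 0.37 - 1), 0.15)
})

test_that("gen_communities: richness model, clipping, determinism", {
  tr <- gen_tree(40, seed = 1)
  # flat model: E[R] = 5 regardless of area
  set.seed(31)
  patches <- data.frame(patch_id = 1:150,
                        PA_m2 = exp(runif(150, log(0.2), log(60))))
  cfg <- synth_config(n_taxa = 40, richness_intercept = 5,
                      richness_slope = 0, seed = 2)
  comm <- gen_communities(patches, tr, cfg, seed = 2)
  expect_identical(comm, gen_communities(patches, tr, cfg, seed = 2))
  expect_true(all(comm >= 0) && all(comm == round(comm)))
  r <- rowSums(comm > 0)
  # mean of 150 Poisson(5) draws (clipped at 1): 3 SE tolerance
  expect_lt(abs(mean(r) - 5), 3 * sqrt(5 / 150) + 0.05)
  # out-of-range target is clipped with a warning
  cfg_neg <- synth_config(n_taxa = 40, richness_intercept = 0,
                          richness_slope = 1, seed = 2)
  tiny <- data.frame(patch_id = 1, PA_m2 = 0.15)
  expect_warning(c2 <- gen_communities(tiny, tr, cfg_neg, seed = 3),
                 "clipped")
  expect_gte(richness(c2[1, ]), 1)
})

test_that("richness increases with log area as configured", {
  tr <- gen_tree(98, seed = 5)
  set.seed(77)
  patches <- data.frame(patch_id = 1:100,
                        PA_m2 = 10^runif(100, log10(0.15), log10(67)))
  cfg <- synth_config(seed = 5)  # intercept 10, slope 8
  comm <- gen_communities(patches, tr, cfg, seed = 5)
  fit <- fit_loglinear(patches$PA_m2, rowSums(comm > 0))
  expect_gt(fit$slope, 0)
  expect_equal(fit$slope, 8, tolerance = 0.35)
})
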