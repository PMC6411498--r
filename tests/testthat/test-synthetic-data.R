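# Tube template generation, cohort construction with dose-graded atrophy,
# and the matched demographics generator.

test_that("template tube is closed genus zero with near-analytic volume", {
  tube <- make_template_tube(50, 30, length = 40, radius_profile = 5,
                             bend = 0, cross_aspect = 1)
  top <- check_topology(tube)
  expect_identical(top$euler, 2L)
  expect_true(top$closed)
  # volume of the inscribed 30-gon prism: pi r^2 L scaled by sinc(2 pi / n)
  analytic <- pi * 25 * 40
  expect_equal(mesh_volume(tube), analytic, tolerance = 0.03)
  # voxel-counting oracle agrees
  vox <- voxel_volume(rasterize_mesh(tube, voxel_size = 0.2))
  expect_equal(mesh_volume(tube), vox, tolerance = 0.03)
  # elliptic cross-sections preserve the cross-section area
  te <- make_template_tube(50, 30, length = 40, radius_profile = 5,
                           bend = 0, cross_aspect = 1.5)
  expect_equal(mesh_volume(te), mesh_volume(tube), tolerance = 0.01)
})

test_that("template generation is deterministic and validates inputs", {
  a <- make_template_tube(20, 12, jitter_sd = 0.1, seed = 5)
  b <- make_template_tube(20, 12, jitter_sd = 0.1, seed = 5)
  expect_identical(a$vertices, b$vertices)
  expect_error(make_template_tube(3, 12), ">= 4")
  expect_error(make_template_tube(10, 12, length = -1), "positive")
  expect_error(make_template_tube(10, 12, radius_profile = -2), "positive")
})

test_that("cohort_spec validates the dose structure", {
  expect_error(cohort_spec(group_sizes = c(NC = 1L, HT = 5L, HM = 5L)),
               "at least 2")
  expect_error(cohort_spec(effect_magnitudes = c(NC = 0.5, HT = 0.2, HM = 1)),
               "non-decreasing")
  expect_error(cohort_spec(patch_radius = -0.1), "> 0")
  expect_error(cohort_spec(vertex_noise_sd = -1), ">= 0")
  d <- cohort_spec()
  expect_identical(d$group_sizes, c(NC = 44L, HT = 36L, HM = 37L))
})

test_that("make_cohort produces valid meshes with recorded dose labels", {
  spec <- small_cohort_spec(seed = 4)
  co <- make_cohort(spec)
  expect_identical(length(co$meshes), 12L)
  expect_identical(table(co$labels)[["HM"]], 4L)
  tops <- lapply(co$meshes[c(1, 6, 12)], check_topology)
  for (tp in tops) {
    expect_identical(tp$euler, 2L)
    expect_true(tp$closed)
  }
  expect_true(any(co$truth_mask))
  # null cohorts carry no truth patch
  null_spec <- small_cohort_spec(
    effect_magnitudes = c(NC = 0, HT = 0, HM = 0), seed = 4)
  expect_false(any(make_cohort(null_spec)$truth_mask))
})

test_that("cohorts are reproducible from their seed", {
  s <- small_cohort_spec(seed = 99)
  a <- make_cohort(s)
  b <- make_cohort(s)
  expect_identical(a$meshes[[7]]$vertices, b$meshes[[7]]$vertices)
  expect_identical(a$labels, b$labels)
})

test_that("mean enclosed volumes order with the dose", {
  spec <- cohort_spec(group_sizes = c(NC = 6L, HT = 6L, HM = 6L),
                      effect_magnitudes = c(NC = 0, HT = 0.4, HM = 0.8),
                      patch_radius = 0.15,
                      template_args = list(n_rings = 30, n_around = 20),
                      seed = 12)
  co <- make_cohort(spec)
  vols <- vapply(co$meshes, mesh_volume, 1)
  m <- tapply(vols, co$labels, mean)
  expect_gte(m[["NC"]], m[["HT"]])
  expect_gte(m[["HT"]], m[["HM"]])
})

test_that("demographics generator is reproducible with requested moments", {
  d1 <- make_demographics(seed = 6)
  d2 <- make_demographics(seed = 6)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 117L)
  expect_identical(as.vector(table(d1$group)[c("NC", "HT", "HM")]),
                   c(44L, 36L, 37L))
  # moments in expectation: with 3-SD separated means ANOVA always rejects
  shifted <- default_demographic_distributions()
  shifted$age <- list(NC = c(50, 2), HT = c(56, 2), HM = c(62, 2))
  ps <- replicate(50, {
    dd <- make_demographics(c(NC = 15L, HT = 15L, HM = 15L), shifted,
                            seed = sample.int(1e6, 1))
    anova_from_raw(split(dd$age, dd$group))$p
  })
  expect_true(all(ps < 0.001))
  expect_error(make_demographics(
    distributions = utils::modifyList(default_demographic_distributions(),
                                      list(sex_male_prob = list(NC = 1.4,
                                                                HT = 0.3,
                                                                HM = 0.3)))),
    "probabilities")
})

test_that("identical group distributions keep the ANOVA at its nominal size", {
  set.seed(14)
  same <- default_demographic_distributions()
  for (v in c("age", "education", "mmse", "avlt_ltm"))
    same[[v]] <- list(NC = c(58, 6), HT = c(58, 6), HM = c(58, 6))
  ps <- replicate(500, {
    dd <- make_demographics(c(NC = 12L, HT = 12L, HM = 12L), same,
                            seed = sample.int(1e6, 1))
    anova_from_raw(split(dd$age, dd$group))$p
  })
  rate <- mean(ps < 0.05)
  # binomial 95% band around 0.05 at 500 replicates
  expect_gt(rate, 0.05 - 2 * sqrt(0.05 * 0.95 / 500) - 1e-9)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 500) + 1e-9)
})
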