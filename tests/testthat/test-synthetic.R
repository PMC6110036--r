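test_that("noise-free concentric section reproduces circle areas", {
  spec <- group_spec("toy", lumen_radius_mean = 1,
                     intima_thickness_mean = 0, media_thickness_mean = 1,
                     eccentricity = 0, cv = 0)
  set.seed(1)
  cs <- generate_section(spec, n_vertices = 128L)
  a_eel <- polygon_area(cs$eel)
  a_iel <- polygon_area(cs$iel)
  a_lum <- polygon_area(cs$lumen)
  expect_equal(a_eel, pi * 4, tolerance = 1e-3)
  expect_equal(a_iel, pi, tolerance = 1e-3)
  # zero intima: lumen boundary coincides with the IEL
  expect_identical(a_lum, a_iel)
  expect_false(cs$floor_applied)
})

test_that("hyperplastic sections keep the IEL strictly outside the lumen", {
  spec <- group_spec("model", lumen_radius_mean = 250,
                     intima_thickness_mean = 120, eccentricity = 0.5)
  set.seed(42)
  for (i in 1:20) {
    cs <- generate_section(spec)
    expect_gt(polygon_area(cs$iel), polygon_area(cs$lumen))
  }
})

test_that("nesting invariant holds across parameter space", {
  set.seed(99)
  specs <- list(
    group_spec("thin", lumen_radius_mean = 300, intima_thickness_mean = 5,
               cv = 0.15, eccentricity = 0.9),
    group_spec("thick", lumen_radius_mean = 200, intima_thickness_mean = 150,
               cv = 0.15, eccentricity = 0.5),
    group_spec("none", lumen_radius_mean = 350, intima_thickness_mean = 0,
               cv = 0.15))
  for (spec in specs) {
    for (i in 1:30) {
      cs <- generate_section(spec)
      a <- c(polygon_area(cs$lumen), polygon_area(cs$iel),
             polygon_area(cs$eel))
      expect_true(a[1] <= a[2] && a[2] <= a[3])
    }
  }
})

test_that("generated contours are simple polygons", {
  set.seed(7)
  spec <- group_spec("model", lumen_radius_mean = 250,
                     intima_thickness_mean = 120, cv = 0.15,
                     eccentricity = 0.7)
  for (i in 1:10) {
    cs <- generate_section(spec)
    # polygon_area(check = TRUE) errors on self-intersection
    expect_no_error(polygon_area(cs$eel, check = TRUE))
    expect_no_error(polygon_area(cs$lumen, check = TRUE))
  }
})

test_that("Monte-Carlo: mean lumen equivalent radius matches the spec", {
  spec <- group_spec("mc", lumen_radius_mean = 250,
                     intima_thickness_mean = 120, cv = 0.1)
  set.seed(2024)
  r_eq <- replicate(1000, sqrt(polygon_area(generate_section(spec)$lumen,
                                            check = FALSE) / pi))
  expect_lt(abs(mean(r_eq) / 250 - 1), 0.02)
})

test_that("cohort has the configured section count and sidecar", {
  groups <- lapply(paste0("g", 1:9), function(g)
    group_spec(g, n_animals = 8, intima_thickness_mean = 50))
  cfg <- cohort_config(groups, slices_per_vessel = 8, seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh$sections, 9 * 8 * 8)
  expect_named(coh$truth, paste0("g", 1:9))
  expect_equal(coh$truth$g3$intima_thickness_mean, 50)
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- default_cohort_config(n_animals = 2, seed = 11)
  t1 <- as_contour_table(generate_cohort(cfg))
  t2 <- as_contour_table(generate_cohort(cfg))
  expect_identical(t1, t2)
  cfg2 <- default_cohort_config(n_animals = 2, seed = 12)
  t3 <- as_contour_table(generate_cohort(cfg2))
  expect_false(isTRUE(all.equal(t1$x_um, t3$x_um)))
})

test_that("duplicate group labels are rejected", {
  expect_error(cohort_config(list(group_spec("a"), group_spec("a"))),
               "duplicate")
})

test_that("group_spec validates its invariants", {
  expect_error(group_spec("x", n_animals = 0), "n_animals")
  expect_error(group_spec("x", lumen_radius_mean = -1), "lumen_radius")
  expect_error(group_spec("x", intima_thickness_mean = -1), "intima")
  expect_error(group_spec("x", eccentricity = 1), "eccentricity")
  expect_error(group_spec("x", cv = -0.1), "cv")
})

test_that("contour table round-trips through sections", {
  cfg <- default_cohort_config(n_animals = 1, seed = 3)
  coh <- generate_cohort(cfg)
  tab <- as_contour_table(coh)
  back <- contour_table_to_sections(tab)
  expect_length(back, length(coh$sections))
  m1 <- compute_morphometry(coh)
  m2 <- compute_morphometry(back)
  data.table::setkey(m1, group, animal, slice)
  data.table::setkey(m2, group, animal, slice)
  expect_equal(m1$HRIA, m2$HRIA)
})

test_that("densitometry: unit effect and zero noise give relative expression 1", {
  cfg <- cohort_config(list(
    group_spec("g", n_animals = 3, cv = 0,
               expression_effects = c(prot = 1))), seed = 8)
  d <- generate_densitometry(cfg)
  s <- summarize_densitometry(d)
  wb <- s$animal[s$animal$kind == "WB", ]
  expect_equal(wb$value, rep(1, 3))
  expect_true(all(d$iod > 0))
})

test_that("densitometry recovers a 2x group effect (Monte-Carlo)", {
  cfg <- cohort_config(list(
    group_spec("normal", n_animals = 6, cv = 0.1,
               expression_effects = c(pcna = 1)),
    group_spec("model", n_animals = 6, cv = 0.1,
               expression_effects = c(pcna = 2))), seed = 2718)
  s <- summarize_densitometry(generate_densitometry(cfg))$group
  wb <- s[s$kind == "WB", ]
  ratio <- wb$mean[wb$group == "model"] / wb$mean[wb$group == "normal"]
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("unknown protein labels are named in the error", {
  cfg <- default_cohort_config(n_animals = 2, seed = 1)
  expect_error(generate_densitometry(cfg, proteins = "nonexistent"),
               "nonexistent")
})

test_that("write_cohort emits contours.csv and truth.json", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(default_cohort_config(n_animals = 1, seed = 4))
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$model$intima_thickness_mean,
               coh$truth$model$intima_thickness_mean)
})
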