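test_that("hyperuricemia classification is inclusive at the sex thresholds", {
  expect_true(classify_hyperuricemia(420, "male"))
  expect_true(classify_hyperuricemia(360, "female"))
  expect_false(classify_hyperuricemia(419.9, "male"))
  expect_false(classify_hyperuricemia(359.999, "female"))
  expect_error(classify_hyperuricemia(-1, "male"), "positive")
  # monotone in uric acid for fixed sex
  sua <- seq(100, 700, by = 7)
  for (s in c("male", "female"))
    expect_true(all(diff(classify_hyperuricemia(sua, s)) >= 0))
})

test_that("BMI classes use half-open bins at the printed cut points", {
  r <- classify_bmi(c(54, 63, 40, 42.1), c(1.5, 1.5, 1.5, 1.5))
  expect_equal(r$bmi, c(24, 28, 40 / 2.25, 42.1 / 2.25))
  expect_identical(as.character(r$bmi_class),
                   c("overweight", "obese", "underweight", "normal"))
  expect_error(classify_bmi(-1, 1.5), "positive")
  expect_error(classify_bmi(60, 0), "positive")
})

test_that("ATP-III flags, component count and health status line up", {
  r <- metabolic_health_atp3(sbp = 130, dbp = 70, tg = 1.7, fpg = 5.0,
                             hdl = 1.5, sex = "male")
  expect_identical(unlist(r[1, 1:4], use.names = FALSE),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$atp3_component_count, 2L)
  expect_false(r$metabolically_healthy_atp3)

  r0 <- metabolic_health_atp3(120, 70, 1.0, 5.0, 1.5, "male")
  expect_identical(r0$atp3_component_count, 0L)
  expect_true(r0$metabolically_healthy_atp3)

  # female HDL threshold is 1.3; a single abnormality is still healthy
  rf <- metabolic_health_atp3(120, 70, 1.0, 5.0, 1.25, "female")
  expect_true(rf$reduced_hdl)
  expect_identical(rf$atp3_component_count, 1L)
  expect_true(rf$metabolically_healthy_atp3)
  # ...but not with the stricter >= 3 configuration either way
  r3 <- metabolic_health_atp3(130, 90, 2.0, 6.0, 1.0, "male",
                              thresholds = phenotype_thresholds(
                                atp3_unhealthy_min = 3L))
  expect_identical(r3$atp3_component_count, 4L)
  expect_false(r3$metabolically_healthy_atp3)

  # drug flags substitute for the measured abnormality
  rd <- metabolic_health_atp3(120, 70, 1.0, 5.0, 1.5, "male",
                              antihypertensive_drug = 1L)
  expect_true(rd$elevated_bp)
  expect_error(metabolic_health_atp3(NA, 70, 1, 5, 1.5, "male"), "missing")

  # count always equals the popcount of the flags
  set.seed(4)
  n <- 200
  rr <- metabolic_health_atp3(runif(n, 90, 180), runif(n, 50, 110),
                              runif(n, 0.5, 4), runif(n, 3.5, 9),
                              runif(n, 0.5, 2.5),
                              sample(c("male", "female"), n, TRUE))
  expect_identical(rr$atp3_component_count, as.integer(rowSums(rr[, 1:4])))
  expect_identical(rr$metabolically_healthy_atp3, rr$atp3_component_count < 2L)
})

test_that("HOMA-IR follows the insulin x glucose / 22.5 formula", {
  expect_equal(compute_homa_ir(22.5, 1), 1)
  expect_equal(compute_homa_ir(10, 4.5), 2)
  expect_equal(compute_homa_ir(0, 5), 0)
  expect_error(compute_homa_ir(-1, 5), "non-negative")
  expect_error(compute_homa_ir(10, 0), "positive")
})

test_that("VAI evaluates the sex-specific formula and cuts at 1.59", {
  r <- metabolic_health_vai("male", wc = 84.95, bmi = 23.62, tg = 1.8,
                            hdl = 1.38)
  expect_equal(r$vai,
               (84.95 / (39.68 + 1.88 * 23.62)) * (1.8 / 1.03) *
                 (1.31 / 1.38))
  expect_equal(r$vai, 1.676, tolerance = 1e-3)
  expect_false(r$metabolically_healthy_vai)
  rf <- metabolic_health_vai("female", 80, 23, 1.2, 1.5)
  expect_equal(rf$vai,
               (80 / (36.58 + 1.89 * 23)) * (1.2 / 0.81) * (1.52 / 1.5))
  # health is the strict comparison vai < 1.59, verified near the boundary
  set.seed(9)
  n <- 500
  rr <- metabolic_health_vai(sample(c("male", "female"), n, TRUE),
                             runif(n, 60, 110), runif(n, 19, 32),
                             runif(n, 1.35, 1.75), runif(n, 0.9, 1.6))
  expect_identical(rr$metabolically_healthy_vai, rr$vai < 1.59)
  expect_true(any(rr$vai >= 1.59) && any(rr$vai < 1.59))
  expect_error(metabolic_health_vai("male", 0, 23, 1, 1.5), "positive")
})

test_that("phenotype assignment is a bijection over non-underweight cells", {
  expect_identical(as.character(assign_phenotype("normal", TRUE)), "MHNW")
  expect_identical(as.character(assign_phenotype("obese", FALSE)), "MUO")
  expect_identical(as.character(assign_phenotype("underweight", TRUE)),
                   "excluded")
  grid <- expand.grid(cls = c("normal", "overweight", "obese"),
                      healthy = c(TRUE, FALSE), stringsAsFactors = FALSE)
  got <- as.character(assign_phenotype(grid$cls, grid$healthy))
  expect_setequal(got, phenotype_levels())
  expect_identical(anyDuplicated(got), 0L)
  expect_error(assign_phenotype("tiny", TRUE), "unknown")
})

test_that("abdominal obesity uses inclusive, overridable waist cut-offs", {
  expect_true(abdominal_obesity(90, "male"))
  expect_false(abdominal_obesity(79.9, "female"))
  th <- phenotype_thresholds(wc = c(male = 85, female = 75))
  expect_true(abdominal_obesity(86, "male", th))
  expect_false(abdominal_obesity(86, "male"))  # default cut-off unchanged
  expect_error(abdominal_obesity(0, "male"), "positive")
})

test_that("phenotype_cohort derives a consistent augmented table", {
  coh <- minimal_cohort(500, seed = 21)
  ph <- phenotype_cohort(coh)
  expect_true(all(cohort_columns() %in% names(ph)))
  expect_identical(ph$phenotype == "excluded",
                   as.character(ph$bmi_class) == "underweight")
  expect_identical(ph$atp3_component_count,
                   as.integer(rowSums(ph[, c("elevated_bp", "elevated_tg",
                                             "elevated_fpg",
                                             "reduced_hdl")])))
  expect_true(all(ph$vai > 0))
  # VAI-based phenotyping swaps only the health axis
  pv <- phenotype_cohort(coh, health_criterion = "vai")
  expect_identical(as.character(pv$bmi_class), as.character(ph$bmi_class))
})
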