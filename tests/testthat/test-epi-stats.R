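test_that("Wilson interval matches the closed form and stays in [0, 1]", {
  # independent closed-form computation
  wilson <- function(k, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- k / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  r <- prevalence_ci(12, 142)
  expect_equal(r$p_hat, 12 / 142)
  expect_equal(c(r$ci_low, r$ci_high), wilson(12, 142), tolerance = 1e-12)
  # rounded to table precision: 8.5 (4.9-14.2)
  expect_equal(round(100 * c(r$p_hat, r$ci_low, r$ci_high), 1),
               c(8.5, 4.9, 14.2))

  z0 <- prevalence_ci(0, 10)
  expect_equal(z0$p_hat, 0)
  expect_equal(z0$ci_low, 0)
  h <- prevalence_ci(5, 10)
  expect_equal(h$ci_high - 0.5, 0.5 - h$ci_low, tolerance = 1e-12)

  for (k in c(0, 1, 7, 142)) {
    w <- prevalence_ci(k, 142)
    expect_true(w$ci_low >= 0 && w$ci_high <= 1 &&
                  w$ci_low <= w$p_hat && w$p_hat <= w$ci_high)
  }
  expect_error(prevalence_ci(5, 4), "k <= n")

  cp <- prevalence_ci(12, 142, method = "clopper-pearson")
  expect_true(cp$ci_low < 12 / 142 && cp$ci_high > 12 / 142)
})

test_that("descriptives report pooled t and uncorrected chi-square tests", {
  d <- data.frame(sex = rep(c("male", "female"), each = 100),
                  x = rep(c(1.5, 1.5), each = 100) + rep(0:3, 50),
                  flag = c(rep(c(0, 1), c(70, 30)), rep(c(0, 1), c(50, 50))))
  out <- describe_cohort(d, vars = c("x", "flag"))
  # identical continuous distributions: t = 0, p = 1
  xrow <- out[out$variable == "x", ]
  expect_equal(xrow$statistic, 0, tolerance = 1e-12)
  expect_equal(xrow$p_value, 1, tolerance = 1e-12)
  # 2x2 counts (30,70)/(50,50): uncorrected chi-square 50/6
  frow <- out[out$variable == "flag", ]
  expect_equal(frow$statistic, 200 * (30 * 50 - 70 * 50)^2 /
                 (100 * 100 * 80 * 120), tolerance = 1e-9)
  expect_equal(frow$statistic, 8.333, tolerance = 1e-3)
  expect_error(describe_cohort(d[d$sex == "male", ]), "two levels")
  expect_warning(describe_cohort(cbind(d, const = 1), vars = "const"),
                 "constant|variance")
})

test_that("logistic fit reproduces closed-form saturated estimates", {
  # single binary exposure, 20/100 events exposed vs 10/100 unexposed
  x <- rep(c(1, 0), each = 100)
  y <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(10, 90)))
  f <- fit_logistic(cbind(exposed = x), y)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients["exposed"]), log(2.25),
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients["(Intercept)"]), qlogis(0.1),
               tolerance = 1e-6)
  # intercept-only at event rate 0.25
  f0 <- fit_logistic(cbind(z = rnorm(80)), rep(c(1, 0), c(20, 60)))
  expect_equal(unname(f0$coefficients["(Intercept)"]), qlogis(0.25),
               tolerance = 0.5) # z is noise; only sanity
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), y), "collinear")
  sep <- fit_logistic(cbind(x = c(rep(0, 20), rep(1, 20))),
                      c(rep(0, 20), rep(1, 20)))
  expect_false(sep$converged)
  expect_match(sep$diagnostic, "separation")
  expect_error(odds_ratio_table(sep), "non-converged")
})

test_that("odds-ratio tables exponentiate Wald intervals", {
  x <- rep(c(1, 0), each = 100)
  y <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(10, 90)))
  f <- fit_logistic(cbind(exposed = x), y)
  o <- odds_ratio_table(f, "exposed")
  z <- qnorm(0.975)
  expect_equal(o$or, exp(o$estimate))
  expect_equal(o$ci_low, exp(o$estimate - z * o$se))
  expect_equal(o$ci_high, exp(o$estimate + z * o$se))
  # the worked coefficient example: 0.668 (SE 0.3315) -> 1.95 (1.02-3.74)
  expect_equal(exp(0.668), 1.95, tolerance = 5e-3)
  expect_equal(exp(0.668 - z * 0.3315), 1.02, tolerance = 5e-3)
  expect_equal(exp(0.668 + z * 0.3315), 3.74, tolerance = 5e-3)
})

test_that("OR point estimates are invariant to scaling of adjusters", {
  set.seed(31)
  n <- 4000
  x <- rbinom(n, 1, 0.3)
  age <- rnorm(n, 50, 10)
  y <- rbinom(n, 1, plogis(-2 + 0.5 * x + 0.01 * age))
  f1 <- fit_logistic(cbind(x = x, age = age), y)
  f2 <- fit_logistic(cbind(x = x, age = (age - 50) / 10), y)
  expect_equal(unname(f1$coefficients["x"]), unname(f2$coefficients["x"]),
               tolerance = 1e-8)
})

test_that("association models return the full stratum x model x phenotype grid", {
  ph <- phenotype_cohort(sample_cohort(generator_spec(6000, seed = 3)))
  tab <- run_association_models(ph)
  expect_identical(nrow(tab), 6L * 3L * 2L)
  ref <- tab[tab$phenotype == "MHNW", ]
  expect_true(all(ref$or == 1) && all(ref$reference))
  expect_setequal(unique(tab$stratum), c("total", "men", "women"))
  # a women-only table carries no sex term: refitting women manually with
  # the same design must reproduce the packaged estimates
  w <- ph[ph$sex == "female" & ph$phenotype != "excluded", ]
  phen <- factor(as.character(w$phenotype), levels = phenotype_levels())
  fit <- glm(hyperuricemia ~ phen + age + urban + smoker + alcohol,
             family = binomial(), data = w)
  expect_false("sex" %in% names(coef(fit)))
  got <- tab[tab$stratum == "women" & tab$model == 1 &
               tab$phenotype == "MUO", "or"]
  expect_equal(got, unname(exp(coef(fit)["phenMUO"])), tolerance = 1e-6)
})

test_that("backward AIC selection keeps signal and drops pure noise", {
  set.seed(77)
  ph <- phenotype_cohort(sample_cohort(generator_spec(5000, seed = 8)))
  ph$noise1 <- rnorm(nrow(ph))
  ph$noise2 <- rnorm(nrow(ph))
  sel <- stepwise_select(ph, c("age", "noise1", "noise2"))
  # phenotype drives hyperuricemia in the generator; the block survives
  expect_true("phenotype" %in% sel$retained)
  # a candidate equal to the outcome's generator is always retained
  ph$driver <- as.numeric(ph$uric_acid)
  sel2 <- stepwise_select(ph, c("driver", "noise1"))
  expect_true("driver" %in% sel2$retained)
  # deterministic under a fixed input order
  sel3 <- stepwise_select(ph, c("age", "noise1", "noise2"))
  expect_identical(sel$retained, sel3$retained)
})
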