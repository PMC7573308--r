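## Synthetic CHNS-like cohorts.  The generator emulates the marginal and
## conditional structure the analysis assumes: sex ratio, the six-way
## phenotype distribution per sex, and phenotype/sex-conditional
## hyperuricemia prevalence, with all remaining covariates drawn from
## plausible sex-conditional laws.  Serum uric acid follows a sex-specific
## log-normal whose location is calibrated by bisection so that the tail
## mass above the sex threshold equals the requested prevalence cell.

.default_phenotype_probs <- function() {
  m <- cbind(
    male   = c(43.05, 16.96, 2.66, 14.89, 16.03, 6.41),
    female = c(42.97, 17.67, 3.60, 15.31, 13.43, 7.02)) / 100
  rownames(m) <- phenotype_levels()
  m
}

.default_hyperuricemia_prev <- function() {
  m <- cbind(
    male   = c(11.4, 16.6, 15.4, 23.6, 39.4, 38.4),
    female = c(4.0, 5.5, 8.5, 18.7, 23.0, 30.7)) / 100
  rownames(m) <- phenotype_levels()
  m
}

.default_covariate_models <- function() {
  list(
    age = list(mean = 50.3, sd = 14.45, lo = 18, hi = 95),
    height_m = list(mean = c(male = 1.6704, female = 1.5591),
                    sd = c(male = 0.066, female = 0.064),
                    lo = 1.35, hi = 2.05),
    bmi_by_class = list(
      normal = list(mean = 21.8, sd = 1.6),
      overweight = list(mean = 25.6, sd = 1.1),
      obese = list(mean = 29.6, sd = 1.5, hi = 45)),
    waist = list(intercept = c(male = 28.3, female = 22.6),
                 slope = 2.4, sd = 4, lo = 45),
    flag_count = list(healthy = c(`0` = 0.55, `1` = 0.45),
                      unhealthy = c(`2` = 0.6, `3` = 0.3, `4` = 0.1)),
    flag_weights = cbind(male = c(bp = 0.46, tg = 0.36, fpg = 0.26,
                                  hdl = 0.18),
                         female = c(bp = 0.38, tg = 0.30, fpg = 0.23,
                                    hdl = 0.33)),
    sbp = list(mean_hi = 145, sd_hi = 12, mean_lo = 117, sd_lo = 8, lo = 80,
               hi = 220),
    dbp = list(mean = 79, sd = 8, lo = 50, hi = 130),
    tg = list(meanlog_hi = log(2.5), sdlog_hi = 0.35,
              meanlog_lo = log(1.05), sdlog_lo = 0.35),
    fpg = list(mean_hi = 6.6, sd_hi = 1.3, mean_lo = 5.0, sd_lo = 0.45,
               lo = 3.0, hi = 25),
    hdl = list(mean = c(male = 1.38, female = 1.47),
               sd = 0.35, lo = 0.4, hi = 4),
    ldl = list(mean = c(male = 2.94, female = 3.05), sd = 0.97, lo = 0.5,
               hi = 8),
    tc = list(mean = c(male = 4.83, female = 4.92), sd = 1.0, lo = 2.2,
              hi = 12),
    fasting_insulin = list(meanlog = log(11), sdlog = 0.6),
    hs_crp = list(meanlog = log(1.1), sdlog = 0.9),
    white_blood_cell = list(mean = 6.3, sd = 1.6, lo = 2, hi = 18),
    smoker = c(male = 0.62, female = 0.038),
    alcohol = c(male = 0.611, female = 0.087),
    urban = 0.683,
    diabetes_by_phenotype = c(MHNW = 0.02, MHOW = 0.03, MHO = 0.04,
                              MUNW = 0.08, MUOW = 0.10, MUO = 0.14),
    drug_given_flag = c(antihypertensive = 0.15, lipid = 0.05,
                        diabetes = 0.5),
    uric_sdlog = c(male = 0.30, female = 0.29),
    uric_meanlog_marginal = c(male = log(340), female = log(255)))
}

#' Specification for the synthetic-cohort generator
#'
#' Collects every generator parameter: cohort size, female fraction, the
#' six-way phenotype distribution per sex, the per-(phenotype, sex)
#' hyperuricemia prevalence targets, the covariate sampling laws, and the
#' master seed.  On construction the uric-acid location parameters are
#' calibrated by bisection so each stratum's analytic prevalence matches its
#' target cell.  The defaults encode the marginal structure reported for the
#' 2009 CHNS-based study population (53.6% female, the published phenotype
#' shares and stratum prevalences).
#'
#' @param n_subjects cohort size (>= 1).
#' @param female_fraction probability a record is female.
#' @param phenotype_probs_by_sex 6 x 2 matrix (rows MHNW...MUO, columns
#'   male/female); each column must sum to 1 within 1e-9.
#' @param hyperuricemia_prev_by_phenotype_sex 6 x 2 matrix of prevalences in
#'   (0, 1).
#' @param covariate_models per-field sampling laws; see the package source
#'   for the block structure.  Only entries supplied are overridden.
#' @param or_model optional list(`baseline_p`, `log_or`) switching the
#'   outcome law to a logistic model on phenotype: hyperuricemia is drawn
#'   with log-odds `qlogis(baseline_p) + log_or[phenotype]` and uric acid is
#'   then drawn consistently above/below the sex threshold.
#' @param seed master integer seed; per-field streams are derived from it so
#'   draws do not shift when unrelated fields change.
#' @return a validated object of class `uric_generator_spec`.
#' @export
generator_spec <- function(n_subjects = 10000L,
                           female_fraction = 0.536,
                           phenotype_probs_by_sex = NULL,
                           hyperuricemia_prev_by_phenotype_sex = NULL,
                           covariate_models = NULL,
                           or_model = NULL,
                           seed = 1L) {
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    female_fraction = female_fraction,
    phenotype_probs_by_sex =
      if (is.null(phenotype_probs_by_sex)) .default_phenotype_probs()
      else phenotype_probs_by_sex,
    hyperuricemia_prev_by_phenotype_sex =
      if (is.null(hyperuricemia_prev_by_phenotype_sex))
        .default_hyperuricemia_prev()
      else hyperuricemia_prev_by_phenotype_sex,
    covariate_models =
      if (is.null(covariate_models)) .default_covariate_models()
      else modifyList(.default_covariate_models(), covariate_models),
    or_model = or_model,
    seed = as.integer(seed)), class = "uric_generator_spec")
  validate_generator_spec(spec)
  spec$uric_meanlog <- .calibrate_all_strata(spec)
  spec
}

#' @rdname generator_spec
#' @param spec a `uric_generator_spec`.
#' @export
validate_generator_spec <- function(spec) {
  if (is.na(spec$n_subjects) || spec$n_subjects < 1L)
    stop("invalid 'n_subjects': must be a count >= 1")
  p <- spec$female_fraction
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop("invalid 'female_fraction': must be a probability in [0, 1]")
  pp <- spec$phenotype_probs_by_sex
  if (!is.matrix(pp) || !identical(dim(pp), c(6L, 2L)) ||
      any(pp < 0) || any(pp > 1))
    stop("invalid 'phenotype_probs_by_sex': need a 6 x 2 probability matrix")
  if (any(abs(colSums(pp) - 1) > 1e-9))
    stop("invalid 'phenotype_probs_by_sex': columns must sum to 1")
  hp <- spec$hyperuricemia_prev_by_phenotype_sex
  if (!is.matrix(hp) || !identical(dim(hp), c(6L, 2L)) ||
      any(hp <= 0) || any(hp >= 1))
    stop("invalid 'hyperuricemia_prev_by_phenotype_sex': ",
         "cells must be probabilities in (0, 1)")
  if (!is.null(spec$or_model)) {
    om <- spec$or_model
    if (!is.list(om) || is.null(om$baseline_p) || is.null(om$log_or) ||
        om$baseline_p <= 0 || om$baseline_p >= 1 ||
        !all(phenotype_levels() %in% names(om$log_or)))
      stop("invalid 'or_model': need baseline_p in (0,1) and log_or named ",
           "for all six phenotypes")
  }
  invisible(spec)
}

.sex_threshold <- function(sex) {
  phenotype_thresholds()$sua[sex]
}

.calibrate_all_strata <- function(spec, tol = 1e-8) {
  sdlog <- spec$covariate_models$uric_sdlog
  m <- spec$hyperuricemia_prev_by_phenotype_sex
  out <- m * NA_real_
  for (sex in colnames(m))
    for (ph in rownames(m))
      out[ph, sex] <- .bisect_meanlog(m[ph, sex], .sex_threshold(sex),
                                      sdlog[[sex]], tol)
  out
}

.bisect_meanlog <- function(target, threshold, sdlog, tol) {
  tail_mass <- function(mu) plnorm(threshold, mu, sdlog, lower.tail = FALSE)
  lo <- hi <- log(threshold)
  step <- 1
  for (i in seq_len(100L)) {
    if (tail_mass(lo) < target) break
    lo <- lo - step; step <- step * 2
  }
  if (tail_mass(lo) >= target) stop("calibration failure: no lower bracket")
  step <- 1
  for (i in seq_len(100L)) {
    if (tail_mass(hi) > target) break
    hi <- hi + step; step <- step * 2
  }
  if (tail_mass(hi) <= target) stop("calibration failure: no upper bracket")
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (abs(tail_mass(mid) - target) <= tol) return(mid)
    if (tail_mass(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate one stratum's hyperuricemia prevalence
#'
#' Adjusts the uric-acid log-normal location parameter of one
#' (phenotype, sex) stratum by bisection so that the analytic tail mass
#' above the sex-specific threshold is within `tol` of `target`.  The tail
#' mass is strictly increasing in the location, which guarantees bisection
#' converges once a bracket is found (brackets are expanded by doubling, at
#' most 100 times).
#'
#' @param spec a [generator_spec()].
#' @param stratum length-2 character vector `c(phenotype, sex)`.
#' @param target desired prevalence, strictly inside (0, 1).
#' @param tol calibration tolerance on the prevalence scale.
#' @return the spec with the stratum's location recalibrated and its target
#'   cell updated.
#' @export
calibrate_prevalence <- function(spec, stratum, target, tol = 1e-8) {
  validate_generator_spec(spec)
  if (!is.numeric(target) || target <= 0 || target >= 1)
    stop("degenerate target: prevalence must be strictly inside (0, 1)")
  ph <- match.arg(stratum[[1L]], phenotype_levels())
  sex <- match.arg(stratum[[2L]], c("male", "female"))
  spec$hyperuricemia_prev_by_phenotype_sex[ph, sex] <- target
  spec$uric_meanlog[ph, sex] <- .bisect_meanlog(
    target, .sex_threshold(sex), spec$covariate_models$uric_sdlog[[sex]],
    tol)
  spec
}

#' Analytic hyperuricemia prevalence implied by a spec
#'
#' @inheritParams calibrate_prevalence
#' @return the log-normal tail mass above the sex threshold for the stratum.
#' @export
implied_prevalence <- function(spec, stratum) {
  ph <- match.arg(stratum[[1L]], phenotype_levels())
  sex <- match.arg(stratum[[2L]], c("male", "female"))
  unname(plnorm(.sex_threshold(sex), spec$uric_meanlog[ph, sex],
                spec$covariate_models$uric_sdlog[[sex]],
                lower.tail = FALSE))
}

## inverse-CDF truncated normal / log-normal draws
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

.rtlnorm <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- plnorm(lo, meanlog, sdlog); phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

#' Sample a synthetic cohort
#'
#' Draws `n_subjects` records: sex, then the six-way phenotype given sex,
#' then anthropometric and biochemical covariates consistent with the
#' phenotype label (BMI inside its class bin; a number of abnormal ATP-III
#' components compatible with the metabolic-health label, with component
#' values truncated at their thresholds accordingly; drug flags only among
#' threshold-abnormal subjects), and finally uric acid from the calibrated
#' sex/phenotype-conditional log-normal — so re-deriving the phenotype from
#' the raw columns reproduces the generating label, and each stratum's
#' hyperuricemia probability equals its spec cell.  One master seed is
#' split into per-field streams; identical specs give byte-identical tables.
#'
#' @param spec a [generator_spec()].
#' @return a cohort data frame (one row per subject, columns as documented
#'   in [read_cohort()]).
#' @export
sample_cohort <- function(spec) {
  validate_generator_spec(spec)
  n <- spec$n_subjects
  cm <- spec$covariate_models
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 32L)
  draw <- local({
    i <- 0L
    function(expr) {
      i <<- i + 1L
      set.seed(streams[i])
      expr
    }
  })

  sex <- draw(ifelse(runif(n) < spec$female_fraction, "female", "male"))
  phen <- draw({
    out <- character(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      cum <- cumsum(spec$phenotype_probs_by_sex[, s])
      cum[6L] <- 1
      u <- runif(sum(idx))
      out[idx] <- phenotype_levels()[findInterval(u, cum,
                                                  left.open = TRUE) + 1L]
    }
    out
  })
  healthy <- phen %in% c("MHNW", "MHOW", "MHO")
  bclass <- c(MHNW = "normal", MHOW = "overweight", MHO = "obese",
              MUNW = "normal", MUOW = "overweight", MUO = "obese")[phen]

  age <- draw(.rtnorm(n, cm$age$mean, cm$age$sd, cm$age$lo, cm$age$hi))
  height <- draw(.rtnorm(n, cm$height_m$mean[sex], cm$height_m$sd[sex],
                         cm$height_m$lo, cm$height_m$hi))
  bb <- phenotype_thresholds()$bmi
  bmi <- draw({
    out <- numeric(n)
    eps <- 1e-9
    for (cl in c("normal", "overweight", "obese")) {
      idx <- bclass == cl
      par <- cm$bmi_by_class[[cl]]
      bounds <- switch(cl,
        normal = c(bb[["underweight"]], bb[["overweight"]] - eps),
        overweight = c(bb[["overweight"]], bb[["obese"]] - eps),
        obese = c(bb[["obese"]], par$hi))
      out[idx] <- .rtnorm(sum(idx), par$mean, par$sd, bounds[1L], bounds[2L])
    }
    out
  })
  weight <- bmi * height^2
  waist <- draw(pmax(cm$waist$lo,
                     cm$waist$intercept[sex] + cm$waist$slope * bmi +
                       rnorm(n, 0, cm$waist$sd)))

  ## number of abnormal ATP-III components compatible with health status
  count <- draw({
    out <- integer(n)
    for (h in c(TRUE, FALSE)) {
      idx <- healthy == h
      pr <- if (h) cm$flag_count$healthy else cm$flag_count$unhealthy
      cum <- cumsum(pr)
      cum[length(cum)] <- 1
      u <- runif(sum(idx))
      vals <- as.integer(names(pr))
      out[idx] <- vals[findInterval(u, cum, left.open = TRUE) + 1L]
    }
    out
  })
  ## which components: exponential-race weighted sampling without
  ## replacement, vectorized over records (rank_j = 1 + #{l: key_l < key_j})
  flags <- draw({
    w <- t(cm$flag_weights[, sex])
    keys <- matrix(stats::rexp(n * 4L), n, 4L) / w
    rk <- matrix(1L, n, 4L)
    for (j in 1:4) for (l in 1:4) if (l != j)
      rk[, j] <- rk[, j] + (keys[, l] < keys[, j])
    rk <= count
  })
  colnames(flags) <- c("bp", "tg", "fpg", "hdl")

  t3 <- phenotype_thresholds()$atp3
  eps <- 1e-9
  sbp <- draw(ifelse(flags[, "bp"],
                     .rtnorm(n, cm$sbp$mean_hi, cm$sbp$sd_hi, t3$sbp,
                             cm$sbp$hi),
                     .rtnorm(n, cm$sbp$mean_lo, cm$sbp$sd_lo, cm$sbp$lo,
                             t3$sbp - eps)))
  dbp <- draw(ifelse(flags[, "bp"],
                     .rtnorm(n, cm$dbp$mean + 6, cm$dbp$sd, cm$dbp$lo,
                             cm$dbp$hi),
                     .rtnorm(n, cm$dbp$mean, cm$dbp$sd, cm$dbp$lo,
                             t3$dbp - eps)))
  tg <- draw(ifelse(flags[, "tg"],
                    .rtlnorm(n, cm$tg$meanlog_hi, cm$tg$sdlog_hi, t3$tg),
                    .rtlnorm(n, cm$tg$meanlog_lo, cm$tg$sdlog_lo, 0.1,
                             t3$tg - eps)))
  fpg <- draw(ifelse(flags[, "fpg"],
                     .rtnorm(n, cm$fpg$mean_hi, cm$fpg$sd_hi, t3$fpg,
                             cm$fpg$hi),
                     .rtnorm(n, cm$fpg$mean_lo, cm$fpg$sd_lo, cm$fpg$lo,
                             t3$fpg - eps)))
  hdl_thr <- t3$hdl[sex]
  hdl <- draw(ifelse(flags[, "hdl"],
                     .rtnorm(n, cm$hdl$mean[sex] - 0.35, cm$hdl$sd,
                             cm$hdl$lo, hdl_thr - eps),
                     .rtnorm(n, cm$hdl$mean[sex], cm$hdl$sd, hdl_thr,
                             cm$hdl$hi)))

  diabetes <- draw(as.integer(runif(n) <
                                cm$diabetes_by_phenotype[phen]))
  dgf <- cm$drug_given_flag
  drug <- draw(cbind(
    antihypertensive_drug = as.integer(flags[, "bp"] &
                                         runif(n) < dgf[["antihypertensive"]]),
    lipid_drug = as.integer(flags[, "tg"] & runif(n) < dgf[["lipid"]]),
    diabetes_drug = as.integer(flags[, "fpg"] & diabetes == 1L &
                                 runif(n) < dgf[["diabetes"]])))

  sdlog <- cm$uric_sdlog[sex]
  if (is.null(spec$or_model)) {
    uric <- draw(rlnorm(n, spec$uric_meanlog[cbind(phen, sex)], sdlog))
  } else {
    om <- spec$or_model
    eta <- qlogis(om$baseline_p) + om$log_or[phen]
    hu <- draw(as.integer(runif(n) < plogis(eta)))
    thr <- .sex_threshold(sex)
    mu <- cm$uric_meanlog_marginal[sex]
    uric <- draw(ifelse(hu == 1L,
                        .rtlnorm(n, mu, sdlog, lo = thr),
                        .rtlnorm(n, mu, sdlog, lo = 0, hi = thr - 1e-9)))
  }

  ldl <- draw(.rtnorm(n, cm$ldl$mean[sex], cm$ldl$sd, cm$ldl$lo, cm$ldl$hi))
  tc <- draw(.rtnorm(n, cm$tc$mean[sex], cm$tc$sd, cm$tc$lo, cm$tc$hi))
  insulin <- draw(rlnorm(n, cm$fasting_insulin$meanlog,
                         cm$fasting_insulin$sdlog))
  hs_crp <- draw(rlnorm(n, cm$hs_crp$meanlog, cm$hs_crp$sdlog))
  wbc <- draw(.rtnorm(n, cm$white_blood_cell$mean, cm$white_blood_cell$sd,
                      cm$white_blood_cell$lo, cm$white_blood_cell$hi))
  smoker <- draw(as.integer(runif(n) < cm$smoker[sex]))
  alcohol <- draw(as.integer(runif(n) < cm$alcohol[sex]))
  urban <- draw(as.integer(runif(n) < cm$urban))

  data.frame(
    id = seq_len(n), sex = sex, age = age, weight = weight, height = height,
    waist_circumference = waist, sbp = sbp, dbp = dbp, fpg = fpg, tg = tg,
    hdl_c = hdl, ldl_c = ldl, tc = tc, uric_acid = uric,
    fasting_insulin = insulin, hs_crp = hs_crp, white_blood_cell = wbc,
    smoker = smoker, alcohol = alcohol, urban = urban, diabetes = diabetes,
    antihypertensive_drug = drug[, "antihypertensive_drug"],
    lipid_drug = drug[, "lipid_drug"],
    diabetes_drug = drug[, "diabetes_drug"],
    row.names = NULL)
}
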