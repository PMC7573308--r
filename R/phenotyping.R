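#' Default clinical thresholds for phenotype derivation
#'
#' All cut-offs used when deriving categorical variables from raw
#' measurements, collected in one overridable list:
#' \itemize{
#'   \item `sua`: hyperuricemia thresholds, µmol/L (>= 420 men, >= 360
#'     women, inclusive).
#'   \item `bmi`: BMI class bounds, kg/m² (underweight < 18.5; normal
#'     18.5–23.9; overweight 24.0–27.9; obese >= 28.0 — the cut points
#'     recommended for Chinese adults).
#'   \item `atp3`: ATP-III component thresholds — SBP >= 130 or DBP >= 85
#'     mmHg (or antihypertensive drugs); TG >= 1.7 mmol/L (or lipid-lowering
#'     drugs); FPG >= 5.6 mmol/L (or diabetes medication); HDL-C < 1.04
#'     mmol/L men / < 1.3 mmol/L women.
#'   \item `atp3_unhealthy_min`: number of abnormal components at which a
#'     subject counts as metabolically unhealthy (default 2; see Details).
#'   \item `vai`: VAI threshold, metabolically healthy iff VAI < 1.59.
#'   \item `wc`: abdominal-obesity waist cut-offs, cm (>= 90 men / >= 80
#'     women, inclusive; config-overridable as the criterion varies across
#'     guidelines).
#' }
#'
#' @details The ATP-III metabolic-syndrome convention, with the waist
#'   criterion dropped for collinearity with BMI, labels a subject unhealthy
#'   at two or more of the four remaining abnormalities; set
#'   `atp3_unhealthy_min = 3` for the stricter reading.  All comparisons are
#'   made at full floating precision.
#'
#' @param ... named overrides of any of the entries above (partial lists are
#'   merged into the defaults).
#' @return a named list of thresholds.
#' @export
phenotype_thresholds <- function(...) {
  defaults <- list(
    sua = c(male = 420, female = 360),
    bmi = c(underweight = 18.5, overweight = 24.0, obese = 28.0),
    atp3 = list(sbp = 130, dbp = 85, tg = 1.7, fpg = 5.6,
                hdl = c(male = 1.04, female = 1.3)),
    atp3_unhealthy_min = 2L,
    vai = 1.59,
    wc = c(male = 90, female = 80))
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  defaults
}

.check_sex <- function(sex, n = NULL) {
  sex <- as.character(sex)
  if (!is.null(n) && length(sex) == 1L) sex <- rep(sex, n)
  if (any(!sex %in% c("male", "female")))
    stop("'sex' must be \"male\" or \"female\"")
  sex
}

#' Classify hyperuricemia from serum uric acid
#'
#' Hyperuricemia is serum uric acid at or above the sex-specific threshold
#' (420 µmol/L in men, 360 µmol/L in women; inclusive).
#'
#' @param sua serum uric acid, µmol/L (> 0).
#' @param sex `"male"`/`"female"`, recycled to the length of `sua`.
#' @param thresholds a [phenotype_thresholds()] list.
#' @return logical vector.
#' @export
classify_hyperuricemia <- function(sua, sex,
                                   thresholds = phenotype_thresholds()) {
  if (any(!is.finite(sua)) || any(sua <= 0))
    stop("'sua' must be strictly positive")
  sex <- .check_sex(sex, length(sua))
  sua >= thresholds$sua[sex]
}

#' BMI and BMI class
#'
#' BMI is weight (kg) over height (m) squared; classes use half-open bins
#' \eqn{[18.5, 24)} normal, \eqn{[24, 28)} overweight, \eqn{[28, \infty)}
#' obese, with BMI below 18.5 labeled underweight.
#'
#' @param weight kg (> 0).
#' @param height m (> 0).
#' @param thresholds a [phenotype_thresholds()] list.
#' @return data frame with columns `bmi` and `bmi_class` (ordered factor
#'   underweight < normal < overweight < obese).
#' @export
classify_bmi <- function(weight, height,
                         thresholds = phenotype_thresholds()) {
  if (any(!is.finite(weight)) || any(weight <= 0) ||
      any(!is.finite(height)) || any(height <= 0))
    stop("'weight' and 'height' must be strictly positive")
  bmi <- weight / height^2
  b <- thresholds$bmi
  cls <- cut(bmi, breaks = c(-Inf, b[["underweight"]], b[["overweight"]],
                             b[["obese"]], Inf),
             labels = c("underweight", "normal", "overweight", "obese"),
             right = FALSE, ordered_result = TRUE)
  data.frame(bmi = bmi, bmi_class = cls)
}

#' ATP-III metabolic-health assessment
#'
#' Flags the four ATP-III components (waist excluded): elevated blood
#' pressure, elevated triglycerides, elevated fasting glucose, reduced HDL-C
#' — each true when its threshold is met or the matching drug flag is set.
#' A subject is metabolically healthy when fewer than
#' `thresholds$atp3_unhealthy_min` components are abnormal.
#'
#' @param sbp,dbp blood pressure, mmHg.
#' @param tg triglycerides, mmol/L.
#' @param fpg fasting plasma glucose, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param sex `"male"`/`"female"`.
#' @param antihypertensive_drug,lipid_drug,diabetes_drug 0/1 medication
#'   flags (default none).
#' @param thresholds a [phenotype_thresholds()] list.
#' @return data frame with logical columns `elevated_bp`, `elevated_tg`,
#'   `elevated_fpg`, `reduced_hdl`, integer `atp3_component_count`, and
#'   logical `metabolically_healthy_atp3`.
#' @export
metabolic_health_atp3 <- function(sbp, dbp, tg, fpg, hdl, sex,
                                  antihypertensive_drug = 0L,
                                  lipid_drug = 0L, diabetes_drug = 0L,
                                  thresholds = phenotype_thresholds()) {
  args <- list(sbp = sbp, dbp = dbp, tg = tg, fpg = fpg, hdl = hdl)
  for (nm in names(args))
    if (any(is.na(args[[nm]])))
      stop("missing values in '", nm, "'")
  sex <- .check_sex(sex, length(sbp))
  t3 <- thresholds$atp3
  flags <- data.frame(
    elevated_bp = sbp >= t3$sbp | dbp >= t3$dbp | antihypertensive_drug > 0,
    elevated_tg = tg >= t3$tg | lipid_drug > 0,
    elevated_fpg = fpg >= t3$fpg | diabetes_drug > 0,
    reduced_hdl = hdl < t3$hdl[sex])
  flags$atp3_component_count <- as.integer(rowSums(flags))
  flags$metabolically_healthy_atp3 <-
    flags$atp3_component_count < thresholds$atp3_unhealthy_min
  flags
}

#' HOMA-IR insulin-resistance index
#'
#' `HOMA-IR = fasting insulin (µIU/mL) x FPG (mmol/L) / 22.5`.
#'
#' @param insulin fasting insulin, µIU/mL (>= 0).
#' @param fpg fasting plasma glucose, mmol/L (> 0).
#' @return numeric vector.
#' @export
compute_homa_ir <- function(insulin, fpg) {
  if (any(!is.finite(insulin)) || any(insulin < 0))
    stop("'insulin' must be non-negative")
  if (any(!is.finite(fpg)) || any(fpg <= 0))
    stop("'fpg' must be strictly positive")
  insulin * fpg / 22.5
}

#' Visceral Adiposity Index and VAI-based metabolic health
#'
#' Sex-specific VAI:
#' males \eqn{(WC / (39.68 + 1.88\,BMI)) (TG/1.03) (1.31/HDL)},
#' females \eqn{(WC / (36.58 + 1.89\,BMI)) (TG/0.81) (1.52/HDL)}.
#' Metabolically healthy iff VAI < 1.59 (strict).
#'
#' @param sex `"male"`/`"female"`.
#' @param wc waist circumference, cm (> 0).
#' @param bmi kg/m² (> 0).
#' @param tg triglycerides, mmol/L (> 0).
#' @param hdl HDL cholesterol, mmol/L (> 0).
#' @param thresholds a [phenotype_thresholds()] list.
#' @return data frame with columns `vai` and logical
#'   `metabolically_healthy_vai`.
#' @export
metabolic_health_vai <- function(sex, wc, bmi, tg, hdl,
                                 thresholds = phenotype_thresholds()) {
  for (x in list(wc, bmi, tg, hdl))
    if (any(!is.finite(x)) || any(x <= 0))
      stop("'wc', 'bmi', 'tg' and 'hdl' must be strictly positive")
  sex <- .check_sex(sex, length(wc))
  male <- sex == "male"
  vai <- ifelse(male,
                (wc / (39.68 + 1.88 * bmi)) * (tg / 1.03) * (1.31 / hdl),
                (wc / (36.58 + 1.89 * bmi)) * (tg / 0.81) * (1.52 / hdl))
  data.frame(vai = vai, metabolically_healthy_vai = vai < thresholds$vai)
}

#' Six-way metabolic-obesity phenotype
#'
#' Cross-classifies BMI class and metabolic health into MHNW, MHOW, MHO,
#' MUNW, MUOW, MUO; underweight subjects are labeled `excluded` (the
#' phenotype taxonomy starts at BMI 18.5) and should be dropped from
#' phenotype-stratified outputs.
#'
#' @param bmi_class factor/character in underweight/normal/overweight/obese.
#' @param healthy logical metabolic-health indicator.
#' @return factor with levels MHNW, MHOW, MHO, MUNW, MUOW, MUO, excluded.
#' @export
assign_phenotype <- function(bmi_class, healthy) {
  bmi_class <- as.character(bmi_class)
  ok <- c("underweight", "normal", "overweight", "obese")
  if (any(!bmi_class %in% ok))
    stop("unknown BMI class value(s)")
  map <- c(normal = "NW", overweight = "OW", obese = "O")
  out <- ifelse(bmi_class == "underweight", "excluded",
                paste0(ifelse(healthy, "MH", "MU"), map[bmi_class]))
  factor(out, levels = phenotype_levels(TRUE))
}

#' Phenotype level sets
#'
#' @param with_excluded include the `excluded` (underweight) label.
#' @return character vector of phenotype labels in canonical order.
#' @export
phenotype_levels <- function(with_excluded = FALSE) {
  lv <- c("MHNW", "MHOW", "MHO", "MUNW", "MUOW", "MUO")
  if (with_excluded) c(lv, "excluded") else lv
}

#' Abdominal obesity from waist circumference
#'
#' Waist at or above the sex-specific cut-off (default 90 cm men / 80 cm
#' women, inclusive).
#'
#' @param wc waist circumference, cm (> 0).
#' @param sex `"male"`/`"female"`.
#' @param thresholds a [phenotype_thresholds()] list.
#' @return logical vector.
#' @export
abdominal_obesity <- function(wc, sex, thresholds = phenotype_thresholds()) {
  if (any(!is.finite(wc)) || any(wc <= 0))
    stop("'wc' must be strictly positive")
  sex <- .check_sex(sex, length(wc))
  wc >= thresholds$wc[sex]
}

#' Derive every phenotype column for a cohort table
#'
#' Appends to the raw cohort the derived columns: `bmi`, `bmi_class`, the
#' four ATP-III component flags, `atp3_component_count`,
#' `metabolically_healthy_atp3`, `homa_ir`, `vai`,
#' `metabolically_healthy_vai`, `phenotype` (ATP-III-based by default),
#' `abdominal_obesity` and `hyperuricemia`.
#'
#' @param cohort a cohort data frame (see [read_cohort()] for the column
#'   dictionary).
#' @param thresholds a [phenotype_thresholds()] list.
#' @param health_criterion `"atp3"` (default) or `"vai"`: which
#'   metabolic-health definition feeds the six-way phenotype.
#' @return the cohort with derived columns appended (stable order).
#' @export
phenotype_cohort <- function(cohort, thresholds = phenotype_thresholds(),
                             health_criterion = c("atp3", "vai")) {
  health_criterion <- match.arg(health_criterion)
  sex <- .check_sex(cohort$sex, nrow(cohort))
  b <- classify_bmi(cohort$weight, cohort$height, thresholds)
  m <- metabolic_health_atp3(cohort$sbp, cohort$dbp, cohort$tg, cohort$fpg,
                             cohort$hdl_c, sex,
                             cohort$antihypertensive_drug,
                             cohort$lipid_drug, cohort$diabetes_drug,
                             thresholds)
  v <- metabolic_health_vai(sex, cohort$waist_circumference, b$bmi,
                            cohort$tg, cohort$hdl_c, thresholds)
  healthy <- if (health_criterion == "atp3") m$metabolically_healthy_atp3
             else v$metabolically_healthy_vai
  out <- cbind(cohort, b, m, v)
  out$homa_ir <- compute_homa_ir(cohort$fasting_insulin, cohort$fpg)
  out$phenotype <- assign_phenotype(b$bmi_class, healthy)
  out$abdominal_obesity <- abdominal_obesity(cohort$waist_circumference, sex,
                                             thresholds)
  out$hyperuricemia <- classify_hyperuricemia(cohort$uric_acid, sex,
                                              thresholds)
  out
}
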