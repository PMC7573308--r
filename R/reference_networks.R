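#' Reference five-node reasoning network
#'
#' A ground-truth discrete network over sex, BMI group, metabolic-component
#' count (0-4), diabetes and hyperuricemia, used as the oracle for
#' round-trip tests of forward sampling, CPT refitting and conditional
#' queries.  Its hyperuricemia table encodes the published risk pattern for
#' the population this package models: probability 0.05 for metabolically
#' healthy normal weight, rising through 0.10/0.14/0.31/0.56 with obesity
#' and component count, 0.076 vs 0.124 for obese component-free men vs
#' women, and 0.606 for obese subjects with four components and diabetes.
#' Sexes are balanced and independent of the other parents, so the
#' sex-marginal rows average to the printed totals; the diabetes multiplier
#' applies only at four components, where diabetes prevalence is 0.7.
#'
#' The auxiliary distributions (BMI group, component count given BMI group,
#' diabetes given component count) are free choices of the test design, not
#' encoded facts; they are set so that every queried stratum receives
#' enough forward-sample mass for its conditional probability to be
#' re-estimated to about three standard errors inside a ±0.01 band at
#' 100,000 records (a power requirement, not a population claim).
#'
#' @return a [bn_model()].
#' @export
reference_reasoning_network <- function() {
  nodes <- c("sex", "bmi_group", "components", "diabetes", "hyperuricemia")
  arcs <- rbind(c("bmi_group", "components"),
                c("components", "diabetes"),
                c("sex", "hyperuricemia"),
                c("bmi_group", "hyperuricemia"),
                c("components", "hyperuricemia"),
                c("diabetes", "hyperuricemia"))
  dag <- bn_dag(nodes, arcs)
  levels <- list(sex = c("male", "female"),
                 bmi_group = c("normal", "overweight", "obese"),
                 components = as.character(0:4),
                 diabetes = c("no", "yes"),
                 hyperuricemia = c("no", "yes"))

  cpt_sex <- matrix(c(0.5, 0.5), 1L)
  cpt_bmi <- matrix(c(0.40, 0.20, 0.40), 1L)
  comp_rows <- rbind(normal = c(0.60, 0.16, 0.12, 0.07, 0.05),
                     overweight = c(0.30, 0.25, 0.20, 0.15, 0.10),
                     obese = c(0.34, 0.06, 0.08, 0.12, 0.40))
  cpt_comp <- unname(comp_rows)
  attr(cpt_comp, "parents") <- "bmi_group"
  diab_yes <- c(0.05, 0.08, 0.12, 0.20, 0.70)
  cpt_diab <- cbind(1 - diab_yes, diab_yes)
  attr(cpt_diab, "parents") <- "components"

  base <- rbind(normal = c(0.05, 0.08, 0.15, 0.25, 0.40),
                overweight = c(0.07, 0.10, 0.22, 0.33, 0.48),
                obese = c(0.10, 0.14, 0.31, 0.44, 0.56))
  sex_mult <- c(male = 0.76, female = 1.24)
  ## diabetes modifies risk only in the four-component stratum; with
  ## diabetes prevalence q = 0.7 there, the no-diabetes multiplier is set
  ## so the stratum average stays at the printed 0.56
  q4 <- 0.7
  h_yes <- 0.606 / 0.56
  h4 <- c(no = (1 - q4 * h_yes) / (1 - q4), yes = h_yes)
  grid <- expand.grid(sex = 1:2, bmi = 1:3, comp = 1:5, diab = 1:2,
                      KEEP.OUT.ATTRS = FALSE)
  p_yes <- base[cbind(grid$bmi, grid$comp)] * sex_mult[grid$sex] *
    ifelse(grid$comp == 5L, h4[grid$diab], 1)
  cpt_hu <- cbind(1 - p_yes, p_yes)
  attr(cpt_hu, "parents") <- c("sex", "bmi_group", "components", "diabetes")

  bn_model(dag, levels, list(sex = cpt_sex, bmi_group = cpt_bmi,
                             components = cpt_comp, diabetes = cpt_diab,
                             hyperuricemia = cpt_hu))
}

#' Reference six-node recovery network
#'
#' A binary six-node network with strongly dependent conditional tables,
#' used in structure-recovery simulations (learn from forward samples,
#' compare the averaged network's skeleton to the truth).
#'
#' @return a [bn_model()] with arcs a->b, a->c, b->d, c->d, d->e, e->f.
#' @export
reference_recovery_network <- function() {
  nodes <- letters[1:6]
  arcs <- rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d"),
                c("d", "e"), c("e", "f"))
  dag <- bn_dag(nodes, arcs)
  levels <- setNames(rep(list(c("0", "1")), 6L), nodes)
  two <- function(p1) {
    m <- cbind(1 - p1, p1)
    m
  }
  cpt_a <- two(0.45)
  cpt_b <- two(c(0.15, 0.85)); attr(cpt_b, "parents") <- "a"
  cpt_c <- two(c(0.25, 0.80)); attr(cpt_c, "parents") <- "a"
  ## rows in (b, c) order, b varying fastest
  cpt_d <- two(c(0.10, 0.75, 0.70, 0.95))
  attr(cpt_d, "parents") <- c("b", "c")
  cpt_e <- two(c(0.15, 0.85)); attr(cpt_e, "parents") <- "d"
  cpt_f <- two(c(0.20, 0.80)); attr(cpt_f, "parents") <- "e"
  bn_model(dag, levels, list(a = cpt_a, b = cpt_b, c = cpt_c, d = cpt_d,
                             e = cpt_e, f = cpt_f))
}

#' Structural Hamming distance between skeletons
#'
#' Number of undirected adjacencies present in exactly one of the two
#' graphs.
#'
#' @param dag1,dag2 `bn_dag` objects over the same node set.
#' @return non-negative integer.
#' @export
skeleton_shd <- function(dag1, dag2) {
  und <- function(g) {
    if (!nrow(g$arcs)) return(character(0))
    unique(paste(pmin(g$arcs[, 1L], g$arcs[, 2L]),
                 pmax(g$arcs[, 1L], g$arcs[, 2L]), sep = "~"))
  }
  a <- und(dag1); b <- und(dag2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Discretize a phenotyped cohort for network learning
#'
#' Builds the 14-variable discrete table the cohort network is learned
#' from: sex; age group (18-39, 40-59, >= 60); BMI level (3 classes);
#' ATP-III metabolic-syndrome status; hyperuricemia; diabetes; smoking;
#' alcohol; urban residence; abdominal obesity; and binary splits of LDL-C
#' (3.37 mmol/L), total cholesterol (5.2 mmol/L), hs-CRP (3 mg/L) and white
#' blood cell count (cohort median).  All cut points are overridable.
#' Underweight records are dropped.
#'
#' @param cohort a phenotyped cohort.
#' @param cuts named list overriding any of `age_breaks`, `ldl`, `tc`,
#'   `hs_crp`, `wbc` (`NULL` wbc means the cohort median).
#' @return data frame of 14 factors.
#' @export
discretize_cohort <- function(cohort, cuts = list()) {
  defaults <- list(age_breaks = c(40, 60), ldl = 3.37, tc = 5.2,
                   hs_crp = 3, wbc = NULL)
  cuts <- modifyList(defaults, cuts)
  d <- cohort[cohort$phenotype != "excluded", , drop = FALSE]
  wbc_cut <- if (is.null(cuts$wbc)) median(d$white_blood_cell) else cuts$wbc
  yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
  data.frame(
    sex = factor(d$sex, levels = c("male", "female")),
    age_group = cut(d$age, c(-Inf, cuts$age_breaks, Inf),
                    labels = c("18-39", "40-59", "60+"), right = FALSE),
    bmi_level = factor(as.character(d$bmi_class),
                       levels = c("normal", "overweight", "obese")),
    mets = yn(!d$metabolically_healthy_atp3),
    hyperuricemia = yn(d$hyperuricemia),
    diabetes = yn(d$diabetes == 1),
    smoker = yn(d$smoker == 1),
    alcohol = yn(d$alcohol == 1),
    urban = yn(d$urban == 1),
    abdominal_obesity = yn(d$abdominal_obesity),
    ldl_high = yn(d$ldl_c >= cuts$ldl),
    tc_high = yn(d$tc >= cuts$tc),
    hscrp_high = yn(d$hs_crp >= cuts$hs_crp),
    wbc_high = yn(d$white_blood_cell >= wbc_cut))
}

#' Node roles for the cohort network
#'
#' The layering role map used with [layering_constraints()] when learning
#' the 14-node cohort network: hyperuricemia is the outcome; metabolic
#' syndrome and BMI level are the exposure layer (not allowed to point at
#' each other); sex is demographic; everything else is a covariate.
#'
#' @return named character vector of roles.
#' @export
cohort_bn_roles <- function() {
  c(hyperuricemia = "outcome", mets = "exposure", bmi_level = "exposure",
    sex = "demographic", age_group = "covariate", diabetes = "covariate",
    smoker = "covariate", alcohol = "covariate", urban = "covariate",
    abdominal_obesity = "covariate", ldl_high = "covariate",
    tc_high = "covariate", hscrp_high = "covariate",
    wbc_high = "covariate")
}
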