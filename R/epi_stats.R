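#' Binomial prevalence with confidence interval
#'
#' Point prevalence \eqn{\hat p = k/n} with, by default, the Wilson score
#' interval (good small-sample coverage and asymmetric near the boundary);
#' the exact Clopper-Pearson interval is available via `method`.
#'
#' @param k event count (0 <= k <= n).
#' @param n stratum size (>= 1).
#' @param level confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return data frame with columns `k`, `n`, `p_hat`, `ci_low`, `ci_high`,
#'   `level`.
#' @export
prevalence_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n and n >= 1")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  p <- k / n
  if (method == "wilson") {
    z <- qnorm(1 - (1 - level) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
    lo[k == 0] <- 0   # boundary cases are exact
    hi[k == n] <- 1
  } else {
    a <- 1 - level
    lo <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  }
  data.frame(k = k, n = n, p_hat = p, ci_low = lo, ci_high = hi,
             level = level)
}

#' Sex-specific hyperuricemia prevalence by phenotype
#'
#' Tabulates hyperuricemia prevalence with confidence intervals for each
#' (phenotype, sex) stratum of a phenotyped cohort, dropping `excluded`
#' (underweight) records.
#'
#' @param cohort a phenotyped cohort (see [phenotype_cohort()]).
#' @inheritParams prevalence_ci
#' @return data frame with one row per occupied stratum.
#' @export
prevalence_by_phenotype <- function(cohort, level = 0.95,
                                    method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  keep <- cohort$phenotype != "excluded"
  d <- cohort[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, list(d$phenotype, d$sex), drop = TRUE),
    function(s) {
      cbind(data.frame(phenotype = as.character(s$phenotype[1L]),
                       sex = as.character(s$sex[1L])),
            prevalence_ci(sum(s$hyperuricemia), nrow(s), level, method))
    }))
  out <- out[order(out$sex, match(out$phenotype, phenotype_levels())), ]
  rownames(out) <- NULL
  out
}

#' Cohort descriptives with two-group tests
#'
#' Mean ± SD with a pooled-variance two-sample t-test for continuous fields;
#' counts, percentages and an uncorrected Pearson chi-square test for
#' categorical/binary fields.  Fields with zero variance in both groups get
#' an `NA` statistic with a warning.
#'
#' @param cohort data frame.
#' @param group name of a binary grouping column (default `"sex"`).
#' @param vars columns to summarize; defaults to all columns except the
#'   grouping variable and `id`.
#' @return data frame with one row per variable: group-wise summaries, the
#'   test statistic and its p-value.
#' @export
describe_cohort <- function(cohort, group = "sex", vars = NULL) {
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2L)
    stop("grouping variable '", group, "' must have exactly two levels")
  if (is.null(vars)) vars <- setdiff(names(cohort), c(group, "id"))
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      m <- tapply(x, g, mean); s <- tapply(x, g, sd)
      if (all(s == 0, na.rm = TRUE)) {
        warning("zero variance in '", v, "'; t-test undefined")
        stat <- p <- NA_real_
      } else {
        tt <- t.test(x ~ g, var.equal = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      data.frame(variable = v, type = "continuous",
                 summary_1 = sprintf("%.2f ± %.2f", m[1L], s[1L]),
                 summary_2 = sprintf("%.2f ± %.2f", m[2L], s[2L]),
                 statistic = stat, p_value = p)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      if (nrow(tab) < 2L) {
        warning("'", v, "' is constant; chi-square undefined")
        stat <- p <- NA_real_
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      ref <- rownames(tab)[nrow(tab)]
      data.frame(variable = v, type = "categorical",
                 summary_1 = sprintf("%d (%.1f%%)", tab[nrow(tab), 1L],
                                     100 * tab[nrow(tab), 1L] /
                                       sum(tab[, 1L])),
                 summary_2 = sprintf("%d (%.1f%%)", tab[nrow(tab), 2L],
                                     100 * tab[nrow(tab), 2L] /
                                       sum(tab[, 2L])),
                 statistic = stat, p_value = p)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binomial-logit GLM by iteratively reweighted least squares.  The
#' design is checked for rank deficiency before fitting (collinear columns
#' are named in the error); apparent perfect separation (diverging
#' coefficients or boundary fitted probabilities) is flagged by setting
#' `converged = FALSE` with a diagnostic message.
#'
#' @param design numeric matrix of predictors with named columns (no
#'   intercept column; one is added).
#' @param outcome binary 0/1 (or logical) response.
#' @return list of class `uric_logit`: `coefficients`, `vcov` (inverse
#'   observed information), `log_likelihood`, `converged`, `diagnostic`,
#'   `n`, `events`.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.matrix(design)
  if (is.null(colnames(design)) || any(!nzchar(colnames(design))))
    stop("'design' must have named columns")
  outcome <- as.numeric(outcome)
  if (any(!outcome %in% c(0, 1))) stop("'outcome' must be binary")
  if (any(apply(design, 2L, function(x) all(x == 0))))
    stop("constant-zero design column")
  X <- cbind(`(Intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(X, outcome, family = binomial(), control = list(epsilon = 1e-10,
                                                            maxit = 50L)))
  cf <- fit$coefficients
  separated <- any(abs(cf) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  converged <- fit$converged && !separated
  diagnostic <- if (!fit$converged) "IRLS did not converge"
    else if (separated) "apparent perfect separation (diverging estimates)"
    else "ok"
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  ll <- sum(outcome * log(mu) + (1 - outcome) * log(1 - mu))
  structure(list(coefficients = cf, vcov = vc, log_likelihood = ll,
                 converged = converged, diagnostic = diagnostic,
                 n = length(outcome), events = sum(outcome)),
            class = "uric_logit")
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(coef)` and `CI = exp(coef ± z SE)` with the normal quantile at
#' the requested level (1.95996 at 95%).
#'
#' @param fit a converged [fit_logistic()] result.
#' @param terms coefficient names to report; defaults to all non-intercept
#'   terms.
#' @param level confidence level, default 0.95.
#' @return data frame with columns `term`, `estimate` (log-odds), `se`,
#'   `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_table <- function(fit, terms = NULL, level = 0.95) {
  if (!inherits(fit, "uric_logit")) stop("'fit' must come from fit_logistic()")
  if (!fit$converged)
    stop("refusing to report odds ratios from a non-converged fit: ",
         fit$diagnostic)
  if (is.null(terms))
    terms <- setdiff(names(fit$coefficients), "(Intercept)")
  missing_terms <- setdiff(terms, names(fit$coefficients))
  if (length(missing_terms))
    stop("unknown term(s): ", paste(missing_terms, collapse = ", "))
  z <- qnorm(1 - (1 - level) / 2)
  cf <- fit$coefficients[terms]
  se <- sqrt(diag(fit$vcov)[terms])
  data.frame(term = terms, estimate = unname(cf), se = unname(se),
             or = unname(exp(cf)), ci_low = unname(exp(cf - z * se)),
             ci_high = unname(exp(cf + z * se)), row.names = NULL)
}

.model_terms <- function(model, stratified) {
  base <- c("age", if (!stratified) "sex_female", "urban", "smoker",
            "alcohol")
  extra <- c("white_blood_cell", "tc", "ldl_c", "hs_crp", "diabetes")
  if (model == 1L) base else c(base, extra)
}

.phenotype_design <- function(d, stratified, model) {
  phen <- factor(as.character(d$phenotype), levels = phenotype_levels())
  ind <- sapply(phenotype_levels()[-1L], function(p)
    as.numeric(phen == p))
  colnames(ind) <- paste0("phenotype", phenotype_levels()[-1L])
  covs <- .model_terms(model, stratified)
  X <- ind
  for (v in covs) {
    X <- cbind(X, if (v == "sex_female") as.numeric(d$sex == "female")
               else as.numeric(d[[v]]))
    colnames(X)[ncol(X)] <- v
  }
  X
}

#' Sequentially adjusted phenotype odds-ratio table
#'
#' Fits, for the total cohort and for each sex stratum, two logistic models
#' of hyperuricemia on the six-way phenotype (MHNW reference, five indicator
#' terms): model 1 adjusts for age, sex (total stratum only), urban/rural
#' residence, smoking and alcohol status; model 2 additionally adjusts for
#' white blood cell count, total cholesterol, LDL-C, hs-CRP and diabetes.
#' Underweight (`excluded`) records are dropped.  A phenotype unoccupied in
#' a stratum yields a row with `NA` odds ratio and a warning.
#'
#' @param cohort a phenotyped cohort.
#' @param level confidence level for Wald intervals.
#' @return data frame of class `uric_or_table`: one row per stratum x model
#'   x phenotype (including the reference row with OR exactly 1).
#' @export
run_association_models <- function(cohort, level = 0.95) {
  d0 <- cohort[cohort$phenotype != "excluded", , drop = FALSE]
  if (length(unique(d0$phenotype)) < 2L)
    stop("phenotype must have at least two occupied levels")
  strata <- list(total = d0,
                 men = d0[d0$sex == "male", , drop = FALSE],
                 women = d0[d0$sex == "female", , drop = FALSE])
  rows <- list()
  both_sexes <- length(unique(d0$sex)) == 2L
  for (s in names(strata)) {
    d <- strata[[s]]
    if (nrow(d) == 0L) {
      warning("stratum '", s, "' is empty; rows reported as NA")
      for (mdl in c(1L, 2L)) for (p in phenotype_levels())
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, phenotype = p, model = mdl, or = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, reference = p == "MHNW")
      next
    }
    occupied <- phenotype_levels() %in% unique(as.character(d$phenotype))
    names(occupied) <- phenotype_levels()
    for (mdl in c(1L, 2L)) {
      X <- .phenotype_design(d, stratified = s != "total" || !both_sexes,
                             model = mdl)
      missing_lv <- phenotype_levels()[-1L][!occupied[-1L]]
      empty_ind <- paste0("phenotype", missing_lv, recycle0 = TRUE)
      keep <- setdiff(colnames(X), empty_ind)
      if (length(missing_lv))
        warning("stratum '", s, "': empty phenotype cell(s) ",
                paste(missing_lv, collapse = ", "))
      fit <- fit_logistic(X[, keep, drop = FALSE], d$hyperuricemia)
      pterms <- grep("^phenotype", keep, value = TRUE)
      if (fit$converged) {
        ors <- odds_ratio_table(fit, pterms, level)
      } else {
        warning("stratum '", s, "', model ", mdl, ": ", fit$diagnostic,
                "; odds ratios reported as NA")
        ors <- data.frame(term = character(0), or = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0))
      }
      for (p in phenotype_levels()) {
        if (p == "MHNW") {
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = s, phenotype = p, model = mdl, or = 1,
            ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
        } else {
          r <- ors[ors$term == paste0("phenotype", p), , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = s, phenotype = p, model = mdl,
            or = if (nrow(r)) r$or else NA_real_,
            ci_low = if (nrow(r)) r$ci_low else NA_real_,
            ci_high = if (nrow(r)) r$ci_high else NA_real_,
            reference = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("uric_or_table", "data.frame")
  out
}

#' Backward stepwise model selection by AIC
#'
#' Backward elimination from the full model using AIC; the six-way phenotype
#' enters as a single factor and therefore leaves or stays as a block.
#' Deterministic given the input term order.
#'
#' @param cohort a phenotyped cohort (underweight dropped internally).
#' @param candidates character vector of candidate adjuster columns.
#' @param include_phenotype start with the phenotype block in the model.
#' @return list with `retained` (character vector of retained terms) and
#'   `fit` (the final `glm`).
#' @export
stepwise_select <- function(cohort, candidates,
                            include_phenotype = TRUE) {
  if (!length(candidates) && !include_phenotype)
    stop("need at least one candidate term")
  d <- cohort[cohort$phenotype != "excluded", , drop = FALSE]
  d$phenotype <- factor(as.character(d$phenotype),
                        levels = phenotype_levels())
  d$phenotype <- droplevels(d$phenotype)
  terms <- c(if (include_phenotype) "phenotype", candidates)
  full <- as.formula(paste("hyperuricemia ~", paste(terms, collapse = " + ")))
  fit <- glm(full, family = binomial(), data = d)
  sel <- step(fit, direction = "backward", trace = 0)
  retained <- attr(stats::terms(sel), "term.labels")
  list(retained = retained, fit = sel)
}
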