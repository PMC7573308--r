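#' Cohort column dictionary
#'
#' The canonical raw-cohort columns, in order: subject id; sex
#' (male/female); age (years); weight (kg); height (m); waist_circumference
#' (cm); sbp, dbp (mmHg); fpg, tg, hdl_c, ldl_c, tc (mmol/L); uric_acid
#' (µmol/L); fasting_insulin (µIU/mL); hs_crp (mg/L); white_blood_cell
#' (10^9/L); and the 0/1 flags smoker, alcohol, urban, diabetes,
#' antihypertensive_drug, lipid_drug, diabetes_drug.
#'
#' @return character vector of column names.
#' @export
cohort_columns <- function() {
  c("id", "sex", "age", "weight", "height", "waist_circumference", "sbp",
    "dbp", "fpg", "tg", "hdl_c", "ldl_c", "tc", "uric_acid",
    "fasting_insulin", "hs_crp", "white_blood_cell", "smoker", "alcohol",
    "urban", "diabetes", "antihypertensive_drug", "lipid_drug",
    "diabetes_drug")
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, "."-decimal cohort table whose header
#' must match the column dictionary ([cohort_columns()]).  Values in
#' numeric columns must parse as numbers (the offending row is named
#' otherwise); records with any missing required field are dropped with the
#' exclusion count reported, mirroring a complete-case analysis.  Adults
#' only: rows with age below 18 are rejected.
#'
#' @param path CSV file path.
#' @param verbose report row counts and exclusions (default `TRUE`).
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  extra <- setdiff(names(raw), cohort_columns())
  if (length(missing_cols) || length(extra))
    stop("schema error: ",
         if (length(missing_cols)) paste("missing column(s):",
                                         paste(missing_cols, collapse = ", ")),
         if (length(extra)) paste(" unknown column(s):",
                                  paste(extra, collapse = ", ")))
  raw <- raw[cohort_columns()]
  numeric_cols <- setdiff(cohort_columns(), "sex")
  for (v in numeric_cols) {
    x <- raw[[v]]
    blank <- is.na(x) | !nzchar(trimws(x))
    parsed <- suppressWarnings(as.numeric(x))
    bad <- !blank & is.na(parsed)
    if (any(bad))
      stop("parse error: non-numeric value in column '", v, "', row ",
           which(bad)[1L])
    raw[[v]] <- parsed
  }
  raw$sex[!nzchar(trimws(raw$sex))] <- NA_character_
  complete <- complete.cases(raw)
  dropped <- sum(!complete)
  out <- raw[complete, , drop = FALSE]
  if (any(!out$sex %in% c("male", "female")))
    stop("schema error: 'sex' must be male/female")
  if (any(out$age < 18))
    stop("cohort contains subjects under 18 years")
  if (verbose)
    message(nrow(raw), " row(s) read; ", dropped,
            " incomplete row(s) excluded; ", nrow(out), " retained")
  rownames(out) <- NULL
  out
}

#' Write a cohort CSV
#'
#' Comma separator, UTF-8, "." decimal, header row, columns exactly in
#' dictionary order (derived columns, if present, appended after).
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  core <- intersect(cohort_columns(), names(cohort))
  rest <- setdiff(names(cohort), core)
  write.csv(cohort[c(core, rest)], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a DAG as DOT or adjacency JSON
#'
#' DOT output lists nodes and arcs in deterministic (node-set) order, with
#' arcs labeled by bootstrap strength when an arc-strength table is given.
#' The adjacency JSON round-trips through [import_graph()] to an identical
#' DAG.
#'
#' @param dag a `bn_dag`.
#' @param path output file.
#' @param format `"dot"` or `"json"`.
#' @param strengths optional `bn_arc_strength` table for edge labels.
#' @export
export_graph <- function(dag, path, format = c("dot", "json"),
                         strengths = NULL) {
  format <- match.arg(format)
  if (!inherits(dag, "bn_dag")) stop("'dag' must be a bn_dag")
  if (format == "dot") {
    lines <- c("digraph bn {", paste0("  \"", dag$nodes, "\";"))
    if (nrow(dag$arcs)) {
      lab <- rep("", nrow(dag$arcs))
      if (!is.null(strengths)) {
        key <- paste(strengths$from, strengths$to)
        s <- strengths$strength[match(paste(dag$arcs[, 1L], dag$arcs[, 2L]),
                                      key)]
        lab <- ifelse(is.na(s), "",
                      sprintf(" [label=\"%.3f\"]", s))
      }
      lines <- c(lines, paste0("  \"", dag$arcs[, 1L], "\" -> \"",
                               dag$arcs[, 2L], "\"", lab, ";"))
    }
    writeLines(c(lines, "}"), path)
  } else {
    adj <- lapply(setNames(dag$nodes, dag$nodes), function(v)
      sort(dag$arcs[dag$arcs[, 1L] == v, 2L]))
    jsonlite::write_json(list(nodes = dag$nodes, children = adj), path,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- do.call(rbind, lapply(names(x$children), function(v) {
    ch <- unlist(x$children[[v]])
    if (length(ch)) cbind(from = v, to = ch) else NULL
  }))
  bn_dag(unlist(x$nodes), arcs)
}

#' Serialize a fitted Bayesian network as JSON
#'
#' Stores the DAG, every node's level labels, and the CPT of each node as a
#' flat probability vector with its parent order; [read_bn_model()]
#' restores an identical model.
#'
#' @param bn a `bn_model`.
#' @param path output file.
#' @export
write_bn_model <- function(bn, path) {
  cpts <- lapply(bn$dag$nodes, function(v) {
    cpt <- bn$cpts[[v]]
    list(parents = as.list(attr(cpt, "parents")),
         prob = as.numeric(cpt), nrow = nrow(cpt))
  })
  names(cpts) <- bn$dag$nodes
  obj <- list(nodes = bn$dag$nodes,
              arcs = apply(bn$dag$arcs, 1L, as.list),
              levels = bn$levels, cpts = cpts)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bn_model
#' @export
read_bn_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- unlist(x$nodes)
  arcs <- if (length(x$arcs))
    do.call(rbind, lapply(x$arcs, function(a)
      c(unlist(a$from), unlist(a$to)))) else NULL
  dag <- bn_dag(nodes, arcs)
  levels <- lapply(x$levels, function(l) unlist(l))
  cpts <- lapply(setNames(nodes, nodes), function(v) {
    spec <- x$cpts[[v]]
    m <- matrix(unlist(spec$prob), nrow = unlist(spec$nrow))
    attr(m, "parents") <- as.character(unlist(spec$parents))
    m
  })
  bn_model(dag, levels, cpts)
}

#' Write / read a generator spec as YAML
#'
#' @param spec a [generator_spec()].
#' @param path file path.
#' @export
write_generator_spec <- function(spec, path) {
  obj <- list(
    n_subjects = spec$n_subjects,
    female_fraction = spec$female_fraction,
    phenotype_probs_by_sex =
      lapply(as.data.frame(spec$phenotype_probs_by_sex), as.numeric),
    hyperuricemia_prev_by_phenotype_sex =
      lapply(as.data.frame(spec$hyperuricemia_prev_by_phenotype_sex),
             as.numeric),
    or_model = spec$or_model,
    seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  x <- yaml::read_yaml(path)
  mat <- function(l) {
    m <- cbind(male = as.numeric(l$male), female = as.numeric(l$female))
    rownames(m) <- phenotype_levels()
    m
  }
  om <- x$or_model
  if (!is.null(om)) om$log_or <- unlist(om$log_or)
  generator_spec(n_subjects = x$n_subjects,
                 female_fraction = x$female_fraction,
                 phenotype_probs_by_sex = mat(x$phenotype_probs_by_sex),
                 hyperuricemia_prev_by_phenotype_sex =
                   mat(x$hyperuricemia_prev_by_phenotype_sex),
                 or_model = om, seed = x$seed)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings: input (a cohort CSV path, or `NULL` to
#' simulate from `generator`), output directory, phenotype thresholds, the
#' network block (bootstrap count `R`, averaged/simplified thresholds,
#' search parameters, discretization cut points), the stats block
#' (confidence level, interval method), and the master seed.
#'
#' @param input path to a cohort CSV, or `NULL` to simulate.
#' @param out_dir output directory (created if absent).
#' @param generator a [generator_spec()] used when `input` is `NULL`.
#' @param thresholds a [phenotype_thresholds()] list.
#' @param bn list with `R`, `avg_threshold`, `simp_threshold`, `params`
#'   ([search_params()]), `cuts` (see [discretize_cohort()]).
#' @param stats list with `level` and `ci_method`.
#' @param seed master seed applied to every stochastic stage.
#' @return a `uric_pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out_dir = tempfile("uricbn_run_"),
                            generator = NULL,
                            thresholds = phenotype_thresholds(),
                            bn = list(), stats = list(), seed = 1L) {
  bn_defaults <- list(R = 300L, avg_threshold = 0.5, simp_threshold = 0.85,
                      params = search_params(), cuts = list())
  stats_defaults <- list(level = 0.95, ci_method = "wilson")
  bn <- modifyList(bn_defaults, bn)
  stats <- modifyList(stats_defaults, stats)
  if (bn$avg_threshold <= 0 || bn$avg_threshold > 1 ||
      bn$simp_threshold <= 0 || bn$simp_threshold > 1)
    stop("network thresholds must be in (0, 1]")
  structure(list(input = input, out_dir = out_dir, generator = generator,
                 thresholds = thresholds, bn = bn, stats = stats,
                 seed = as.integer(seed)),
            class = "uric_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate or read the cohort; derive phenotypes;
#' sex-group descriptives; stratum prevalences; sequentially adjusted
#' odds-ratio models; discretize and learn the cohort network (bootstrap
#' arc strengths, averaged network at the 0.5 threshold, simplified network
#' at 0.85) under the layering constraints; fit CPTs on the averaged
#' network; and query a set of reasoning scenarios.  Every output table and
#' graph is written under `config$out_dir` together with a run log
#' recording the seed and thresholds in force; a failed stage aborts with
#' the stage name, leaving earlier outputs plus a `FAILED` marker.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "uric_pipeline_config"))
    stop("'config' must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("uricbn pipeline; seed = ", config$seed)
  logf("bootstrap R = ", config$bn$R, "; thresholds ",
       config$bn$avg_threshold, " / ", config$bn$simp_threshold,
       "; CI method = ", config$stats$ci_method,
       "; ATP-III unhealthy at >= ",
       config$thresholds$atp3_unhealthy_min, " components")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- stage("read", {
    if (is.null(config$input)) {
      gen <- config$generator
      if (is.null(gen)) gen <- generator_spec(seed = config$seed)
      gen$seed <- config$seed
      sample_cohort(gen)
    } else read_cohort(config$input)
  })
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  phenotyped <- stage("phenotype",
                      phenotype_cohort(cohort, config$thresholds))
  write_cohort(phenotyped, file.path(config$out_dir, "phenotyped.csv"))

  descriptives <- stage("describe", describe_cohort(phenotyped))
  write.csv(descriptives, file.path(config$out_dir, "descriptives.csv"),
            row.names = FALSE)

  prevalence <- stage("prevalence",
    prevalence_by_phenotype(phenotyped, config$stats$level,
                            config$stats$ci_method))
  write.csv(prevalence, file.path(config$out_dir, "prevalence.csv"),
            row.names = FALSE)

  ors <- stage("associate", run_association_models(phenotyped,
                                                   config$stats$level))
  write.csv(ors, file.path(config$out_dir, "odds_ratios.csv"),
            row.names = FALSE)

  discrete <- stage("discretize", discretize_cohort(phenotyped,
                                                    config$bn$cuts))
  constraints <- layering_constraints(cohort_bn_roles())
  params <- config$bn$params
  params$seed <- config$seed
  strengths <- stage("learn",
    bootstrap_arc_strengths(discrete, constraints, params,
                            R = config$bn$R))
  write.table(strengths, file.path(config$out_dir, "arc_strengths.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  averaged <- stage("average",
                    average_network(strengths, config$bn$avg_threshold))
  simplified <- stage("average",
                      average_network(strengths, config$bn$simp_threshold))
  export_graph(averaged, file.path(config$out_dir, "averaged.dot"), "dot",
               strengths)
  export_graph(averaged, file.path(config$out_dir, "averaged.json"), "json")
  export_graph(simplified, file.path(config$out_dir, "simplified.dot"),
               "dot", strengths)

  bn <- stage("fit_cpts", fit_cpts(averaged, discrete))
  write_bn_model(bn, file.path(config$out_dir, "bn_model.json"))

  scenarios <- list(
    list(bmi_level = "normal", mets = "no"),
    list(bmi_level = "obese", mets = "no"),
    list(bmi_level = "obese", mets = "no", sex = "male"),
    list(bmi_level = "obese", mets = "no", sex = "female"),
    list(bmi_level = "obese", mets = "yes"),
    list(bmi_level = "obese", mets = "yes", diabetes = "yes"))
  reasoning <- stage("reasoning",
                     reasoning_table(bn, scenarios, "hyperuricemia", "yes"))
  write.csv(reasoning, file.path(config$out_dir, "reasoning.csv"),
            row.names = FALSE)

  logf("arcs in averaged network: ", nrow(averaged$arcs),
       "; in simplified network: ", nrow(simplified$arcs))
  logf("completed")
  invisible(list(cohort = cohort, phenotyped = phenotyped,
                 descriptives = descriptives, prevalence = prevalence,
                 odds_ratios = ors, strengths = strengths,
                 averaged = averaged, simplified = simplified, bn = bn,
                 reasoning = reasoning))
}
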