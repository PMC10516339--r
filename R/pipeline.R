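#' Specification of one all-possible-subset model comparison
#'
#' Names the outcome, the candidate measures of interest, and the fixed
#' covariates of no interest. The confederate factor is always a covariate;
#' when neural similarity (whole-brain or region-wise ISC) is among the
#' candidates, the number of retained runs and motion similarity must be
#' covariates as well, which [pipeline_comparisons()] arranges
#' automatically.
#'
#' @param outcome outcome column name.
#' @param candidates character vector of candidate measure columns.
#' @param covariates character vector of covariate columns; must contain the
#'   confederate column.
#' @param confederate name of the confederate column (default
#'   `"confederate_id"`).
#' @return list of class `comparison_spec`.
#' @export
comparison_spec <- function(outcome, candidates,
                            covariates = "confederate_id",
                            confederate = "confederate_id") {
  if (!length(candidates)) stop("at least one candidate measure is required")
  if (!confederate %in% covariates)
    stop("the confederate factor must be among the covariates")
  overlap <- intersect(candidates, covariates)
  if (length(overlap))
    stop("column(s) cannot be both candidate and covariate: ",
         paste(overlap, collapse = ", "))
  structure(list(outcome = outcome, candidates = candidates,
                 covariates = covariates, confederate = confederate,
                 complete_case = TRUE),
            class = "comparison_spec")
}

# listwise deletion over every column a comparison touches, applied once
complete_case_data <- function(spec, data, extra = character(0)) {
  cols <- unique(c(spec$outcome, spec$candidates, spec$covariates, extra))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  data[keep, , drop = FALSE]
}

# shared machinery: evaluate a list of term sets against the covariates-only
# baseline and rank them
evaluate_model_set <- function(term_sets, spec, data, prior, method,
                               mc_iterations, seed) {
  results <- vector("list", length(term_sets))
  for (i in seq_along(term_sets)) {
    extras <- term_sets[[i]]
    terms <- c(extras, spec$covariates)
    nm <- if (length(extras)) paste(c(extras, "covariates"), collapse = " + ")
          else "covariates"
    d <- design_spec(data, spec$outcome, terms)
    results[[i]] <- jzs_bf(d, prior = prior, method = method,
                           mc_iterations = mc_iterations,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, nm),
                           model_name = nm)
  }
  base_idx <- which(lengths(term_sets) == 0L)
  stopifnot(length(base_idx) == 1L)
  log_base <- results[[base_idx]]$log_bf10
  tab <- data.frame(
    model = vapply(results, `[[`, "", "model_name"),
    n_candidates = lengths(term_sets),
    bf10 = vapply(results, `[[`, 0, "bf10"),
    log_bf10 = vapply(results, `[[`, 0, "log_bf10"),
    relative_bf = exp(vapply(results, `[[`, 0, "log_bf10") - log_base),
    band = vapply(results, `[[`, "", "band"),
    r_squared = vapply(results, `[[`, 0, "r_squared"),
    n_used = nrow(data),
    stringsAsFactors = FALSE)
  tab$terms <- term_sets
  # larger BF wins; exact ties go to the more parsimonious model, then
  # lexical order
  ord <- order(-tab$log_bf10, tab$n_candidates, tab$model)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(table = tab, results = results[ord], baseline = results[[base_idx]])
}

#' All-possible-subset Bayes-factor comparison
#'
#' Enumerates every subset of the candidate measures (including the empty
#' one), augments each with the fixed covariates, and computes the JZS Bayes
#' factor of each model against the intercept-only null plus its relative
#' Bayes factor against the covariates-only baseline. Listwise deletion over
#' the full variable set is applied once, before any model is fit.
#'
#' @param spec a [comparison_spec()].
#' @param data outcome table (one row per participant).
#' @param prior a [jzs_prior()].
#' @param method,mc_iterations,seed passed to [jzs_bf()].
#' @return object of class `comparison_result`: ranked `table` (model,
#'   bf10, relative_bf, band, n_used, terms), `winner` (top model name),
#'   `top_measure` (best single-candidate measure), `baseline` (the
#'   covariates-only `bf_result`).
#' @export
all_subsets <- function(spec, data, prior = jzs_prior(),
                        method = "quadrature", mc_iterations = 500000L,
                        seed = NULL) {
  stopifnot(inherits(spec, "comparison_spec"))
  data <- complete_case_data(spec, data)
  m <- length(spec$candidates)
  if (m > 12L) stop("refusing to enumerate 2^", m, " candidate subsets")
  term_sets <- lapply(seq_len(2^m) - 1L, function(bits)
    spec$candidates[bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0L])
  ev <- evaluate_model_set(term_sets, spec, data, prior, method,
                           mc_iterations, seed)
  structure(list(table = ev$table, winner = ev$table$model[1],
                 top_measure = top_single_measure(ev$table),
                 baseline = ev$baseline, spec = spec),
            class = "comparison_result")
}

top_single_measure <- function(tab) {
  singles <- tab[tab$n_candidates == 1L, , drop = FALSE]
  if (!nrow(singles)) return(NA_character_)
  best <- singles$log_bf10 == max(singles$log_bf10)
  names <- sort(vapply(singles$terms[best], `[[`, "", 1L))
  if (length(names) > 1L)
    warning("exact tie among single-measure models; choosing '", names[1],
            "' (lexically first)")
  names[1]
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("All-possible-subset BF comparison for", x$spec$outcome, "\n")
  tab <- x$table[, c("model", "bf10", "relative_bf", "band", "n_used")]
  tab$bf10 <- signif(tab$bf10, 4)
  tab$relative_bf <- signif(tab$relative_bf, 4)
  print(tab, row.names = FALSE)
  cat("winner:", x$winner, "| top measure:", x$top_measure, "\n")
  invisible(x)
}

#' Top measure per comparison category
#'
#' The candidate (non-covariate) measure whose single-measure model attains
#' the highest Bayes factor within each category's comparison; this measure
#' feeds the follow-up interaction analysis. Exact ties break to the
#' lexically first measure, with a warning.
#'
#' @param results a `comparison_result` or a named list of them (one per
#'   category).
#' @return character vector of selected measure names.
#' @export
select_top_measure <- function(results) {
  if (inherits(results, "comparison_result")) results <- list(results)
  if (!length(results)) stop("no comparison results supplied")
  vapply(results, function(r) {
    stopifnot(inherits(r, "comparison_result"))
    r$top_measure
  }, character(1))
}

#' Interaction model-comparison test for two selected measures
#'
#' Evaluates the covariates-only baseline, both single main-effect models,
#' the additive joint model and the full model with the `a:b` interaction
#' term, reporting Bayes factors, relative Bayes factors and the
#' main-effects-over-interaction ratio
#' `BF(a + b + cov) / BF(a + b + a:b + cov)`.
#'
#' @param measure_a,measure_b the two selected measure columns (continuous).
#' @param spec a [comparison_spec()] supplying outcome and covariates (its
#'   `candidates` slot is ignored here).
#' @param data outcome table.
#' @param prior,method,mc_iterations,seed passed to [jzs_bf()].
#' @return `comparison_result` with an extra `maineffects_vs_interaction`
#'   element.
#' @export
interaction_test <- function(measure_a, measure_b, spec, data,
                             prior = jzs_prior(), method = "quadrature",
                             mc_iterations = 500000L, seed = NULL) {
  stopifnot(inherits(spec, "comparison_spec"))
  inter <- paste0(measure_a, ":", measure_b)
  data <- complete_case_data(spec, data, extra = c(measure_a, measure_b))
  term_sets <- list(character(0), measure_a, measure_b,
                    c(measure_a, measure_b),
                    c(measure_a, measure_b, inter))
  ev <- evaluate_model_set(term_sets, spec, data, prior, method,
                           mc_iterations, seed)
  additive <- paste(c(measure_a, measure_b, "covariates"), collapse = " + ")
  full <- paste(c(measure_a, measure_b, inter, "covariates"),
                collapse = " + ")
  ratio <- exp(ev$table$log_bf10[ev$table$model == additive] -
                 ev$table$log_bf10[ev$table$model == full])
  structure(list(table = ev$table, winner = ev$table$model[1],
                 top_measure = top_single_measure(ev$table),
                 baseline = ev$baseline, spec = spec,
                 measures = c(measure_a, measure_b),
                 maineffects_vs_interaction = ratio),
            class = "comparison_result")
}

#' Exploratory region-wise Bayes-factor mapping
#'
#' Re-fits a winning model once per atlas region, substituting that region's
#' ISC for the whole-brain similarity term, and reports each region's Bayes
#' factor, evidence band and threshold flags (`BF > 3`, `BF >= 10`). No
#' multiplicity correction is applied; the output is exploratory. A BF label
#' map can be written as NIfTI by painting each parcel of the atlas with its
#' region's Bayes factor, and a network-membership lookup table can be
#' joined.
#'
#' @param terms additional measure terms retained in every model (e.g. the
#'   selected trait measure); the region ISC term and the covariates are
#'   added automatically.
#' @param region_table dyads x regions matrix or data frame of region-wise
#'   correlations, rows aligned with `data` rows (by `participant_id` when
#'   both carry ids, positionally otherwise); columns `r<k>`.
#' @param spec a [comparison_spec()] supplying outcome and covariates.
#' @param data outcome table.
#' @param thresholds two BF thresholds, default `c(3, 10)`.
#' @param atlas optional 3D label atlas (array or NIfTI) for writing the map.
#' @param map_file optional path of the NIfTI BF map to write.
#' @param network_lookup optional data frame with columns `region` and
#'   `network` to join.
#' @param prior,method,mc_iterations,seed passed to [jzs_bf()].
#' @return data frame: one row per region with `region`, `bf10`, `band`,
#'   flag columns, and `network` when a lookup is given.
#' @export
regionwise_analysis <- function(terms, region_table, spec, data,
                                thresholds = c(3, 10), atlas = NULL,
                                map_file = NULL, network_lookup = NULL,
                                prior = jzs_prior(), method = "quadrature",
                                mc_iterations = 500000L, seed = NULL) {
  stopifnot(inherits(spec, "comparison_spec"))
  region_table <- as.matrix(region_table)
  if (!is.null(rownames(region_table)) && "participant_id" %in% names(data)) {
    idx <- match(data$participant_id, rownames(region_table))
    if (anyNA(idx))
      stop("region table is missing participant(s): ",
           paste(data$participant_id[is.na(idx)], collapse = ", "))
    region_table <- region_table[idx, , drop = FALSE]
  } else if (nrow(region_table) != nrow(data)) {
    stop("region table rows (", nrow(region_table),
         ") do not align with data rows (", nrow(data), ")")
  }
  ids <- sub("^r", "", colnames(region_table) %||%
               as.character(seq_len(ncol(region_table))))
  cov_terms <- unique(c(terms, spec$covariates))
  out <- vector("list", ncol(region_table))
  for (k in seq_len(ncol(region_table))) {
    d2 <- data
    d2$region_isc <- region_table[, k]
    keep <- stats::complete.cases(
      d2[, unique(c(spec$outcome, "region_isc", cov_terms)), drop = FALSE])
    d <- design_spec(d2[keep, , drop = FALSE], spec$outcome,
                     c("region_isc", cov_terms))
    bf <- jzs_bf(d, prior = prior, method = method,
                 mc_iterations = mc_iterations,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, k),
                 model_name = paste0("region ", ids[k]))
    out[[k]] <- data.frame(region = as.integer(ids[k]), bf10 = bf$bf10,
                           log_bf10 = bf$log_bf10, band = bf$band,
                           n_used = sum(keep))
  }
  tab <- do.call(rbind, out)
  tab[[paste0("bf_gt_", thresholds[1])]] <- tab$bf10 > thresholds[1]
  tab[[paste0("bf_ge_", thresholds[2])]] <- tab$bf10 >= thresholds[2]
  if (!is.null(network_lookup))
    tab$network <- network_lookup$network[match(tab$region,
                                                network_lookup$region)]
  if (!is.null(atlas) && !is.null(map_file)) {
    arr <- unclass(as.array(atlas))
    map <- array(0, dim = dim(arr))
    for (i in seq_len(nrow(tab)))
      map[arr == tab$region[i]] <- tab$bf10[i]
    RNifti::writeNifti(RNifti::asNifti(map), map_file)
  }
  tab
}

#' Default end-to-end pipeline configuration
#'
#' A self-contained configuration running the full workflow on synthetic
#' data at a reduced imaging size (10 regions, shorter runs) that completes
#' in minutes on one CPU while keeping the study's dyad count and design.
#'
#' @param n_dyads dyads to simulate (default 60).
#' @param n_regions parcels to simulate (default 10).
#' @param seed master seed.
#' @param ... overrides for [simulation_config()] fields.
#' @return nested configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(n_dyads = 60, n_regions = 10, seed = 1L,
                                    ...) {
  list(
    simulation = utils::modifyList(
      list(n_dyads = n_dyads, n_regions = n_regions, volumes_per_run = 120,
           video_end_volume = 110, trim_volumes = 21, seed = seed),
      list(...)),
    outcomes = list(success = "communicative_success",
                    quality = "perceived_quality"),
    categories = list(
      social_cognitive = c("iri", "mrms"),
      similarity = c("whole_brain", "big_five_sim", "avocation_sim",
                     "perceived_similarity")),
    covariates = list(base = "confederate_id",
                      imaging = c("n_runs_used", "fd_similarity")),
    bf = list(method = "quadrature", mc_iterations = 500000),
    regionwise = list(thresholds = c(3, 10))
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  utils::modifyList(default_pipeline_config(), config)
}

# covariates for a comparison: imaging nuisance terms join only when an ISC
# measure is among the candidates
covariates_for <- function(cfg, candidates) {
  isc_terms <- c("whole_brain", "region_isc")
  if (any(candidates %in% isc_terms))
    c(cfg$covariates$base, cfg$covariates$imaging)
  else cfg$covariates$base
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' The four per-outcome-per-category comparisons
#'
#' Runs the all-possible-subset comparison for each outcome (communicative
#' success, perceived quality) crossed with each measure category
#' (social-cognitive, similarity), wiring in the covariate rules.
#'
#' @param cfg pipeline configuration list.
#' @param outcome_table assembled outcome table.
#' @param seed optional seed for Monte-Carlo BF methods.
#' @return named list of `comparison_result`s.
#' @keywords internal
pipeline_comparisons <- function(cfg, outcome_table, seed = NULL) {
  out <- list()
  for (oc_name in names(cfg$outcomes)) {
    oc <- cfg$outcomes[[oc_name]]
    for (cat_name in names(cfg$categories)) {
      cand <- cfg$categories[[cat_name]]
      sp <- comparison_spec(oc, cand, covariates_for(cfg, cand),
                            confederate = cfg$covariates$base[1])
      out[[paste(oc_name, cat_name, sep = "_")]] <-
        all_subsets(sp, outcome_table, method = cfg$bf$method,
                    mc_iterations = cfg$bf$mc_iterations,
                    seed = if (is.null(seed)) NULL
                           else derive_seed(seed, oc_name, cat_name))
    }
  }
  out
}

#' Run the full dyadic-similarity analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or reuse of a supplied
#' dataset), per-dyad neural and motion similarity, outcome-table assembly,
#' the per-category all-possible-subset comparisons, the follow-up
#' interaction tests on the top measure from each category, and the
#' exploratory region-wise analysis of the winning communicative-success
#' model. Optionally writes CSV tables, log-scale BF bar-chart data, a run
#' log and a machine-readable summary JSON.
#'
#' @param config configuration list or YAML/JSON path; see
#'   [default_pipeline_config()]. Anything not supplied falls back to the
#'   defaults.
#' @param seed overrides `config$simulation$seed` when given.
#' @param out_dir optional output directory for the report bundle.
#' @param dataset optional pre-built [simulate_dyad_dataset()] result,
#'   bypassing the simulate stage.
#' @param stages last stage to run, from
#'   `c("simulate", "similarity", "score", "compare", "regions")`; earlier
#'   stages always run.
#' @return (invisibly) list with `dataset`, `similarity`, `outcome_table`,
#'   `comparisons`, `interactions`, `regionwise`, `summary`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL,
                         out_dir = NULL, dataset = NULL,
                         stages = "regions") {
  cfg <- pipeline_stage("config", load_pipeline_config(config))
  stage_order <- c("simulate", "similarity", "score", "compare", "regions")
  last <- match.arg(stages, stage_order)
  depth <- match(last, stage_order)
  if (!is.null(seed)) cfg$simulation$seed <- as.integer(seed)
  master <- cfg$simulation$seed

  bundle <- list(config = cfg)
  bundle$dataset <- pipeline_stage("simulate",
    dataset %||% simulate_dyad_dataset(do.call(simulation_config,
                                               cfg$simulation)))

  if (depth >= 2L) bundle$similarity <- pipeline_stage("similarity",
    dataset_similarity(bundle$dataset))

  if (depth >= 3L) bundle$outcome_table <- pipeline_stage("score", {
    oc <- bundle$dataset$outcomes
    needed <- unlist(cfg$outcomes, use.names = FALSE)
    missing_oc <- setdiff(needed, names(oc))
    if (length(missing_oc))
      stop("outcome column(s) missing from dataset: ",
           paste(missing_oc, collapse = ", "))
    sim <- bundle$similarity$summary
    oc <- oc[, setdiff(names(oc),
                       c("whole_brain", "weighted", "fd_similarity",
                         "n_runs_used", "minutes_used")), drop = FALSE]
    merge(oc, sim, by = "participant_id")
  })

  if (depth >= 4L) {
    bundle$comparisons <- pipeline_stage("compare",
      pipeline_comparisons(cfg, bundle$outcome_table,
                           seed = if (cfg$bf$method == "monte_carlo")
                             master else NULL))
    bundle$interactions <- pipeline_stage("compare", {
      out <- list()
      for (oc_name in names(cfg$outcomes)) {
        top_soc <- bundle$comparisons[[paste0(oc_name,
                                              "_social_cognitive")]]$top_measure
        top_sim <- bundle$comparisons[[paste0(oc_name,
                                              "_similarity")]]$top_measure
        covs <- covariates_for(cfg, c(top_soc, top_sim))
        sp <- comparison_spec(cfg$outcomes[[oc_name]],
                              candidates = c(top_soc, top_sim),
                              covariates = covs,
                              confederate = cfg$covariates$base[1])
        out[[oc_name]] <- interaction_test(top_soc, top_sim, sp,
                                           bundle$outcome_table,
                                           method = cfg$bf$method,
                                           mc_iterations = cfg$bf$mc_iterations)
      }
      out
    })
  }

  if (depth >= 5L) bundle$regionwise <- pipeline_stage("regions", {
    regions <- bundle$similarity$regions
    top_soc <- bundle$comparisons$success_social_cognitive$top_measure
    covs <- c(cfg$covariates$base, cfg$covariates$imaging)
    sp <- comparison_spec(cfg$outcomes$success, candidates = "region_isc",
                          covariates = covs,
                          confederate = cfg$covariates$base[1])
    regionwise_analysis(top_soc, regions, sp, bundle$outcome_table,
                        thresholds = cfg$regionwise$thresholds,
                        method = cfg$bf$method,
                        mc_iterations = cfg$bf$mc_iterations)
  })

  bundle$summary <- pipeline_summary(bundle, master)
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  invisible(bundle)
}

pipeline_summary <- function(bundle, master_seed) {
  comp <- lapply(bundle$comparisons, function(r)
    list(winner = r$winner, top_measure = r$top_measure,
         top_bf10 = r$table$bf10[1],
         top_relative_bf = r$table$relative_bf[1]))
  inter <- lapply(bundle$interactions, function(r)
    list(winner = r$winner,
         maineffects_vs_interaction = r$maineffects_vs_interaction))
  list(seed = master_seed,
       n_dyads = bundle$dataset$config$n_dyads,
       n_excluded = sum(bundle$dataset$manifest$excluded),
       n_regions = bundle$dataset$config$n_regions,
       comparisons = comp, interactions = inter,
       n_regions_bf_gt_3 = if (!is.null(bundle$regionwise))
         sum(bundle$regionwise[[grep("^bf_gt_",
                                     names(bundle$regionwise))[1]]])
       else NULL,
       package_version = as.character(utils::packageVersion("dyadisc")))
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$comparisons)) {
    tab <- bundle$comparisons[[nm]]$table
    tab$terms <- vapply(tab$terms, paste, "", collapse = "+")
    utils::write.csv(tab, file.path(out_dir, paste0("comparison_", nm,
                                                    ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(bundle$interactions)) {
    tab <- bundle$interactions[[nm]]$table
    tab$terms <- vapply(tab$terms, paste, "", collapse = "+")
    utils::write.csv(tab, file.path(out_dir, paste0("interaction_", nm,
                                                    ".csv")),
                     row.names = FALSE)
    # bar-chart data on the log10 scale, mirroring how BF comparisons are
    # usually plotted
    chart <- data.frame(model = tab$model, log10_bf10 = tab$log_bf10 / log(10))
    utils::write.csv(chart, file.path(out_dir, paste0("chart_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$regionwise))
    utils::write.csv(bundle$regionwise,
                     file.path(out_dir, "regionwise.csv"), row.names = FALSE)
  utils::write.csv(bundle$outcome_table,
                   file.path(out_dir, "outcome_table.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(sprintf("seed: %s", bundle$summary$seed),
               sprintf("R version: %s", R.version.string),
               sprintf("dyadisc version: %s",
                       bundle$summary$package_version)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
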