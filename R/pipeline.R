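#' Configuration for an end-to-end analysis run
#'
#' @param input Path to a long-format component CSV (see
#'   [read_twin_csv()]), an existing [twin_dataset()], or `NULL` to
#'   simulate from `sim_config`.
#' @param sim_config A [twin_sim_config()] used when `input` is `NULL`.
#' @param traits Trait subset to analyze (default: all seven components).
#' @param models Model set passed to [selection_driver()].
#' @param transform_traits Traits log(x+1)-transformed before continuous
#'   modelling (default: sleep latency and sleep disturbances, the
#'   right-skewed scores).
#' @param covariates Include age/sex mean covariates in the twin models.
#' @param cfa Run the phenotypic confirmatory factor analyses (only
#'   meaningful with all seven components).
#' @param restarts Optimizer restarts per fit.
#' @param seed Master seed; each stage derives its own stream from it.
#' @param out_dir Output directory for the report bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim_config = twin_sim_config(),
                            traits = psqi_components(),
                            models = c("multivariate_AE", "independent_pathway",
                                       "common_pathway_1"),
                            transform_traits = intersect(c("latency", "disturbances"),
                                                         traits),
                            covariates = FALSE, cfa = length(traits) == 7L,
                            restarts = 1L, seed = 1L, out_dir = tempfile("twinsleep_run")) {
  structure(list(input = input, sim_config = sim_config, traits = traits,
                 models = models, transform_traits = transform_traits,
                 covariates = covariates, cfa = cfa, restarts = restarts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

fit_to_list <- function(f) {
  if (!inherits(f, "twin_fit")) return(list(failed = TRUE, error = f$error))
  list(failed = FALSE, estimates = as.list(f$estimates),
       minus2LL = f$minus2LL, n_params = f$n_params, AIC = f$AIC,
       converged = f$converged, n_pairs_used = f$n_pairs_used,
       model = list(type = f$model$type, kind = f$model$kind))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the stages end to end: load or simulate the cohort,
#' describe it, apply the log(x+1) transform to the skewed components,
#' compute cross-twin correlations, fit and compare the model family,
#' derive the decomposition tables (standardized variance components,
#' etiological correlations, covariance decomposition) from the
#' multivariate fit, compute standardized pathway shares, and run the
#' competing confirmatory factor analyses. All outputs (CSV + JSON) carry
#' the seed; rerunning with the same configuration reproduces them.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`data`,
#'   `description`, `cross_twin`, `selection`, `decomposition`,
#'   `pathway_shares`, `cfa`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  data <- if (inherits(config$input, "twin_dataset")) {
    config$input
  } else if (is.character(config$input)) {
    read_twin_csv(config$input)
  } else {
    sc <- config$sim_config
    sc$seed <- seed
    simulate_twins(sc)
  }
  missing_tr <- setdiff(config$traits, data$specs$trait)
  if (length(missing_tr))
    stop_input("trait(s) not in the input schema: %s",
               paste(missing_tr, collapse = ", "))
  sub_specs <- data$specs[match(config$traits, data$specs$trait), ]
  keep_cols <- c("family_id", "zygosity", "age", "sex1", "sex2",
                 paste0(rep(config$traits, each = 2L), c("_1", "_2")))
  data <- twin_dataset(data$data[, keep_cols], sub_specs)

  desc <- describe_dataset(data)
  jsonlite::write_json(c(desc["n_families"], desc["n_individuals"],
                         list(groups = desc$groups), desc[-(1:3)],
                         list(seed = seed)),
                       file.path(config$out_dir, "description.json"),
                       auto_unbox = TRUE, digits = NA)

  for (tr in config$transform_traits) {
    for (s in c("_1", "_2")) {
      col <- paste0(tr, s)
      data$data[[col]] <- log1_transform(data$data[[col]])
    }
  }

  ctc <- cross_twin_correlations(data)
  utils::write.csv(ctc, file.path(config$out_dir, "cross_twin_correlations.csv"),
                   row.names = FALSE)

  sel <- selection_driver(data, models = config$models, specs = sub_specs,
                          covariates = config$covariates,
                          restarts = config$restarts, seed = seed + 1L)
  utils::write.csv(sel$table, file.path(config$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(sel$fits, fit_to_list),
                       file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)

  decomp <- NULL
  if (inherits(sel$fits$multivariate_AE, "twin_fit")) {
    decomp <- decomposition_table(sel$fits$multivariate_AE$vc)
    write_decomposition_csv(decomp,
                            file.path(config$out_dir, "standardized_components.csv"),
                            file.path(config$out_dir, "covariance_decomposition.csv"))
  }
  shares <- list()
  for (nm in intersect(c("common_pathway_1", "common_pathway_3",
                         "independent_pathway"), names(sel$fits))) {
    if (inherits(sel$fits[[nm]], "twin_fit")) {
      sh <- pathway_shares(sel$fits[[nm]])
      shares[[nm]] <- sh
      utils::write.csv(data.frame(trait = rownames(sh), sh, row.names = NULL),
                       file.path(config$out_dir, paste0("shares_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  cfa_res <- NULL
  if (isTRUE(config$cfa)) {
    one <- select_one_twin_per_pair(data, seed = seed + 2L)
    cfa_res <- lapply(psqi_cfa_specs(), function(sp)
      tryCatch(fit_cfa(sp, table = one), error = function(e) NULL))
    idx <- do.call(rbind, lapply(names(cfa_res), function(nm) {
      f <- cfa_res[[nm]]
      if (is.null(f)) return(data.frame(model = nm, failed = TRUE))
      i <- f$indices
      data.frame(model = nm, failed = FALSE, chi2 = i$chi2, df = i$df,
                 RMSEA = i$RMSEA, RMSEA_lo = i$RMSEA_lo, RMSEA_hi = i$RMSEA_hi,
                 SRMR = i$SRMR, CFI = i$CFI, TLI = i$TLI, BIC = i$BIC,
                 n = i$n_obs, stringsAsFactors = FALSE)
    }))
    utils::write.csv(idx, file.path(config$out_dir, "cfa_indices.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(list(seed = seed, traits = config$traits,
                            models = config$models,
                            transform_traits = config$transform_traits,
                            package_version = as.character(utils::packageVersion("twinsleep"))),
                       file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(list(data = data, description = desc, cross_twin = ctc,
                 selection = sel, decomposition = decomp,
                 pathway_shares = shares, cfa = cfa_res,
                 out_dir = config$out_dir))
}
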