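#' Evidence scenarios
#'
#' The four evidence scenarios used throughout: randomized trials alone,
#' trials plus comparative real-world evidence, all evidence, and all
#' evidence with the bias-adjusted model.
#'
#' @export
SCENARIOS <- c("RCT", "RCT+cRWE", "RCT+cRWE+sRWE", "RCT+cRWE+sRWE-bias")

scenario_designs <- function(scenario) {
  switch(scenario,
         "RCT" = "RCT",
         "RCT+cRWE" = c("RCT", "cRWE"),
         "RCT+cRWE+sRWE" = STUDY_DESIGNS,
         "RCT+cRWE+sRWE-bias" = STUDY_DESIGNS)
}

#' Run one evidence scenario end to end
#'
#' Filters the dataset to the scenario's designs, fits the requested
#' surrogacy model, evaluates the surrogacy criteria, optionally runs
#' take-one-out cross-validation, and (when `out_dir` is given) writes
#' the posterior-summary and cross-validation tables as CSV plus a
#' plain-text manifest recording the configuration, seeds, and
#' convergence diagnostics.
#'
#' @param data study-effects data frame covering all designs.
#' @param model `"dh"`, `"brma"`, or `"brma_bias"`.
#' @param scenario one of [SCENARIOS]. The bias-adjusted scenario
#'   requires `model = "brma_bias"` and non-RCT studies.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param crossval run cross-validation (default TRUE).
#' @param out_dir optional output directory.
#' @return list of class `scenario_result` with elements `fit`,
#'   `criteria`, `cv` (or NULL), `manifest`.
#' @export
run_scenario <- function(data, model = c("dh", "brma", "brma_bias"),
                         scenario = "RCT", priors = prior_config(),
                         mcmc = mcmc_settings(), crossval = TRUE,
                         out_dir = NULL) {
  model <- match.arg(model)
  scenario <- match.arg(scenario, SCENARIOS)
  data <- validate_study_effects(data)
  if (scenario == "RCT+cRWE+sRWE-bias" && model != "brma_bias") {
    stop("the bias-adjusted scenario requires model = 'brma_bias'",
         call. = FALSE)
  }
  if (model == "brma_bias" && scenario == "RCT") {
    stop("configuration error: the bias-adjusted model cannot run on an ",
         "RCT-only scenario; use 'brma'", call. = FALSE)
  }
  sub <- data[data$design %in% scenario_designs(scenario), , drop = FALSE]
  stage <- "model fitting"
  res <- tryCatch({
    fit <- surrofit(sub, model = model, priors = priors, mcmc = mcmc)
    stage <- "criteria evaluation"
    criteria <- evaluate_criteria(fit)
    cv <- NULL
    if (crossval) {
      stage <- "cross-validation"
      cv <- crossvalidate(sub, model = model, priors = priors, mcmc = mcmc)
    }
    list(fit = fit, criteria = criteria, cv = cv)
  }, error = function(e) {
    stop("scenario '", scenario, "' failed during ", stage, " (studies: ",
         paste(sub$study_id, collapse = ", "), "): ",
         conditionMessage(e), call. = FALSE)
  })
  manifest <- c(
    sprintf("scenario: %s", scenario),
    sprintf("model: %s", model),
    sprintf("n_studies: %d", nrow(sub)),
    sprintf("designs: %s", paste(sort(unique(sub$design)), collapse = ",")),
    sprintf("seed: %d", mcmc$seed),
    sprintf("n_iter: %d", mcmc$n_iter),
    sprintf("n_burnin: %d", mcmc$n_burnin),
    sprintf("n_chains: %d", mcmc$n_chains),
    sprintf("priors: location_sd=%g psi2_upper=%g tau_upper=%g bias_sd_upper=%g rho_w_fixed=%s",
            priors$location_sd, priors$psi2_upper, priors$tau_upper,
            priors$bias_sd_upper,
            if (is.null(priors$rho_w_fixed)) "none"
            else format(priors$rho_w_fixed)),
    sprintf("data_md5: %s", data_md5(sub)),
    sprintf("converged: %s", res$fit$converged))
  out <- c(res, list(manifest = manifest, scenario = scenario))
  class(out) <- "scenario_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$fit$summary,
                     file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$criteria,
                     file.path(out_dir, "criteria.csv"),
                     row.names = FALSE, quote = TRUE)
    if (!is.null(res$cv)) {
      utils::write.csv(res$cv$records,
                       file.path(out_dir, "crossval.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  out
}

# md5 of the canonical CSV serialisation of a study-effects table
data_md5 <- function(data) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_study_effects(data, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n\n")
  print(x$fit)
  if (!is.null(x$cv)) {
    cat("\n")
    print(x$cv)
  }
  invisible(x)
}

#' Match single-arm studies and estimate their treatment effects
#'
#' Chains the matching stage into effect estimation: computes the
#' distance matrix between treatment-like and control-like single-arm
#' studies, selects unique matched pairs at the threshold, and — when
#' digitized survival data are supplied — reconstructs pseudo patient
#' data for both arms of each pair and estimates the log hazard ratios
#' on the surrogate and final outcome by Cox regression, yielding
#' study-effects rows with design `"sRWE"`.
#'
#' @param treat,ctrl covariate-profile data frames (one row per study).
#' @param threshold maximum allowable distance; derive it from reference
#'   two-arm designs with [derive_threshold()] or supply the published
#'   override.
#' @param spec a [covariate_spec()].
#' @param km_data optional named list keyed by study id; each element a
#'   list with components `surrogate` and `final`, both [km_dataset()]
#'   objects for that study's arm.
#' @return list with `matrix` (the distance matrix), `matches` (from
#'   [select_matches()]), and `effects` (study-effects rows for the
#'   matched pairs, or NULL when `km_data` is absent).
#' @export
run_matching_stage <- function(treat, ctrl, threshold,
                               spec = covariate_spec(), km_data = NULL) {
  if (is.null(treat) || nrow(treat) == 0L ||
      is.null(ctrl) || nrow(ctrl) == 0L) {
    return(list(matrix = NULL,
                matches = data.frame(treat_id = character(0),
                                     ctrl_id = character(0),
                                     distance = numeric(0)),
                effects = NULL))
  }
  m <- distance_matrix(treat, ctrl, spec)
  matches <- select_matches(m, threshold)
  effects <- NULL
  if (!is.null(km_data) && nrow(matches) > 0L) {
    rows <- vector("list", nrow(matches))
    for (r in seq_len(nrow(matches))) {
      tid <- matches$treat_id[r]
      cid <- matches$ctrl_id[r]
      for (id in c(tid, cid)) {
        if (is.null(km_data[[id]])) {
          stop("matched study '", id, "' (pair ", tid, " vs ", cid,
               ") has no digitized survival data", call. = FALSE)
        }
      }
      eff <- lapply(c("surrogate", "final"), function(outc) {
        cox_loghr(reconstruct_ipd(km_data[[tid]][[outc]]),
                  reconstruct_ipd(km_data[[cid]][[outc]]))
      })
      rows[[r]] <- data.frame(
        study_id = paste(tid, cid, sep = " vs "),
        design = "sRWE",
        y1 = eff[[1]]$loghr, se1 = eff[[1]]$se,
        y2 = eff[[2]]$loghr, se2 = eff[[2]]$se,
        rho_w = NA_real_, stringsAsFactors = FALSE)
    }
    effects <- validate_study_effects(do.call(rbind, rows))
  }
  list(matrix = m, matches = matches, effects = effects)
}
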