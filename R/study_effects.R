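#' Study designs recognised by the surrogacy models
#'
#' `"RCT"` — randomized controlled trial; `"cRWE"` — comparative (two-arm)
#' real-world study; `"sRWE"` — matched pair of single-arm real-world
#' studies.
#'
#' @export
STUDY_DESIGNS <- c("RCT", "cRWE", "sRWE")

#' Validate a table of study-level treatment effects
#'
#' Checks the contract shared by all model-fitting functions: one row per
#' study with log hazard ratios on the surrogate (`y1`) and final (`y2`)
#' outcome, positive standard errors (`se1`, `se2`), a design label, and an
#' optional within-study correlation `rho_w` in \[0, 1\] (`NA` = unknown).
#' `y2` may be `NA` (treated as missing at random, as in cross-validation);
#' `y1` must be observed.
#'
#' @param data data frame of study effects.
#' @return the validated data frame, with `rho_w` added (all `NA`) when
#'   absent, columns in canonical order, and `design` as character.
#' @export
validate_study_effects <- function(data) {
  required <- c("study_id", "design", "y1", "se1", "y2", "se2")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("study-effects table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)
  data$study_id <- as.character(data$study_id)
  data$design <- as.character(data$design)
  if (!("rho_w" %in% names(data))) data$rho_w <- NA_real_
  bad_design <- !(data$design %in% STUDY_DESIGNS)
  if (any(bad_design)) {
    stop("unknown design label(s) for study ",
         paste(data$study_id[bad_design], collapse = ", "),
         "; expected one of ", paste(STUDY_DESIGNS, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("y1", "se1", "y2", "se2", "rho_w")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  bad_se <- !is.na(data$se1) & !is.na(data$se2) &
    (data$se1 > 0) & (data$se2 > 0)
  if (any(!bad_se)) {
    stop("non-positive or missing standard error for study ",
         paste(data$study_id[!bad_se], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(data$y1))) {
    stop("missing y1 for study ",
         paste(data$study_id[is.na(data$y1)], collapse = ", "),
         call. = FALSE)
  }
  rw <- data$rho_w
  bad_rw <- !is.na(rw) & (rw < 0 | rw > 1)
  if (any(bad_rw)) {
    stop("rho_w outside [0, 1] for study ",
         paste(data$study_id[bad_rw], collapse = ", "), call. = FALSE)
  }
  rownames(data) <- NULL
  data[, c(required, "rho_w",
           setdiff(names(data), c(required, "rho_w")))]
}

#' Read a study-effects table from a CSV file
#'
#' The file must have a header naming at least `study_id`, `design`, `y1`,
#' `se1`, `y2`, `se2`; `rho_w` is optional and may be left empty for
#' studies with unknown within-study correlation. Row order is preserved.
#'
#' @param path path to a comma-separated UTF-8 file.
#' @return data frame of validated study effects.
#' @seealso [write_study_effects()], [validate_study_effects()]
#' @export
read_study_effects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        strip.white = TRUE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    return(validate_study_effects(df[0, , drop = FALSE])[0, , drop = FALSE])
  }
  validate_study_effects(df)
}

#' Write a study-effects table to CSV
#'
#' @param data study-effects data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_effects <- function(data, path) {
  data <- validate_study_effects(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Summarise a posterior sample for one parameter
#'
#' Returns the empirical 2.5% and 97.5% quantiles as a 95% equal-tailed
#' credible interval, and a point estimate that is the posterior mean for
#' approximately symmetric samples and the median for skewed ones. With
#' `style = "auto"` the median is used when |mean - median| exceeds 0.1
#' times the interquartile range.
#'
#' @param draws a numeric vector of posterior draws, a matrix with named
#'   columns, or a [surrofit] object.
#' @param parameter parameter name (required unless `draws` is a vector).
#' @param style `"auto"`, `"mean"`, or `"median"`.
#' @return one-row data frame with columns `parameter`, `point`,
#'   `cri_low`, `cri_high`, `point_style`.
#' @export
summarize_posterior <- function(draws, parameter = NULL,
                                style = c("auto", "mean", "median")) {
  style <- match.arg(style)
  x <- extract_draws(draws, parameter)
  if (is.null(parameter)) parameter <- attr(x, "parameter") %||% "parameter"
  if (length(x) < 100L) {
    stop("need at least 100 retained draws to summarise '", parameter,
         "'; got ", length(x), call. = FALSE)
  }
  q <- unname(stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7))
  m <- mean(x)
  md <- stats::median(x)
  if (style == "auto") {
    iqr <- unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))
    style <- if (abs(m - md) > 0.1 * iqr) "median" else "mean"
  }
  data.frame(parameter = parameter,
             point = if (style == "mean") m else md,
             cri_low = q[1], cri_high = q[2],
             point_style = style,
             stringsAsFactors = FALSE)
}

# Pull the numeric draws for one parameter out of the supported containers.
extract_draws <- function(draws, parameter = NULL) {
  if (inherits(draws, "surrofit")) draws <- draws$draws
  if (inherits(draws, "mcmc.list")) draws <- as.matrix(draws)
  if (is.matrix(draws) || is.data.frame(draws)) {
    if (is.null(parameter)) {
      stop("'parameter' must be given when 'draws' has several columns",
           call. = FALSE)
    }
    if (!(parameter %in% colnames(draws))) {
      stop("unknown parameter '", parameter, "'; available: ",
           paste(utils::head(colnames(draws), 20), collapse = ", "),
           call. = FALSE)
    }
    x <- as.numeric(draws[, parameter])
  } else {
    x <- as.numeric(draws)
  }
  attr(x, "parameter") <- parameter
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MCMC run settings
#'
#' Defaults follow the convention of long single-configuration runs used
#' for these models: 150,000 iterations of which 50,000 are burn-in, with
#' two chains for convergence diagnostics. Tests and simulation studies
#' use much shorter runs.
#'
#' @param n_iter total iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations per chain, `< n_iter`.
#' @param n_chains number of chains (>= 1; 2+ enables between-chain R-hat).
#' @param seed integer seed controlling all MCMC randomness.
#' @param thin thinning interval for retained draws.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 150000, n_burnin = 50000, n_chains = 2,
                          seed = 1L, thin = 1L) {
  stopifnot(n_iter >= 1, n_burnin >= 0, n_burnin < n_iter, n_chains >= 1,
            thin >= 1)
  retained <- n_chains * floor((n_iter - n_burnin) / thin)
  if (retained <= 0) stop("no retained draws under these settings")
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 thin = as.integer(thin),
                 retained = as.integer(retained)),
            class = "mcmc_settings")
}
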