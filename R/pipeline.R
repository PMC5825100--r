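epp_predictors <- function() setdiff(trait_variables(), "epp")

#' The six shipped EPP path models
#'
#' Loads the six a-priori model configurations installed with the
#' package (`inst/models/model[1-6].yaml`) and validates their
#' structural constraints.  All six regress EPP directly on each of the
#' eight predictors; they differ in the inter-predictor regressions.
#' None regresses testes size on body size (the testes variable is a
#' body-size-corrected residual).
#'
#' @return a named list of six `path_model`s (`model1` ... `model6`).
#' @export
shipped_models <- function() {
  load_model_suite(system.file("models", package = "sempic"))
}

#' Load and validate a directory of EPP model configurations
#'
#' Reads every `*.yaml` in `dir` as a [read_path_model()] configuration
#' and checks the suite-level constraints: each model must (i) contain
#' all eight direct predictor-to-EPP edges, (ii) not regress
#' `testes_residual` on `body_size`, (iii) match its declared
#' `expected_df`, and (iv) match its declared `endogenous` set if one is
#' given.  Violations are rejected with explicit diagnostics, so edits
#' to the configs-as-data stay honest about the documented structure.
#'
#' @param dir directory holding the YAML model files.
#' @return named list of validated `path_model`s, in file order.
#' @export
load_model_suite <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (!length(files)) stop("no YAML model files in ", dir)
  models <- lapply(files, function(f) {
    m <- read_path_model(f)   # df mismatch against expected_df errors here
    y <- yaml::read_yaml(f)
    missing_epp <- setdiff(epp_predictors(),
                           m$variables[m$B_free["epp", ]])
    if (length(missing_epp))
      stop("model '", m$name, "': missing direct EPP edge(s) from: ",
           paste(missing_epp, collapse = ", "))
    if (m$B_free["testes_residual", "body_size"])
      stop("model '", m$name, "': forbidden edge body_size -> ",
           "testes_residual (testes variable is already size-corrected)")
    if (!is.null(y$endogenous) &&
        !setequal(unlist(y$endogenous), m$endogenous))
      stop("model '", m$name, "': declared endogenous set {",
           paste(unlist(y$endogenous), collapse = ", "),
           "} does not match the regressions, which make {",
           paste(m$endogenous, collapse = ", "), "} endogenous")
    m
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "name"))
}

#' Dual-mode path analysis of a trait table
#'
#' Fits every model of the suite to the raw (tip-level) data and, when a
#' tree (or a precomputed contrast matrix) is supplied, to the
#' phylogenetically-independent-contrast-transformed data, then collects
#' the model-comparison table (AIC, delta-AIC, chi-square, df,
#' chi-square/df, p, CFI, RMSEA, sorted by delta-AIC), the standardized
#' direct effects of the eight predictors on EPP with significance
#' markers at the 0.05 level, the r-squared of every endogenous
#' variable, and the full effect decomposition of the best (lowest-AIC)
#' model per mode.  A model that fails to converge is reported as such
#' and the run continues.
#'
#' @param suite named list of `path_model`s (see [shipped_models()]).
#' @param traits a (transformed) `trait_table`.
#' @param tree optional [ape::phylo] covering the table's species;
#'   enables contrast mode.
#' @param contrasts optional precomputed result of
#'   [contrasts_for_table()]; alternative to `tree`.
#' @param chisq_convention,moments_center,rmsea_n fitting conventions,
#'   recorded in the report; see [fit_ml()] and [sample_moments()].
#'   `moments_center` applies to the contrast mode only (tip-level raw
#'   data always have their mean estimated).
#' @return object of class `"epp_report"`: a list with elements `raw`
#'   and (if applicable) `pic`, each holding `fit_table`,
#'   `direct_effects`, `r2`, `best`, `effects`, `failed`; plus the
#'   conventions under `$conventions`.
#' @export
run_analysis <- function(suite, traits, tree = NULL, contrasts = NULL,
                         chisq_convention = c("N", "N-1"),
                         moments_center = c("mean", "origin"),
                         rmsea_n = chisq_convention) {
  chisq_convention <- match.arg(chisq_convention)
  moments_center <- match.arg(moments_center)
  rmsea_n <- match.arg(rmsea_n, c("N", "N-1"))
  stopifnot(inherits(traits, "trait_table"))
  divisor <- chisq_convention
  modes <- list(raw = sample_moments(traits, center = "mean",
                                     divisor = divisor))
  if (!is.null(tree) && !is.null(contrasts))
    stop("give either 'tree' or 'contrasts', not both")
  if (!is.null(tree))
    contrasts <- contrasts_for_table(tree, traits)
  if (!is.null(contrasts))
    modes$pic <- sample_moments(contrasts$contrasts,
                                center = moments_center, divisor = divisor)
  out <- lapply(modes, function(mom)
    analyze_mode(suite, mom, chisq_convention, rmsea_n))
  structure(c(out, list(conventions = list(
    chisq = chisq_convention, rmsea_n = rmsea_n,
    contrast_center = moments_center, divisor = divisor))),
    class = "epp_report")
}

analyze_mode <- function(suite, moments, chisq_convention, rmsea_n) {
  fits <- lapply(suite, function(m)
    tryCatch(fit_ml(m, moments, chisq_convention = chisq_convention,
                    rmsea_n = rmsea_n),
             error = function(e) e))
  failed <- vapply(fits, inherits, logical(1), "error")
  if (all(failed)) stop("no model converged")
  ok <- fits[!failed]
  fit_table <- do.call(rbind, lapply(names(ok), function(nm) {
    f <- ok[[nm]]
    data.frame(model = nm, aic = f$aic, chisq = f$chisq, df = f$df,
               chisq_df = f$chisq / f$df, pvalue = f$chisq_pvalue,
               cfi = f$cfi, rmsea = f$rmsea, stringsAsFactors = FALSE)
  }))
  fit_table$delta_aic <- fit_table$aic - min(fit_table$aic)
  fit_table <- fit_table[order(fit_table$delta_aic),
                         c("model", "aic", "delta_aic", "chisq", "df",
                           "chisq_df", "pvalue", "cfi", "rmsea")]
  rownames(fit_table) <- NULL
  preds <- epp_predictors()
  direct <- do.call(rbind, lapply(names(ok), function(nm) {
    f <- ok[[nm]]
    est <- f$std$B["epp", preds]
    pv <- f$pvalue[paste0("epp~", preds)]
    row <- data.frame(model = nm, t(est), stringsAsFactors = FALSE)
    row[paste0(preds, "_sig")] <- !is.na(pv) & pv < 0.05
    row
  }))
  direct <- direct[match(fit_table$model, direct$model), ]
  rownames(direct) <- NULL
  r2 <- do.call(rbind, lapply(names(ok), function(nm) {
    v <- r_squared(ok[[nm]])
    all <- stats::setNames(rep(NA_real_, length(trait_variables())),
                           trait_variables())
    all[names(v)] <- v
    data.frame(model = nm, t(all), stringsAsFactors = FALSE)
  }))
  r2 <- r2[match(fit_table$model, r2$model), ]
  rownames(r2) <- NULL
  best <- fit_table$model[1]
  list(fit_table = fit_table, direct_effects = direct, r2 = r2,
       best = best, effects = effects(ok[[best]]),
       fits = ok,
       failed = lapply(fits[failed], conditionMessage))
}

#' @export
print.epp_report <- function(x, digits = 3, ...) {
  for (mode in intersect(c("pic", "raw"), names(x))) {
    cat("== ", if (mode == "pic") "independent-contrast" else "raw",
        " data ==\n", sep = "")
    ft <- x[[mode]]$fit_table
    num <- vapply(ft, is.numeric, logical(1))
    ft[num] <- lapply(ft[num], round, digits)
    print(ft, row.names = FALSE)
    cat("best model:", x[[mode]]$best, "\n\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `fit_table.csv` (model-comparison rows for every mode),
#' `r2_table.csv`, `effects.csv` (effect decomposition of each mode's
#' best model), `report.json` (everything, machine-readable) and
#' `run.log` (conventions used).  Identical reports produce
#' byte-identical files.
#'
#' @param report an `epp_report` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "epp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modes <- intersect(c("pic", "raw"), names(report))
  stack <- function(field)
    do.call(rbind, lapply(modes, function(m)
      cbind(mode = m, report[[m]][[field]])))
  utils::write.csv(stack("fit_table"), file.path(dir, "fit_table.csv"),
                   row.names = FALSE)
  utils::write.csv(stack("r2"), file.path(dir, "r2_table.csv"),
                   row.names = FALSE)
  utils::write.csv(stack("effects"), file.path(dir, "effects.csv"),
                   row.names = FALSE)
  json <- lapply(report[modes], function(m)
    m[c("fit_table", "direct_effects", "r2", "best", "effects", "failed")])
  json$conventions <- report$conventions
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(c(paste("chisq convention:", report$conventions$chisq),
               paste("rmsea denominator N:", report$conventions$rmsea_n),
               paste("contrast centering:", report$conventions$contrast_center),
               paste("covariance divisor:", report$conventions$divisor)),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' The study species fixture
#'
#' The 36 passerine species (15 families) of the printed study table,
#' with their extra-pair-paternity rates (percent of broods with
#' extra-pair young).  The remaining eight predictor columns of the full
#' deposited data set are not reprinted in the text, so this fixture
#' carries only family, species, common name and EPP.
#'
#' @return data.frame with columns `family`, `species`, `common_name`,
#'   `epp`.
#' @export
study_species <- function() {
  utils::read.csv(system.file("extdata", "table1_species.csv",
                              package = "sempic"),
                  stringsAsFactors = FALSE)
}
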