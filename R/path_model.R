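#' Specify a recursive path model
#'
#' A path model over observed variables is a set of simultaneous linear
#' regressions: a directed acyclic graph whose edge `source -> target`
#' carries a free coefficient `B[target, source]`, plus a residual /
#' exogenous covariance structure `Psi`.  Variables with at least one
#' incoming edge are *endogenous* (they get a residual variance and an
#' r-squared); the rest are *exogenous* (their variances, and optionally
#' their pairwise covariances, are free parameters).  Residuals of
#' distinct endogenous variables are uncorrelated (diagonal endogenous
#' block of `Psi`), which keeps every model in the recursive class.
#'
#' @param variables character vector of variable names (defines the
#'   canonical order of all matrices).
#' @param regressions named list: `target = c(source, ...)`.  Each name
#'   must be a variable; the induced graph must be acyclic.
#' @param exog_cov `"free"` (exogenous variables may covary; default) or
#'   `"zero"` (their covariances are fixed at 0).
#' @param name optional label.
#' @param expected_df optional integer; if given, [model_df()] is checked
#'   against it at construction and a mismatch is an error.
#' @return an object of class `"path_model"`.
#' @examples
#' m <- path_model(c("x", "m", "y"),
#'                 list(m = "x", y = c("x", "m")), name = "mediation")
#' model_df(m)   # 0: just-identified
#' @export
path_model <- function(variables, regressions, exog_cov = c("free", "zero"),
                       name = NULL, expected_df = NULL) {
  exog_cov <- match.arg(exog_cov)
  stopifnot(is.character(variables), !anyDuplicated(variables))
  p <- length(variables)
  B_free <- matrix(FALSE, p, p, dimnames = list(variables, variables))
  for (tgt in names(regressions)) {
    src <- regressions[[tgt]]
    if (!tgt %in% variables) stop("unknown target variable: ", tgt)
    if (!all(src %in% variables))
      stop("unknown source variable(s): ",
           paste(setdiff(src, variables), collapse = ", "))
    if (tgt %in% src) stop("self-loop on ", tgt)
    B_free[tgt, src] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(t(B_free), mode = "directed")
  if (!igraph::is_dag(g))
    stop("regression graph has a cycle; the model must be recursive")
  endo <- variables[rowSums(B_free) > 0]
  exog <- setdiff(variables, endo)
  psi_free <- diag(p) == 1
  dimnames(psi_free) <- list(variables, variables)
  if (exog_cov == "free" && length(exog) > 1)
    psi_free[exog, exog] <- TRUE
  m <- structure(list(variables = variables, B_free = B_free,
                      psi_free = psi_free, exog_cov = exog_cov,
                      endogenous = endo, exogenous = exog,
                      name = name %||% "path_model"),
                 class = "path_model")
  if (!is.null(expected_df) && model_df(m) != expected_df)
    stop("model '", m$name, "': computed df ", model_df(m),
         " != expected df ", expected_df)
  m$expected_df <- expected_df
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.path_model <- function(x, ...) {
  cat("Path model '", x$name, "': ", length(x$variables), " variables, ",
      sum(x$B_free), " regressions, df = ", model_df(x), "\n", sep = "")
  for (tgt in x$endogenous)
    cat("  ", tgt, " ~ ",
        paste(x$variables[x$B_free[tgt, ]], collapse = " + "), "\n", sep = "")
  cat("  exogenous (", x$exog_cov, " covariances): ",
      paste(x$exogenous, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a path model
#' @param model a `path_model`.
#' @return integer: free regression coefficients plus free (co)variances.
#' @export
n_free_params <- function(model) {
  stopifnot(inherits(model, "path_model"))
  sum(model$B_free) + sum(model$psi_free[upper.tri(model$psi_free, diag = TRUE)])
}

#' Degrees of freedom of a path model
#'
#' `p(p+1)/2` unique covariance moments minus the number of free
#' parameters.  Negative df means the model is not identified.
#'
#' @param model a `path_model`.
#' @return integer df (>= 0).
#' @export
model_df <- function(model) {
  p <- length(model$variables)
  df <- p * (p + 1) / 2 - n_free_params(model)
  if (df < 0)
    stop("model '", model$name, "' is unidentified: df = ", df)
  as.integer(df)
}

#' Read / write path models as YAML
#'
#' The on-disk schema has keys `name`, `variables`, `regressions`
#' (mapping `target: [sources]`), `exogenous_covariances`
#' (`free`/`zero`) and optional `expected_df`; it round-trips losslessly
#' through [write_path_model()].
#'
#' @param path YAML file path.
#' @return `read_path_model()`: a `path_model`.
#' @export
read_path_model <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("variables", "regressions")
  if (!all(need %in% names(y)))
    stop(path, ": YAML must define ", paste(need, collapse = " and "))
  path_model(unlist(y$variables),
             lapply(y$regressions, unlist),
             exog_cov = y$exogenous_covariances %||% "free",
             name = y$name %||% sub("\\.ya?ml$", "", basename(path)),
             expected_df = y$expected_df)
}

#' @param model a `path_model` to serialize.
#' @rdname read_path_model
#' @return `write_path_model()`: `path`, invisibly.
#' @export
write_path_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  regs <- lapply(stats::setNames(model$endogenous, model$endogenous),
                 function(tgt) model$variables[model$B_free[tgt, ]])
  y <- list(name = model$name, variables = model$variables,
            regressions = regs, exogenous_covariances = model$exog_cov)
  if (!is.null(model$expected_df)) y$expected_df <- model$expected_df
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Enumerate indirect paths into a target variable
#'
#' All directed simple paths of length >= 2 edges ending at `target`.
#' Each such path contributes the product of its coefficients to the
#' indirect effect of its first variable on `target`.
#'
#' @param model a `path_model`.
#' @param target variable name.
#' @return A list: `paths` (list of character vectors, each a full
#'   variable sequence ending at `target`), `count` (their number) and
#'   `by_source` (named integer vector, paths per originating variable).
#' @export
enumerate_indirect_paths <- function(model, target) {
  stopifnot(inherits(model, "path_model"), target %in% model$variables)
  g <- igraph::graph_from_adjacency_matrix(t(model$B_free), mode = "directed")
  paths <- list()
  for (v in setdiff(model$variables, target)) {
    ps <- igraph::all_simple_paths(g, from = v, to = target, mode = "out")
    ps <- Filter(function(pp) length(pp) >= 3, ps)  # >= 2 edges
    paths <- c(paths, lapply(ps, function(pp) model$variables[as.integer(pp)]))
  }
  src <- vapply(paths, `[`, character(1), 1)
  by_source <- if (length(src)) table(factor(src, levels = model$variables))
               else table(factor(character(), levels = model$variables))
  list(paths = paths, count = length(paths),
       by_source = c(by_source[by_source > 0]))
}
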