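#' Sample moments for covariance-structure fitting
#'
#' @param x numeric matrix or data.frame (rows = observations, columns =
#'   model variables) or a `trait_table` (its `species` column is
#'   dropped).
#' @param center `"mean"` (deviations from the sample mean; default) or
#'   `"origin"` (cross-products about zero -- the natural choice for
#'   independent contrasts, which have expectation zero by construction).
#' @param divisor `"N"` (default; pairs with the `N * F` chi-square
#'   convention) or `"N-1"`.
#' @return list of class `"sample_moments"`: `S` (covariance matrix),
#'   `N` (sample size), plus the conventions used.
#' @export
sample_moments <- function(x, center = c("mean", "origin"),
                           divisor = c("N", "N-1")) {
  center <- match.arg(center)
  divisor <- match.arg(divisor)
  if (inherits(x, "trait_table")) x <- x[, trait_variables()]
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (center == "mean") x <- sweep(x, 2, colMeans(x))
  d <- if (divisor == "N") n else n - 1
  S <- crossprod(x) / d
  if (n <= ncol(x))
    warning("sample size (", n, ") not larger than variable count (",
            ncol(x), "); estimates will be unstable")
  structure(list(S = S, N = n, center = center, divisor = divisor),
            class = "sample_moments")
}

#' Model-implied covariance matrix
#'
#' For a recursive path model `y = B y + e` with `Cov(e) = Psi`, the
#' implied covariance of the observed variables is
#' `Sigma = (I - B)^-1 Psi (I - B)^-T`.
#'
#' @param B coefficient matrix (`B[target, source]`).
#' @param Psi residual / exogenous covariance matrix (symmetric).
#' @return symmetric implied covariance `Sigma`.
#' @export
implied_covariance <- function(B, Psi) {
  p <- nrow(B)
  IB <- diag(p) - B
  A <- tryCatch(solve(IB), error = function(e)
    stop("I - B is singular (cycle or unit-coefficient loop)"))
  Sigma <- A %*% Psi %*% t(A)
  dimnames(Sigma) <- dimnames(B)
  (Sigma + t(Sigma)) / 2
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`; non-negative, and
#' zero exactly when `Sigma = S`.
#'
#' @param S sample covariance (positive definite).
#' @param Sigma implied covariance (positive definite).
#' @return the scalar discrepancy.
#' @export
fml <- function(S, Sigma) {
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e)
    stop("S is not positive definite (condition number ",
         format(kappa(S), digits = 3), ")"))
  cSig <- tryCatch(chol(Sigma), error = function(e)
    stop("Sigma is not positive definite (condition number ",
         format(kappa(Sigma), digits = 3), ")"))
  val <- 2 * sum(log(diag(cSig))) + sum(diag(chol2inv(cSig) %*% S)) -
    2 * sum(log(diag(cS))) - p
  max(val, 0)
}

#' Chi-square statistic from the ML discrepancy
#'
#' @param fml_value minimized discrepancy.
#' @param N sample size.
#' @param df model degrees of freedom.
#' @param convention `"N"` (statistic `N * F`, default) or `"N-1"`.
#' @return list with `statistic`, `df`, `pvalue` (1 when `df = 0`, where
#'   the test is vacuous) and the convention used.
#' @export
chisquare <- function(fml_value, N, df, convention = c("N", "N-1")) {
  convention <- match.arg(convention)
  stopifnot(fml_value >= -1e-12, df >= 0)
  mult <- if (convention == "N") N else N - 1
  stat <- mult * max(fml_value, 0)
  pvalue <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, pvalue = pvalue, convention = convention)
}

#' Fit indices: AIC, CFI, RMSEA
#'
#' `AIC = -2 logL + 2k`.  `CFI` compares the model's excess chi-square
#' to that of the baseline model with all covariances fixed at zero:
#' `1 - max(chisq - df, 0) / max(chisq_B - df_B, chisq - df, 0)`.
#' `RMSEA = sqrt(max(chisq - df, 0) / (df * N))`, 0 by convention when
#' `df = 0`; `rmsea_n = "N-1"` swaps the denominator sample size.
#'
#' @param chisq,df model chi-square and degrees of freedom.
#' @param chisq_B,df_B baseline chi-square and degrees of freedom.
#' @param N sample size.
#' @param k number of free parameters.
#' @param logL maximized log-likelihood.
#' @param rmsea_n `"N"` (default) or `"N-1"`.
#' @return list with `aic`, `cfi`, `rmsea`.
#' @export
fit_indices <- function(chisq, df, chisq_B, df_B, N, k, logL,
                        rmsea_n = c("N", "N-1")) {
  rmsea_n <- match.arg(rmsea_n)
  num <- max(chisq - df, 0)
  den <- max(chisq_B - df_B, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  nn <- if (rmsea_n == "N") N else N - 1
  rmsea <- if (df == 0) 0 else sqrt(num / (df * nn))
  list(aic = -2 * logL + 2 * k, cfi = cfi, rmsea = rmsea)
}

## ---- free-parameter bookkeeping ------------------------------------------

par_template <- function(model) {
  v <- model$variables
  bi <- which(model$B_free, arr.ind = TRUE)          # target row, source col
  bi <- bi[order(bi[, 1], bi[, 2]), , drop = FALSE]
  pu <- which(model$psi_free & upper.tri(model$psi_free, diag = TRUE),
              arr.ind = TRUE)
  pu <- pu[order(pu[, 1] != pu[, 2], pu[, 1], pu[, 2]), , drop = FALSE]
  names_b <- paste0(v[bi[, 1]], "~", v[bi[, 2]])
  names_p <- paste0(v[pu[, 1]], "~~", v[pu[, 2]])
  list(b = bi, psi = pu, n_b = nrow(bi), n_psi = nrow(pu),
       names = c(names_b, names_p),
       is_variance = c(rep(FALSE, nrow(bi)), pu[, 1] == pu[, 2]))
}

par_to_matrices <- function(theta, model, tpl) {
  p <- length(model$variables)
  B <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  Psi <- B
  if (tpl$n_b) B[tpl$b] <- theta[seq_len(tpl$n_b)]
  th_p <- theta[tpl$n_b + seq_len(tpl$n_psi)]
  Psi[tpl$psi] <- th_p
  Psi[tpl$psi[, c(2, 1), drop = FALSE]] <- th_p
  list(B = B, Psi = Psi)
}

# per-equation least squares from the sample covariance; exact ML for
# recursive models with diagonal endogenous residuals and a free
# exogenous block, and a good start otherwise
start_values <- function(model, S, tpl) {
  v <- model$variables
  theta <- numeric(tpl$n_b + tpl$n_psi)
  B <- matrix(0, length(v), length(v), dimnames = list(v, v))
  psi_diag <- stats::setNames(diag(S), v)
  for (tgt in model$endogenous) {
    src <- v[model$B_free[tgt, ]]
    b <- solve(S[src, src, drop = FALSE], S[src, tgt])
    B[tgt, src] <- b
    psi_diag[tgt] <- max(S[tgt, tgt] - drop(crossprod(b, S[src, tgt])),
                         1e-8 * S[tgt, tgt])
  }
  if (tpl$n_b) theta[seq_len(tpl$n_b)] <- B[tpl$b]
  for (j in seq_len(tpl$n_psi)) {
    i1 <- tpl$psi[j, 1]; i2 <- tpl$psi[j, 2]
    theta[tpl$n_b + j] <- if (i1 == i2) psi_diag[i1] else S[i1, i2]
  }
  theta
}

fml_gradient <- function(theta, model, tpl, S) {
  m <- par_to_matrices(theta, model, tpl)
  p <- nrow(S)
  A <- solve(diag(p) - m$B)
  Sigma <- A %*% m$Psi %*% t(A)
  Sinv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) NULL)
  if (is.null(Sinv)) return(rep(NA_real_, length(theta)))
  W <- Sinv %*% (Sigma - S) %*% Sinv
  g <- numeric(length(theta))
  if (tpl$n_b) {
    SWA <- Sigma %*% W %*% A
    g[seq_len(tpl$n_b)] <- 2 * SWA[tpl$b[, c(2, 1), drop = FALSE]]
  }
  AWA <- t(A) %*% W %*% A
  dg <- AWA[tpl$psi]
  off <- tpl$psi[, 1] != tpl$psi[, 2]
  dg[off] <- 2 * dg[off]
  g[tpl$n_b + seq_len(tpl$n_psi)] <- dg
  g
}

numeric_hessian <- function(fun, theta, ...) {
  k <- length(theta)
  H <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    up <- dn <- theta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    H[, j] <- (fun(up, ...) - fun(dn, ...)) / (2 * h)
  }
  (H + t(H)) / 2
}

## ---- the fitter ----------------------------------------------------------

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy [fml()] between the sample covariance and
#' the model-implied covariance over the free coefficients and
#' (co)variances, by quasi-Newton iteration with the analytic gradient,
#' started from per-equation least squares.  Standard errors come from
#' the inverse observed information of the ML objective.  The chi-square
#' multiplier (`N * F` by default, `(N-1) * F` by flag) and the RMSEA
#' denominator follow the conventions given; both are recorded in the
#' fit.
#'
#' @param model a [path_model()].
#' @param moments a [sample_moments()] object, or a data matrix /
#'   `trait_table` from which moments are computed with the divisor
#'   matching `chisq_convention`.
#' @param chisq_convention `"N"` (default) or `"N-1"`.
#' @param rmsea_n sample size used in the RMSEA denominator; defaults to
#'   the chi-square convention.
#' @param se compute standard errors (set `FALSE` to speed up large
#'   simulation studies).
#' @param bound_variances keep residual-variance estimates above 1e-10;
#'   a bound that binds (Heywood case) triggers a warning.
#' @return An object of class `"sem_fit"`; see [summary.sem_fit()],
#'   [standardize()], [effects.sem_fit()], [r_squared()].
#' @examples
#' m <- path_model(c("x", "y"), list(y = "x"))
#' set.seed(1)
#' d <- cbind(x = rnorm(200), y = NA)
#' d[, "y"] <- 0.5 * d[, "x"] + rnorm(200, sd = sqrt(0.75))
#' fit <- fit_ml(m, sample_moments(d))
#' coef(fit)
#' @export
fit_ml <- function(model, moments, chisq_convention = c("N", "N-1"),
                   rmsea_n = chisq_convention, se = TRUE,
                   bound_variances = TRUE) {
  chisq_convention <- match.arg(chisq_convention)
  rmsea_n <- match.arg(rmsea_n, c("N", "N-1"))
  stopifnot(inherits(model, "path_model"))
  if (!inherits(moments, "sample_moments"))
    moments <- sample_moments(moments, divisor = chisq_convention)
  S <- moments$S[model$variables, model$variables]
  N <- moments$N
  p <- length(model$variables)
  df <- model_df(model)
  tpl <- par_template(model)
  if (N <= tpl$n_b + tpl$n_psi)
    warning("sample size (", N, ") not larger than free-parameter count (",
            tpl$n_b + tpl$n_psi, ")")

  obj <- function(theta) {
    m <- par_to_matrices(theta, model, tpl)
    Sigma <- tryCatch(implied_covariance(m$B, m$Psi),
                      error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    tryCatch(fml(S, Sigma), error = function(e) 1e10)
  }
  grad <- function(theta) {
    g <- fml_gradient(theta, model, tpl, S)
    if (anyNA(g)) rep(0, length(theta)) else g
  }
  start <- start_values(model, S, tpl)
  lower <- rep(-Inf, length(start))
  if (bound_variances) lower[tpl$is_variance] <- 1e-10
  opt <- stats::nlminb(start, obj, gradient = grad, lower = lower,
                       control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                      iter.max = 500, eval.max = 1000))
  theta <- opt$par
  at_bound <- tpl$is_variance & theta <= 1e-9
  if (any(at_bound))
    warning("Heywood case: variance estimate(s) at the lower bound: ",
            paste(tpl$names[at_bound], collapse = ", "))
  gnorm <- max(abs(grad(theta)[!at_bound]))
  if (gnorm > 1e-5 * max(1, abs(opt$objective))) {
    err <- simpleError(paste0("fit_ml did not converge (max |gradient| = ",
                              format(gnorm, digits = 3), ")"))
    attr(err, "best_par") <- stats::setNames(theta, tpl$names)
    class(err) <- c("sem_nonconvergence", class(err))
    stop(err)
  }

  m <- par_to_matrices(theta, model, tpl)
  Sigma <- implied_covariance(m$B, m$Psi)
  F_ml <- fml(S, Sigma)
  chi <- chisquare(F_ml, N, df, chisq_convention)
  mult <- if (chisq_convention == "N") N else N - 1

  # baseline: free variances, all covariances fixed at zero
  F_base <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  chisq_B <- mult * max(F_base, 0)
  df_B <- p * (p - 1) / 2

  logL <- -(N / 2) * (p * log(2 * pi) + determinant(Sigma, TRUE)$modulus[1] +
                        sum(diag(S %*% chol2inv(chol(Sigma)))))
  k <- tpl$n_b + tpl$n_psi
  idx <- fit_indices(chi$statistic, df, chisq_B, df_B, N, k, logL, rmsea_n)

  vcov_theta <- NULL
  se_theta <- rep(NA_real_, k)
  if (se) {
    H <- numeric_hessian(function(th) fml_gradient(th, model, tpl, S), theta)
    vcov_theta <- tryCatch((2 / mult) * solve(H), error = function(e) NULL)
    if (is.null(vcov_theta)) {
      warning("observed information is singular; standard errors unavailable")
    } else {
      dimnames(vcov_theta) <- list(tpl$names, tpl$names)
      se_theta <- sqrt(pmax(diag(vcov_theta), 0))
    }
  }
  z <- theta / se_theta
  fit <- structure(list(
    model = model, S = S, N = N, df = df, B = m$B, Psi = m$Psi,
    Sigma = Sigma, theta = stats::setNames(theta, tpl$names),
    se = stats::setNames(se_theta, tpl$names),
    z = stats::setNames(z, tpl$names),
    pvalue = stats::setNames(2 * stats::pnorm(-abs(z)), tpl$names),
    vcov = vcov_theta, template = tpl, fml = F_ml,
    chisq = chi$statistic, chisq_pvalue = chi$pvalue,
    chisq_convention = chisq_convention, rmsea_n = rmsea_n,
    baseline = list(chisq = chisq_B, df = df_B),
    logL = logL, n_free = k, aic = idx$aic, cfi = idx$cfi,
    rmsea = idx$rmsea,
    convergence = list(code = opt$convergence, iterations = opt$iterations,
                       max_abs_gradient = gnorm,
                       message = opt$message)),
    class = "sem_fit")
  fit$std <- standardize(fit)
  fit
}

#' @export
coef.sem_fit <- function(object, ...) object$theta

#' @export
print.sem_fit <- function(x, ...) {
  cat("ML path-model fit '", x$model$name, "' (", length(x$model$variables),
      " variables, N = ", x$N, ")\n", sep = "")
  cat(sprintf("  chisq = %.3f on df = %d (p = %.3f, %s convention)\n",
              x$chisq, x$df, x$chisq_pvalue, x$chisq_convention))
  cat(sprintf("  AIC = %.2f  CFI = %.3f  RMSEA = %.3f\n",
              x$aic, x$cfi, x$rmsea))
  invisible(x)
}

#' Summarize a fitted path model
#' @param object a `sem_fit`.
#' @param ... unused.
#' @return data.frame of free parameters with estimates, standard
#'   errors, z statistics, two-sided p-values and standardized estimates
#'   (for regression coefficients).
#' @export
summary.sem_fit <- function(object, ...) {
  tpl <- object$template
  std <- rep(NA_real_, length(object$theta))
  if (tpl$n_b) std[seq_len(tpl$n_b)] <- object$std$B[tpl$b]
  data.frame(parameter = tpl$names, estimate = unname(object$theta),
             se = unname(object$se), z = unname(object$z),
             pvalue = unname(object$pvalue), std = std,
             stringsAsFactors = FALSE)
}

#' Standardized solution
#'
#' Rescales every coefficient by the ratio of implied standard
#' deviations, `beta_std = beta * sd(source) / sd(target)`, with the
#' standard deviations taken from the implied covariance.  Standardized
#' coefficients are invariant to any positive rescaling of the observed
#' variables (such as dividing percentage variables by 10).
#'
#' @param fit a `sem_fit`.
#' @return list with `B` (standardized coefficient matrix) and `Psi`
#'   (residual covariance of the standardized variables).
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  sds <- sqrt(diag(fit$Sigma))
  if (any(sds <= 0)) stop("zero implied variance; cannot standardize")
  Dinv <- diag(1 / sds)
  D <- diag(sds)
  list(B = Dinv %*% fit$B %*% D |>
         `dimnames<-`(dimnames(fit$B)),
       Psi = Dinv %*% fit$Psi %*% Dinv |>
         `dimnames<-`(dimnames(fit$Psi)))
}

#' Direct, indirect and total effects
#'
#' For a recursive model the total-effect matrix is
#' `(I - B)^-1 - I`; the direct effect is the single-edge coefficient
#' `B[target, source]` and the indirect effect (the sum over all
#' directed paths of length >= 2 of the products of their coefficients)
#' is their difference.  Standard errors for indirect effects use the
#' delta method on the free parameters; standardized versions use the
#' implied standard deviations.
#'
#' @param object a `sem_fit`.
#' @param ... unused.
#' @return data.frame with one row per (source, target) pair that has at
#'   least one directed path, holding direct / indirect / total effects,
#'   their standardized versions, and delta-method `se`, `z`, `pvalue`
#'   for the (unstandardized) indirect effect where one exists.
#' @export
effects.sem_fit <- function(object, ...) {
  v <- object$model$variables
  p <- length(v)
  total <- solve(diag(p) - object$B) - diag(p)
  indirect <- total - object$B
  sds <- sqrt(diag(object$Sigma))
  scale <- outer(1 / sds, sds)          # [target, source]
  reach <- path_reachability(object$model)
  pairs <- which(reach$any, arr.ind = TRUE)
  out <- data.frame(
    source = v[pairs[, 2]], target = v[pairs[, 1]],
    direct = object$B[pairs], indirect = indirect[pairs],
    total = total[pairs],
    std_direct = (object$B * scale)[pairs],
    std_indirect = (indirect * scale)[pairs],
    std_total = (total * scale)[pairs],
    se_indirect = NA_real_, z_indirect = NA_real_,
    p_indirect = NA_real_, stringsAsFactors = FALSE)
  has_ind <- reach$indirect[pairs]
  if (any(has_ind) && !is.null(object$vcov)) {
    tgt_idx <- pairs[has_ind, 1]; src_idx <- pairs[has_ind, 2]
    f <- function(theta) {
      m <- par_to_matrices(theta, object$model, object$template)
      ind <- solve(diag(p) - m$B) - diag(p) - m$B
      ind[cbind(tgt_idx, src_idx)]
    }
    J <- numeric_jacobian(f, object$theta)
    vv <- diag(J %*% object$vcov %*% t(J))
    out$se_indirect[has_ind] <- sqrt(pmax(vv, 0))
    out$z_indirect <- out$indirect / out$se_indirect
    out$p_indirect <- 2 * stats::pnorm(-abs(out$z_indirect))
  }
  out[order(match(out$target, v), match(out$source, v)), ]
}

numeric_jacobian <- function(f, theta) {
  k <- length(theta)
  f0 <- f(theta)
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    up <- dn <- theta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

# which (target, source) pairs are connected by any directed path /
# by a path of length >= 2
path_reachability <- function(model) {
  Bf <- model$B_free * 1
  p <- nrow(Bf)
  reach <- Bf
  pow <- Bf
  indirect <- matrix(0, p, p)
  for (len in 2:max(2, p)) {
    pow <- (pow %*% Bf > 0) * 1
    indirect <- indirect + pow
    reach <- reach + pow
  }
  list(any = reach > 0, indirect = indirect > 0)
}

#' Explained variance of endogenous variables
#'
#' `r^2(y) = 1 - psi_yy / Sigma_yy`, reported only for variables on the
#' left-hand side of at least one regression equation.
#'
#' @param fit a `sem_fit`.
#' @return named numeric vector, one entry per endogenous variable.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  endo <- fit$model$endogenous
  stats::setNames(1 - diag(fit$Psi)[endo] / diag(fit$Sigma)[endo], endo)
}
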