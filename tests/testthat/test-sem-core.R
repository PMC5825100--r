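test_that("implied covariance matches closed forms and a Monte-Carlo oracle", {
  Psi <- diag(c(1, 2, 3))
  expect_equal(implied_covariance(matrix(0, 3, 3), Psi), Psi)

  B <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  B["y", "x"] <- 0.5
  Psi2 <- diag(c(1, 0.75)); dimnames(Psi2) <- dimnames(B)
  expect_equal(implied_covariance(B, Psi2),
               matrix(c(1, 0.5, 0.5, 1), 2, dimnames = dimnames(B)))

  # brute-force simulation from the structural equations, 1e6 draws
  rr <- random_recursive_model(5, seed = 41)
  Sig <- implied_covariance(rr$truth$B, diag(rr$truth$psi))
  set.seed(42)
  n <- 1e6
  E <- sapply(rr$truth$psi, function(s2) rnorm(n, 0, sqrt(s2)))
  Y <- E %*% t(solve(diag(5) - rr$truth$B))
  Smc <- crossprod(sweep(Y, 2, colMeans(Y))) / n
  # se of a covariance entry ~ sqrt((sii*sjj + sij^2)/n)
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / n)
  expect_true(all(abs(Smc - Sig) < 3 * se))

  B["x", "y"] <- 2  # unit loop x->y->x with product 1: singular
  expect_error(implied_covariance(B, Psi2), "singular")
})

test_that("the ML discrepancy has its closed-form values and zero floor", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(fml(S, S), 0)
  expect_equal(fml(matrix(2), matrix(1)), log(1) + 2 - log(2) - 1,
               tolerance = 1e-12)
  expect_equal(fml(matrix(2), matrix(1)), 0.30685, tolerance = 1e-5)
  for (cc in c(0.5, 2, 5))
    expect_equal(fml(S, cc * S), 2 * (log(cc) + 1 / cc - 1),
                 tolerance = 1e-10)
  expect_error(fml(matrix(c(1, 2, 2, 1), 2), S), "positive definite")
})

test_that("a just-identified model reproduces S exactly with chisq 0", {
  rr <- random_recursive_model(4, seed = 43, density = 1)
  expect_equal(model_df(rr$model), 0L)
  set.seed(44)
  fit <- fit_ml(rr$model, sample_moments(mvn_sample(80, rr$truth$Sigma)))
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_lt(max(abs(fit$Sigma - fit$S)), 1e-8)
  expect_equal(fit$chisq_pvalue, 1)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
})

test_that("fit_ml recovers simulated coefficients within analytic error", {
  m <- path_model(c("x", "y"), list(y = "x"))
  set.seed(45)
  n <- 1e5
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
  fit <- fit_ml(m, sample_moments(cbind(x = x, y = y)))
  beta <- coef(fit)["y~x"]
  se_analytic <- sqrt(0.75 / (n * var(x)))
  expect_lt(abs(beta - 0.5), 3 * se_analytic)
  expect_equal(unname(fit$se["y~x"]), se_analytic, tolerance = 0.05)
})

test_that("ML estimates equal per-equation least squares where that is exact", {
  # recursive models with diagonal endogenous residuals and a free
  # exogenous block: the likelihood factorizes, so OLS per equation is
  # the ML solution -- an independent closed-form oracle for the
  # quasi-Newton fitter
  for (s in 1:20) {
    p <- sample(3:6, 1)
    rr <- random_recursive_model(p, seed = 500 + s)
    set.seed(600 + s)
    d <- mvn_sample(500, rr$truth$Sigma)
    fit <- fit_ml(rr$model, sample_moments(d), se = FALSE)
    for (tgt in rr$model$endogenous) {
      src <- rr$model$variables[rr$model$B_free[tgt, ]]
      # least squares on mean-centred data mirrors mean-estimated moments
      dc <- sweep(d, 2, colMeans(d))
      ols <- solve(crossprod(dc[, src, drop = FALSE]),
                   crossprod(dc[, src, drop = FALSE], dc[, tgt]))
      expect_equal(unname(fit$B[tgt, src]), unname(drop(ols)),
                   tolerance = 1e-6)
      resid <- dc[, tgt] - dc[, src, drop = FALSE] %*% ols
      expect_equal(unname(fit$Psi[tgt, tgt]), drop(crossprod(resid)) / 500,
                   tolerance = 1e-6)
    }
  }
})

test_that("chi-square conventions and nesting behave", {
  ch <- chisquare(0, 50, 5)
  expect_equal(ch$statistic, 0)
  expect_equal(ch$pvalue, 1)
  expect_equal(chisquare(30.04 / 35, 35, 12)$statistic, 30.04)
  expect_equal(chisquare(0.5, 35, 12, "N-1")$statistic, 17)

  # a nested (more constrained) model can never fit better
  rr <- random_recursive_model(5, seed = 46, density = 0.8)
  smaller <- rr$model
  drop_tgt <- smaller$endogenous[which.max(rowSums(smaller$B_free))]
  regs_small <- lapply(setNames(smaller$endogenous, smaller$endogenous),
                       function(t) smaller$variables[smaller$B_free[t, ]])
  regs_small[[drop_tgt]] <- regs_small[[drop_tgt]][-1]
  regs_small <- Filter(length, regs_small)
  nested <- path_model(smaller$variables, regs_small)
  set.seed(47)
  d <- mvn_sample(200, rr$truth$Sigma)
  f_full <- fit_ml(rr$model, sample_moments(d), se = FALSE)
  f_nested <- fit_ml(nested, sample_moments(d), se = FALSE)
  expect_gte(f_nested$chisq + 1e-10, f_full$chisq)
})

test_that("fit indices reproduce their defining formulas", {
  idx <- fit_indices(chisq = 8, df = 12, chisq_B = 300, df_B = 36,
                     N = 35, k = 33, logL = -100)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$aic, 266)
  idx2 <- fit_indices(chisq = 50, df = 10, chisq_B = 100, df_B = 36,
                      N = 40, k = 35, logL = -100)
  expect_equal(idx2$cfi, 1 - 40 / 64)
  expect_equal(idx2$rmsea, sqrt(40 / (10 * 40)))
})

test_that("standardization rescales by implied sds and is scale-stable", {
  m <- path_model(c("x", "y"), list(y = "x"))
  set.seed(48)
  x <- rnorm(300, sd = 2)
  y <- 0.5 * x + rnorm(300, sd = 1)
  fit <- fit_ml(m, sample_moments(cbind(x = x, y = y)))
  sds <- sqrt(diag(fit$Sigma))
  expect_equal(fit$std$B["y", "x"],
               fit$B["y", "x"] * sds["x"] / sds["y"],
               ignore_attr = TRUE)
  # rescale the source column by c: raw coefficient moves by 1/c,
  # standardized coefficient does not
  fit10 <- fit_ml(m, sample_moments(cbind(x = 10 * x, y = y)))
  expect_equal(fit10$B["y", "x"], fit$B["y", "x"] / 10, tolerance = 1e-8)
  expect_equal(fit10$std$B["y", "x"], fit$std$B["y", "x"], tolerance = 1e-8)
})

test_that("standardized solutions ignore positive diagonal rescaling", {
  # certifies that dividing percentage variables by 10 cannot change
  # standardized results
  rr <- random_recursive_model(5, seed = 49)
  set.seed(50)
  d <- mvn_sample(120, rr$truth$Sigma)
  scl <- c(0.1, 10, 1, 0.5, 3)
  f1 <- fit_ml(rr$model, sample_moments(d), se = FALSE)
  f2 <- fit_ml(rr$model, sample_moments(sweep(d, 2, scl, "*")), se = FALSE)
  expect_lt(max(abs(f1$std$B - f2$std$B)), 1e-8)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-8)
  expect_equal(r_squared(f1), r_squared(f2), tolerance = 1e-8)
})

test_that("effect decomposition: products of paths, cancellation, identity", {
  m <- path_model(c("x", "m", "y"), list(m = "x", y = "m"))
  set.seed(51)
  x <- rnorm(2000)
  mm <- 0.5 * x + rnorm(2000, sd = sqrt(0.75))
  y <- 0.4 * mm + rnorm(2000)
  fit <- fit_ml(m, sample_moments(cbind(x = x, m = mm, y = y)))
  ef <- effects(fit)
  xy <- ef[ef$source == "x" & ef$target == "y", ]
  expect_equal(xy$direct, 0)
  expect_equal(xy$indirect, fit$B["m", "x"] * fit$B["y", "m"],
               tolerance = 1e-10)
  expect_equal(xy$indirect, 0.2, tolerance = 3 * xy$se_indirect)
  expect_gt(xy$se_indirect, 0)

  # two parallel mediators with opposite products cancel exactly
  m2 <- path_model(c("x", "a", "b", "y"), list(a = "x", b = "x",
                                               y = c("a", "b")))
  B <- matrix(0, 4, 4, dimnames = list(m2$variables, m2$variables))
  B["a", "x"] <- 0.5; B["b", "x"] <- -0.5
  B["y", "a"] <- 0.2; B["y", "b"] <- 0.2
  Sig <- implied_covariance(B, diag(c(1, 0.75, 0.75, 0.9)))
  fit2 <- fit_ml(m2, structure(list(S = Sig, N = 1000, center = "mean",
                                    divisor = "N"),
                               class = "sample_moments"))
  ef2 <- effects(fit2)
  expect_lt(abs(ef2$indirect[ef2$source == "x" & ef2$target == "y"]), 1e-8)

  # total = direct + indirect for every pair of random models
  for (s in 1:5) {
    rr <- random_recursive_model(6, seed = 700 + s, density = 0.6)
    set.seed(800 + s)
    f <- fit_ml(rr$model, sample_moments(mvn_sample(300, rr$truth$Sigma)),
                se = FALSE)
    ee <- effects(f)
    expect_lt(max(abs(ee$total - ee$direct - ee$indirect)), 1e-10)
    expect_lt(max(abs(ee$std_total - ee$std_direct - ee$std_indirect)),
              1e-10)
  }
})

test_that("r-squared follows its definition and skips exogenous variables", {
  m <- path_model(c("x", "y"), list(y = "x"))
  set.seed(52)
  x <- rnorm(5000)
  y <- 0.7 * x + rnorm(5000, sd = sqrt(1 - 0.49))
  fit <- fit_ml(m, sample_moments(cbind(x = x, y = y)))
  r2 <- r_squared(fit)
  expect_named(r2, "y")                      # x is exogenous: absent
  expect_equal(unname(r2), unname(fit$std$B["y", "x"]^2), tolerance = 1e-10)
  expect_equal(unname(r2), 0.49, tolerance = 0.05)
})

test_that("model df counts moments minus free parameters", {
  sat <- path_model(c("a", "b", "c"), list(b = "a", c = c("a", "b")))
  expect_equal(model_df(sat), 0L)
  expect_error(path_model(letters[1:3], list(b = "a"), expected_df = 99),
               "computed df")
  # cycles are rejected outright
  expect_error(path_model(c("a", "b"), list(a = "b", b = "a")), "cycle")
})

test_that("small-sample estimates are unbiased with honest Wald coverage", {
  # 200 samples of size 35 from the 9-variable generator truth
  truth <- example_truth()
  tpl_names <- paste0(rep(rownames(truth$B), ncol(truth$B)),
                      "~", rep(colnames(truth$B), each = nrow(truth$B)))
  free <- which(truth$model$B_free, arr.ind = TRUE)
  true_vals <- truth$B[free]
  names(true_vals) <- paste0(truth$model$variables[free[, 1]], "~",
                             truth$model$variables[free[, 2]])
  set.seed(53)
  est <- cov <- matrix(NA_real_, 200, length(true_vals),
                       dimnames = list(NULL, names(true_vals)))
  for (r in 1:200) {
    d <- mvn_sample(35, truth$Sigma)
    f <- tryCatch(suppressWarnings(fit_ml(truth$model, sample_moments(d))),
                  error = function(e) NULL)
    if (is.null(f)) next
    est[r, ] <- f$theta[names(true_vals)]
    cov[r, ] <- abs(f$theta[names(true_vals)] - true_vals) <=
      stats::qnorm(0.975) * f$se[names(true_vals)]
  }
  bias <- colMeans(est, na.rm = TRUE) - true_vals
  expect_lt(max(abs(bias)), 0.05)
  coverage <- mean(cov, na.rm = TRUE)       # pooled over coefficients
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.985)
})
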