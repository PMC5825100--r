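test_that("the pure-birth simulator yields valid, seeded, ultrametric trees", {
  tr2 <- simulate_tree(2, seed = 61)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)

  a <- ape::write.tree(simulate_tree(36, seed = 62))
  b <- ape::write.tree(simulate_tree(36, seed = 62))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(36, seed = 63))))

  tr <- simulate_tree(50, seed = 64)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length >= 0))
})

test_that("mean root-to-tip depth matches the Yule expectation", {
  n <- 200
  expected <- sum(1 / (2:n))
  depths <- vapply(1:100, function(s) {
    tr <- simulate_tree(n, birth_rate = 1, seed = 9000 + s)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  # depth variance = sum 1/k^2 ~ 0.64, so se(mean over 100) ~ 0.08
  expect_lt(abs(mean(depths) - expected), 0.3)
  # rate scales time linearly
  d5 <- max(ape::node.depth.edgelength(simulate_tree(n, 5, seed = 65)))
  expect_lt(d5, 4)   # ~ expected/5 + noise; a rate-1 tree averages ~ 5.3
})

test_that("Brownian tip differences have the closed-form variance", {
  two <- parse_newick("(A:1.5,B:1.5);")
  set.seed(66)
  diffs <- replicate(1e4, {x <- simulate_bm(two, 2); x[1] - x[2]})
  expect_lt(abs(var(diffs) / (2 * 2 * 1.5) - 1), 0.05)
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("structural simulation with zero coefficients gives independent BM", {
  m <- shipped_models()$model6
  B0 <- matrix(0, 9, 9, dimnames = list(m$variables, m$variables))
  truth0 <- sim_truth(m, B0)
  tr <- simulate_tree(300, seed = 67)
  tab <- simulate_structural(tr, truth0, seed = 68)
  ct <- contrasts_for_table(tr, tab)$contrasts
  cors <- cor(ct)
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(nrow(ct)))
})

test_that("contrast regression recovers a single structural slope", {
  m <- path_model(c("x", "y"), list(y = "x"))
  B <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  B["y", "x"] <- 0.7
  tr <- simulate_tree(500, seed = 69)
  set.seed(70)
  truth <- sim_truth(m, B)
  E <- sapply(truth$psi, function(s2) simulate_bm(tr, s2))
  y <- 0.7 * E[, "x"] + E[, "y"]
  cx <- pic_table(tr, setNames(E[, "x"], tr$tip.label))$contrast
  cy <- pic_table(tr, setNames(y, tr$tip.label))$contrast
  slope <- sum(cx * cy) / sum(cx^2)          # through-origin regression
  se <- sqrt(sum((cy - slope * cx)^2) / (length(cx) - 1) / sum(cx^2))
  expect_lt(abs(slope - 0.7), 3 * se)
})

test_that("whole-study simulation is byte-identical under one seed", {
  d1 <- tempfile("sima"); d2 <- tempfile("simb")
  simulate_study(n_tips = 25, seed = 7, dir = d1)
  simulate_study(n_tips = 25, seed = 7, dir = d2)
  for (f in c("tree.nwk", "traits.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # raw-like output passes table validation untouched
  tab <- simulate_structural(simulate_tree(30, seed = 8), example_truth(),
                             seed = 9, raw_like = TRUE)
  expect_silent(got <- read_trait_csv(write_traits_csv(tab)))
})

test_that("coefficient error shrinks with tree size and CIs stay honest", {
  truth <- example_truth()
  free <- which(truth$model$B_free, arr.ind = TRUE)
  nm <- paste0(truth$model$variables[free[, 1]], "~",
               truth$model$variables[free[, 2]])
  true_vals <- setNames(truth$B[free], nm)
  run <- function(n_tips, reps, seed0, se = FALSE) {
    est <- cov <- matrix(NA_real_, reps, length(nm),
                         dimnames = list(NULL, nm))
    for (r in seq_len(reps)) {
      tr <- simulate_tree(n_tips, seed = seed0 + r)
      tab <- simulate_structural(tr, truth, seed = seed0 + 5000 + r)
      mom <- sample_moments(contrasts_for_table(tr, tab)$contrasts)
      f <- tryCatch(suppressWarnings(fit_ml(truth$model, mom, se = se)),
                    error = function(e) NULL)
      if (is.null(f)) next
      est[r, ] <- f$theta[nm]
      if (se) cov[r, ] <- abs(f$theta[nm] - true_vals) <=
          qnorm(0.975) * f$se[nm]
    }
    list(est = est, cov = cov)
  }
  r35 <- run(35, 60, 100, se = TRUE)
  r100 <- run(100, 30, 300)
  r500 <- run(500, 15, 500)
  rmse <- function(r) sqrt(mean(sweep(r$est, 2, true_vals)^2, na.rm = TRUE))
  expect_gt(rmse(r35), rmse(r100))
  expect_gt(rmse(r100), rmse(r500))
  coverage <- mean(r35$cov, na.rm = TRUE)   # contrast count 34
  expect_gte(coverage, 0.88)
  expect_lte(coverage, 0.99)
})
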