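#' Simulate a pure-birth (Yule) tree
#'
#' Constant-rate pure-birth process: starting from two lineages at the
#' root, each of the k current lineages splits independently at rate
#' `birth_rate`, so epochs with k lineages last Exp(k * birth_rate).
#' Simulation runs until the n-th lineage is born plus one further
#' exponential epoch, so tips extend beyond the last split and the
#' expected root-to-tip depth is `sum_{k=2}^{n} 1/(k * birth_rate)`.
#' The result is binary and ultrametric.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate.
#' @param seed integer seed; the tree is a deterministic function of
#'   `(n_tips, birth_rate, seed)`.
#' @return an [ape::phylo] with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # grow by splitting a uniformly chosen active tip at each event
  max_nodes <- 2 * n_tips - 1
  parent <- integer(max_nodes)
  birth <- numeric(max_nodes)       # time each lineage came into being
  is_tip <- logical(max_nodes)
  root <- 1
  birth[root] <- 0
  kids <- c(2, 3)
  parent[kids] <- root
  birth[kids] <- 0
  is_tip[kids] <- TRUE
  active <- kids
  nxt <- 4
  t_now <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    who <- active[sample.int(k, 1)]
    is_tip[who] <- FALSE
    new <- c(nxt, nxt + 1)
    parent[new] <- who
    birth[new] <- t_now
    is_tip[new] <- TRUE
    active <- c(setdiff(active, who), new)
    nxt <- nxt + 2
  }
  t_end <- t_now + stats::rexp(1, rate = n_tips * birth_rate)
  # assemble an ape phylo: tips first, then root, then internals
  tips <- which(is_tip)
  internals <- setdiff(which(seq_len(max_nodes) <= nxt - 1 & !is_tip), root)
  id <- integer(max_nodes)
  id[tips] <- seq_len(n_tips)
  id[root] <- n_tips + 1
  id[internals] <- n_tips + 1 + seq_along(internals)
  nodes <- c(tips, internals)
  edge <- cbind(id[parent[nodes]], id[nodes])
  # an internal node's end time is the birth time of its children
  child_birth <- numeric(max_nodes)
  child_birth[parent[2:(nxt - 1)]] <- birth[2:(nxt - 1)]
  end_time <- ifelse(is_tip[nodes], t_end, child_birth[nodes])
  len <- end_time - birth[nodes]
  tr <- list(edge = edge, edge.length = len,
             tip.label = paste0("t", seq_len(n_tips)),
             Nnode = n_tips - 1)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate Brownian-motion evolution of one trait
#'
#' Root value 0; the change along each branch is Normal with mean 0 and
#' variance `sigma2 * branch length`.  Under this model the standardized
#' independent contrasts of the tip values are i.i.d.
#' Normal(0, sigma2).
#'
#' @param tree an [ape::phylo].
#' @param sigma2 Brownian rate (> 0).
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0)
}

#' A numeric "truth" for the shipped model-6 structure
#'
#' The shipped model-6 topology with coefficients of the magnitudes
#' reported for the contrast-scale analysis (direct effects on EPP) and
#' inter-predictor coefficients calibrated so each endogenous variable's
#' explained variance is near its reported r-squared.  Residual Brownian
#' rates are chosen so every implied variance is 1, making the
#' coefficients standardized.  Used as the default generator truth in
#' tests and examples.
#'
#' @return a `sim_truth` list: `model` (the `path_model`), `B` (numeric
#'   coefficient matrix) and `psi` (named residual rates).
#' @export
example_truth <- function() {
  model <- shipped_models()[["model6"]]
  v <- model$variables
  B <- matrix(0, length(v), length(v), dimnames = list(v, v))
  B["epp", c("body_size", "altitude_range", "testes_residual", "range_size",
             "song_complexity", "clutch_range", "longevity",
             "male_feeding")] <-
    c(0.003, -0.118, 0.281, 0.280, -0.108, 0.113, -0.521, -0.531)
  B["longevity", "body_size"] <- 0.566
  B["testes_residual", "longevity"] <- 0.310
  B["range_size", c("longevity", "altitude_range")] <- c(-0.550, 0.250)
  B["male_feeding", c("body_size", "longevity", "testes_residual")] <-
    c(-0.150, 0.150, -0.120)
  B["clutch_range", c("body_size", "range_size", "longevity",
                      "male_feeding")] <- c(0.400, 0.350, 0.300, -0.250)
  B["song_complexity", c("range_size", "altitude_range", "clutch_range",
                         "male_feeding")] <- c(0.200, -0.150, 0.250, -0.150)
  sim_truth(model, B)
}

#' Build a generator truth with unit implied variances
#'
#' Given a model topology and numeric coefficients, solves for residual
#' variances that make every implied variance exactly 1 (so the supplied
#' coefficients are the standardized ones).  Exogenous variables get
#' unit variance and are independent.
#'
#' @param model a `path_model`.
#' @param B numeric coefficient matrix (nonzero only where the model has
#'   an edge).
#' @return a `sim_truth` list (`model`, `B`, `psi`, `Sigma`).
#' @export
sim_truth <- function(model, B) {
  v <- model$variables
  stopifnot(all(B[!model$B_free] == 0))
  order_topo <- v[as.integer(igraph::topo_sort(
    igraph::graph_from_adjacency_matrix(t(model$B_free), mode = "directed")))]
  Sigma <- diag(length(v))
  dimnames(Sigma) <- list(v, v)
  psi <- stats::setNames(rep(1, length(v)), v)
  for (tgt in order_topo) {
    if (!tgt %in% model$endogenous) next
    src <- v[model$B_free[tgt, ]]
    b <- B[tgt, src]
    expl <- drop(t(b) %*% Sigma[src, src] %*% b)
    if (expl >= 1)
      stop("coefficients for '", tgt, "' explain variance >= 1 (",
           format(expl, digits = 3), "); shrink them")
    psi[tgt] <- 1 - expl
    cov_with <- Sigma[, src, drop = FALSE] %*% b
    Sigma[, tgt] <- cov_with
    Sigma[tgt, ] <- cov_with
    Sigma[tgt, tgt] <- 1
  }
  structure(list(model = model, B = B, psi = psi, Sigma = Sigma),
            class = "sim_truth")
}

#' Simulate a trait table from linear structural equations on a tree
#'
#' Every exogenous variable and every residual evolves as an independent
#' Brownian motion on the tree (rate = its `psi` entry); endogenous tip
#' values are then assembled as `y = (I - B)^-1 e`.  Because linear
#' combinations of Brownian motions are Brownian, the independent
#' contrasts of the simulated traits satisfy exactly the same structural
#' equations with residual variances equal to the Brownian rates --
#' the data-generating regime the contrast-then-path-analysis workflow
#' assumes.  With `residuals = "iid"` the residuals are instead drawn
#' i.i.d. across tips, deliberately violating that assumption, for
#' robustness probes.
#'
#' @param tree an [ape::phylo].
#' @param truth a `sim_truth` (see [sim_truth()], [example_truth()]).
#' @param seed optional integer seed; output is a deterministic function
#'   of `(tree, truth, seed)`.
#' @param residuals `"bm"` (default) or `"iid"`.
#' @param raw_like if `TRUE`, post-process columns onto raw-data scales
#'   (percentages times 10 squashed into [0, 100], positive range and
#'   altitude via exponentiation) so the table resembles an untransformed
#'   field data set; default returns the structural (contrast-compatible)
#'   scale.
#' @return a `trait_table` with `species` plus the nine trait columns.
#' @export
simulate_structural <- function(tree, truth, seed = NULL,
                                residuals = c("bm", "iid"),
                                raw_like = FALSE) {
  residuals <- match.arg(residuals)
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  v <- truth$model$variables
  n <- length(tree$tip.label)
  E <- sapply(v, function(var) {
    if (residuals == "bm")
      unname(simulate_bm(tree, truth$psi[var])[tree$tip.label])
    else stats::rnorm(n, 0, sqrt(truth$psi[var]))
  })
  A <- solve(diag(length(v)) - truth$B)
  Y <- E %*% t(A)
  colnames(Y) <- v
  out <- data.frame(species = tree$tip.label, Y, stringsAsFactors = FALSE)
  if (raw_like) {
    squash <- function(x) 100 * stats::plogis(x)   # keep percentages legal
    out$epp <- squash(out$epp)
    out$male_feeding <- squash(out$male_feeding)
    out$range_size <- exp(out$range_size)
    out$altitude_range <- exp(out$altitude_range)
    out$body_size <- exp(out$body_size + 3)
    out$longevity <- exp(out$longevity / 2 + 2)
    out$clutch_range <- abs(out$clutch_range)
  }
  out <- out[, c("species", trait_variables())]
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Run a full synthetic-study simulation to disk
#'
#' Generates a Yule tree and a structural trait table and writes
#' `tree.nwk`, `traits.csv` and `truth.json` (coefficients, residual
#' rates, seed) into `dir`.  Byte-identical output for identical
#' `(n_tips, birth_rate, truth, seed)`.
#'
#' @param n_tips,birth_rate tree parameters (see [simulate_tree()]).
#' @param truth a `sim_truth`; default [example_truth()].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisible list with the tree, table and file paths.
#' @export
simulate_study <- function(n_tips = 36, birth_rate = 1,
                           truth = example_truth(), seed = 1,
                           dir = tempfile("simstudy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, birth_rate, seed = seed)
  traits <- simulate_structural(tree, truth, seed = seed + 1)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  utils::write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_tips = n_tips, birth_rate = birth_rate,
         coefficients = as.data.frame(which(truth$model$B_free,
                                            arr.ind = TRUE)) |>
           (\(ix) data.frame(target = rownames(truth$B)[ix$row],
                             source = colnames(truth$B)[ix$col],
                             value = truth$B[as.matrix(ix)]))(),
         residual_rates = as.list(truth$psi)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, traits = traits, dir = dir))
}
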