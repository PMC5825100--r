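# fixtures are built in code; nothing binary ships with the tests

canonical_vars <- sempic::trait_variables()

# a raw-scale trait table whose percentages and sizes satisfy validation
make_raw_traits <- function(n = 20, seed = 1) {
  tr <- simulate_tree(n, seed = seed)
  simulate_structural(tr, example_truth(), seed = seed + 1000,
                      raw_like = TRUE)
}

write_traits_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  path
}

# recordings table for the song module: k recordings per species around
# species-level means
make_song_recordings <- function(n_species = 6, k = 3, seed = 1) {
  set.seed(seed)
  comps <- c("spectral_entropy", "spectral_flatness", "modulation_index",
             "bandwidth", "duration", "total_notes", "unique_notes")
  base <- matrix(runif(n_species * length(comps), 1, 10), n_species,
                 dimnames = list(NULL, comps))
  base[, "duration"] <- runif(n_species, 1, 5)
  base[, "total_notes"] <- sample(5:40, n_species, replace = TRUE)
  base[, "unique_notes"] <- sample(2:15, n_species, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n_species), function(i)
    do.call(rbind, replicate(k, base[i, ] * runif(length(comps), 0.9, 1.1),
                             simplify = FALSE))))
  data.frame(species = rep(paste0("sp", seq_len(n_species)), each = k),
             rows, stringsAsFactors = FALSE)
}

# random recursive path model over p variables with a fixed edge density,
# plus a truth with unit implied variances
random_recursive_model <- function(p, seed, density = 0.4,
                                   exog_cov = "free") {
  set.seed(seed)
  vars <- paste0("v", seq_len(p))
  regs <- list()
  for (i in 2:p) {
    src <- vars[seq_len(i - 1)][runif(i - 1) < density]
    if (i == p && !length(src)) src <- vars[1]   # keep >= 1 endogenous
    if (length(src)) regs[[vars[i]]] <- src
  }
  m <- path_model(vars, regs, exog_cov = exog_cov,
                  name = paste0("rand", seed))
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  B[m$B_free] <- runif(sum(m$B_free), -0.45, 0.45)
  list(model = m, truth = sim_truth(m, B))
}

# MVN sample from a truth's implied covariance (no tree)
mvn_sample <- function(n, Sigma) {
  L <- chol(Sigma)
  x <- matrix(rnorm(n * ncol(Sigma)), n) %*% L
  colnames(x) <- colnames(Sigma)
  x
}

table1_path <- function() {
  system.file("extdata", "table1_species.csv", package = "sempic")
}
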