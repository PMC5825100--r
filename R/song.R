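#' Trill rate of a recording
#'
#' Total notes divided by song duration, in notes per second.
#'
#' @param total_notes note count (>= 0).
#' @param duration song length in seconds (> 0).
#' @return notes per second; vectorized.
#' @export
trill_rate <- function(total_notes, duration) {
  if (any(duration <= 0)) stop("duration must be > 0")
  if (any(total_notes < 0)) stop("total_notes must be >= 0")
  total_notes / duration
}

song_components <- function() {
  c("spectral_entropy", "spectral_flatness", "modulation_index",
    "bandwidth", "duration", "total_notes", "unique_notes", "trill_rate")
}

#' Per-species means of the eight song components
#'
#' Averages each acoustic component over a species' recordings.  The
#' eight components are spectral entropy, spectral flatness, modulation
#' index, bandwidth (Hz), duration (s), total notes, unique notes and
#' trill rate (notes/s); if `trill_rate` is absent it is computed from
#' `total_notes` and `duration` per recording before averaging.
#'
#' @param f data.frame with a `species` column and the component columns,
#'   one row per recording.  Two to five recordings per species is the
#'   intended design; counts outside that range trigger a warning.
#' @return data.frame, one row per species (in first-appearance order),
#'   columns `species` plus the eight component means.
#' @export
species_means <- function(f) {
  stopifnot(is.data.frame(f), "species" %in% names(f))
  if (!"trill_rate" %in% names(f))
    f$trill_rate <- trill_rate(f$total_notes, f$duration)
  comps <- song_components()
  absent <- setdiff(comps, names(f))
  if (length(absent))
    stop("missing component column(s): ", paste(absent, collapse = ", "))
  if (any(f$duration <= 0)) stop("duration must be > 0")
  counts <- table(f$species)
  odd <- names(counts)[counts < 2 | counts > 5]
  if (length(odd))
    warning("species with fewer than 2 or more than 5 recordings: ",
            paste(odd, collapse = ", "))
  sp <- unique(f$species)
  m <- t(vapply(sp, function(s) {
    colMeans(as.matrix(f[f$species == s, comps, drop = FALSE]))
  }, numeric(length(comps))))
  out <- data.frame(species = sp, m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Composite song-complexity score
#'
#' Collapses the eight per-species component means into one unitless
#' score: each component is scaled across species so all components
#' carry equal weight, then the scaled values are summed.  The default
#' scaling is the z-score (mean 0, sd 1, divisor n - 1), under which the
#' scores sum to zero across species and are invariant to affine
#' rescaling of any raw component; min-max scaling to [0, 1] is offered
#' as an alternative.  Scores are comparable only within one scoring run.
#'
#' @param means output of [species_means()] (or any data.frame with
#'   `species` plus the eight component columns); at least 2 species.
#' @param scaling `"zscore"` (default) or `"minmax"`.
#' @return `means` with an appended `song_complexity` column.
#' @export
composite_score <- function(means, scaling = c("zscore", "minmax")) {
  scaling <- match.arg(scaling)
  comps <- song_components()
  stopifnot(is.data.frame(means), all(c("species", comps) %in% names(means)))
  if (nrow(means) < 2) stop("scaling needs at least 2 species")
  x <- as.matrix(means[, comps])
  scaled <- apply(x, 2, function(col) {
    spread <- if (scaling == "zscore") stats::sd(col) else diff(range(col))
    if (spread == 0) return(rep(0, length(col)))
    if (scaling == "zscore") (col - mean(col)) / spread
    else (col - min(col)) / spread
  })
  flat <- colnames(x)[apply(x, 2, function(c) stats::sd(c) == 0)]
  if (length(flat))
    warning("zero-variance component(s) contribute 0: ",
            paste(flat, collapse = ", "))
  means$song_complexity <- rowSums(scaled)
  means
}
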