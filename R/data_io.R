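#' @details
#' The nine analysis variables, in their canonical order.  `epp` is the
#' response (percent of broods with extra-pair young); the other eight are
#' the candidate predictors.
#' @keywords internal
#' @rdname trait_table
#' @export
trait_variables <- function() {
  c("epp", "body_size", "longevity", "male_feeding", "testes_residual",
    "range_size", "altitude_range", "clutch_range", "song_complexity")
}

#' Read and validate a species-by-trait table
#'
#' Reads a CSV holding one row per species and the nine analysis
#' variables: extra-pair paternity rate (`epp`, percent of broods with
#' extra-pair young), `body_size` (g), `longevity` (years),
#' `male_feeding` (percent of broods fed by the male), `testes_residual`
#' (residual of a testes-size-on-body-size regression, so it may be
#' negative), `range_size` (polygon area), `altitude_range` (m,
#' max - min), `clutch_range` (max - min clutch size) and
#' `song_complexity` (unitless composite, see [composite_score()]).
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping canonical variable names
#'   (plus `"species"`) to the column names used in the file.  Defaults
#'   to the identity mapping, i.e. the file already uses the canonical
#'   names.
#' @return A `data.frame` of class `"trait_table"` with a `species`
#'   column and the nine numeric trait columns, rows in file order.
#' @examples
#' tab <- simulate_structural(simulate_tree(12, seed = 1),
#'                            example_truth(), seed = 2)
#' f <- tempfile(fileext = ".csv")
#' write.csv(tab, f, row.names = FALSE)
#' read_trait_csv(f)[1:3, 1:4]
#' @export
read_trait_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c("species", trait_variables())
  if (is.null(schema)) schema <- stats::setNames(wanted, wanted)
  missing_map <- setdiff(wanted, names(schema))
  if (length(missing_map))
    stop("schema does not map column(s): ", paste(missing_map, collapse = ", "))
  absent <- setdiff(unname(schema[wanted]), names(raw))
  if (length(absent))
    stop("column(s) missing from ", path, ": ", paste(absent, collapse = ", "))
  out <- raw[, unname(schema[wanted])]
  names(out) <- wanted
  validate_trait_table(out)
}

validate_trait_table <- function(out) {
  out$species <- as.character(out$species)
  dup <- out$species[duplicated(out$species)]
  if (length(dup))
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  for (v in trait_variables()) {
    col <- out[[v]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value in column '", v, "' for species: ",
             paste(out$species[bad], collapse = ", "))
      col <- num
    }
    if (anyNA(col))
      stop("missing value in column '", v, "' for species: ",
           paste(out$species[is.na(col)], collapse = ", "))
    out[[v]] <- col
  }
  for (v in c("epp", "male_feeding")) {
    bad <- out[[v]] < 0 | out[[v]] > 100
    if (any(bad))
      stop("'", v, "' outside [0, 100] for species: ",
           paste(out$species[bad], collapse = ", "))
  }
  if (any(out$body_size <= 0)) stop("body_size must be > 0")
  if (any(out$longevity <= 0)) stop("longevity must be > 0")
  if (any(out$altitude_range < 0)) stop("altitude_range must be >= 0")
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  attr(out, "transforms") <- NULL
  out
}

#' Apply the study's deterministic variable transforms
#'
#' Divides `epp` and `male_feeding` by 10 (to bring their variances onto
#' the scale of the other variables), natural-log-transforms
#' `range_size`, and natural-log-transforms `altitude_range` after adding
#' `altitude_offset`.  The offset (default 1) keeps species whose
#' recorded altitudinal span is 0 m in the analysis; it is recorded in the
#' returned table's `"transforms"` attribute.  Standardized path
#' coefficients are invariant to the /10 rescaling and to the base of the
#' logarithm.
#'
#' @param t a `trait_table` from [read_trait_csv()].
#' @param altitude_offset value added to `altitude_range` before the log.
#' @return The transformed table, with attribute `"transforms"` listing
#'   what was applied.  Applying the function twice is an error.
#' @export
apply_transforms <- function(t, altitude_offset = 1) {
  stopifnot(inherits(t, "trait_table"))
  if (!is.null(attr(t, "transforms")))
    stop("table is already transformed (see attr(., 'transforms'))")
  if (any(t$range_size <= 0)) stop("range_size must be > 0 before log")
  if (any(t$altitude_range + altitude_offset <= 0))
    stop("altitude_range + offset must be > 0 before log")
  t$epp <- t$epp / 10
  t$male_feeding <- t$male_feeding / 10
  t$range_size <- log(t$range_size)
  t$altitude_range <- log(t$altitude_range + altitude_offset)
  attr(t, "transforms") <- list(
    epp = "divided by 10", male_feeding = "divided by 10",
    range_size = "natural log",
    altitude_range = sprintf("natural log after +%g offset", altitude_offset))
  t
}

#' Pairwise multicollinearity report
#'
#' Pearson correlations between all nine analysis variables, flagging
#' pairs whose absolute correlation exceeds `threshold`.  Strongly
#' collinear predictors destabilize path-coefficient estimates, so
#' flagged pairs deserve a second look before model fitting.
#'
#' @param t a (transformed) `trait_table`; at least 3 rows.
#' @param threshold absolute-correlation flag level (default 0.8).
#' @return A list with `correlations` (symmetric 9 x 9 matrix) and
#'   `flagged` (data.frame of variable pairs with `|r| > threshold`).
#'   Zero-variance columns yield `NA` correlations and a warning.
#' @export
multicollinearity_report <- function(t, threshold = 0.8) {
  stopifnot(inherits(t, "trait_table"))
  if (nrow(t) < 3) stop("need at least 3 species")
  x <- as.matrix(t[, trait_variables()])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r)[sds > 0] <- 1
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[idx[, 1]],
                        var2 = colnames(r)[idx[, 2]],
                        r = r[idx], stringsAsFactors = FALSE)
  list(correlations = r, flagged = flagged[order(-abs(flagged$r)), ])
}

#' Write a transformed trait table with a transform sidecar
#'
#' @param t a `trait_table`.
#' @param path output CSV path; a JSON sidecar `<path>.json` records the
#'   transforms applied.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(t, path) {
  stopifnot(inherits(t, "trait_table"))
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  tr <- attr(t, "transforms")
  jsonlite::write_json(list(transforms = if (is.null(tr)) "none" else tr),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
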