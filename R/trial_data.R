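#' @keywords internal
"_PACKAGE"

# Column contracts for the three delimited-table schemas. Dead trees keep
# their provenance/block identity but carry NA measurements, so plot counts
# and the harmonic-mean correction can be computed from one table.
.schemas <- list(
  growth = list(
    required = c("provenance", "block", "tree", "alive", "dbh", "height"),
    optional = c("volume"),
    numeric  = c("block", "tree", "dbh", "height", "volume")
  ),
  wood = list(
    required = c("provenance", "tree", "fl", "fd", "vl", "vd", "wbd", "cr"),
    optional = c("fl_fd", "vl_vd", "w1", "w2", "iu", "ia"),
    numeric  = c("tree", "fl", "fd", "vl", "vd", "wbd", "cr",
                 "fl_fd", "vl_vd", "w1", "w2", "iu", "ia")
  ),
  provenance = list(
    required = c("code", "latitude", "longitude"),
    optional = c("altitude", "annual_mean_temp", "min_temp", "max_temp",
                 "frostless_period", "annual_precip"),
    numeric  = c("latitude", "longitude", "altitude", "annual_mean_temp",
                 "min_temp", "max_temp", "frostless_period", "annual_precip")
  )
)

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.coerce_numeric <- function(x, column, allow_na = TRUE) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & toupper(raw) != "NA" & is.na(out))
  if (length(bad)) {
    # +1 for the header row, so the message points at the file line
    stop(sprintf("non-numeric value '%s' in column '%s' on line %d",
                 raw[bad[1]], column, bad[1] + 1L), call. = FALSE)
  }
  out
}

#' Read a delimited provenance-trial table
#'
#' Reads one of the three trial tables: `growth` (one row per planted tree:
#' provenance, block, tree, alive flag, DBH in cm, height in m, optional
#' volume in m\eqn{^3}), `wood` (one row per cored tree: fiber and vessel
#' dimensions in \eqn{\mu}m, wood basic density in g/cm\eqn{^3},
#' crystallinity in %, optional raw lab quantities `w1`, `w2`, `iu`, `ia`),
#' or `provenance` (code, latitude/longitude in decimal degrees, altitude
#' and climate covariates).
#'
#' Comma-separated files with a header row are the native format; tabs are
#' accepted on read. Header matching is case-insensitive. Dead trees
#' (`alive` = 0/FALSE) must carry missing measurements; live trees must have
#' positive DBH and height.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema One of `"growth"`, `"wood"`, `"provenance"`.
#' @param provenances Optional provenance table (as returned with
#'   `schema = "provenance"`); if supplied, provenance codes in the growth
#'   or wood table are checked against it.
#' @return A validated `data.frame` with an attribute `schema`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(provenance = "A", block = 1, tree = 1:2,
#'                      alive = c(TRUE, FALSE), dbh = c(10, NA),
#'                      height = c(9, NA)), f, row.names = FALSE)
#' read_trial_table(f, "growth")
#' @export
read_trial_table <- function(path, schema = c("growth", "wood", "provenance"),
                             provenances = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- .schemas[[schema]]
  df <- utils::read.csv(path, sep = .detect_sep(path), check.names = FALSE,
                        colClasses = "character", na.strings = c("NA", ""))
  names(df) <- tolower(trimws(names(df)))
  missing_cols <- setdiff(spec$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema '%s': missing mandatory column(s): %s", schema,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  keep <- intersect(c(spec$required, spec$optional), names(df))
  df <- df[, keep, drop = FALSE]
  for (col in intersect(spec$numeric, names(df))) {
    df[[col]] <- .coerce_numeric(df[[col]], col)
  }
  if (schema == "growth") {
    df$alive <- .parse_logical(df$alive)
    df$provenance <- as.character(df$provenance)
    .validate_growth_rows(df)
  } else if (schema == "wood") {
    df$provenance <- as.character(df$provenance)
    .validate_wood_rows(df)
  } else {
    df$code <- as.character(df$code)
    .validate_provenance_rows(df)
  }
  if (!is.null(provenances) && schema %in% c("growth", "wood")) {
    unknown <- setdiff(unique(df$provenance), provenances$code)
    if (length(unknown)) {
      stop("provenance code(s) not in the provenance table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "schema") <- schema
  df
}

.parse_logical <- function(x) {
  raw <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[raw %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column 'alive': unparseable value on line %d",
                 which(is.na(out))[1] + 1L), call. = FALSE)
  }
  out
}

.validate_growth_rows <- function(df) {
  bad <- which(df$alive & (is.na(df$dbh) | df$dbh <= 0 |
                             is.na(df$height) | df$height <= 0))
  if (length(bad)) {
    stop(sprintf("live tree with missing or non-positive dbh/height on line %d",
                 bad[1] + 1L), call. = FALSE)
  }
  if ("volume" %in% names(df)) {
    mism <- which(xor(is.na(df$volume), is.na(df$dbh) | is.na(df$height)))
    if (length(mism)) {
      stop(sprintf("volume must be present exactly when dbh and height are (line %d)",
                   mism[1] + 1L), call. = FALSE)
    }
  }
  invisible(df)
}

.validate_wood_rows <- function(df) {
  for (col in c("fl", "fd", "vl", "vd")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("column '%s' must be positive (line %d)", col, bad[1] + 1L),
           call. = FALSE)
    }
  }
  bad <- which(!is.na(df$wbd) & (df$wbd <= 0 | df$wbd >= 1.5))
  if (length(bad)) {
    stop(sprintf("wbd outside (0, 1.5) g/cm3 (line %d)", bad[1] + 1L),
         call. = FALSE)
  }
  bad <- which(!is.na(df$cr) & (df$cr < 0 | df$cr > 100))
  if (length(bad)) {
    stop(sprintf("cr outside [0, 100] %% (line %d)", bad[1] + 1L), call. = FALSE)
  }
  # stored ratios must agree with their parts to 0.5%
  for (pair in list(c("fl_fd", "fl", "fd"), c("vl_vd", "vl", "vd"))) {
    r <- pair[1]
    if (r %in% names(df)) {
      expect <- df[[pair[2]]] / df[[pair[3]]]
      ok <- is.na(df[[r]]) | is.na(expect) |
        abs(df[[r]] - expect) <= 0.005 * abs(expect)
      if (!all(ok)) {
        stop(sprintf("stored %s disagrees with %s/%s by more than 0.5%% (line %d)",
                     r, pair[2], pair[3], which(!ok)[1] + 1L), call. = FALSE)
      }
    }
  }
  invisible(df)
}

.validate_provenance_rows <- function(df) {
  if (anyDuplicated(df$code)) {
    stop("duplicate provenance code: ",
         df$code[duplicated(df$code)][1], call. = FALSE)
  }
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  invisible(df)
}

#' Write a provenance-trial table
#'
#' Writes CSV with a header row and RFC-4180-style quoting; the inverse of
#' [read_trial_table()] (round-trip identity for all three schemas).
#'
#' @param records Table as returned by [read_trial_table()] or built in code.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Summarize a trial's design and surviving plot counts
#'
#' Tabulates the randomized-complete-block layout implied by a growth table:
#' the number of provenances `p`, blocks `b`, planted trees per plot `n`,
#' and the matrix `n_ij` of surviving trees per (block, provenance) plot.
#' `n_ij` drives the harmonic-mean plot size used in provenance
#' heritability ([harmonic_mean_n()]).
#'
#' @param records Growth-schema records (one row per planted tree).
#' @param n_planted Planted trees per plot; defaults to the maximum observed
#'   plot count (alive + dead).
#' @return An object of class `trial_design`: list with `p`, `b`, `n`,
#'   `n_ij` (b x p matrix of surviving counts), `empty_plots`, and
#'   `single_block_provenances`.
#' @export
validate_trial <- function(records, n_planted = NULL) {
  stopifnot(is.data.frame(records))
  if (!any(records$alive)) stop("no live trees in the trial", call. = FALSE)
  blocks <- sort(unique(records$block))
  provs <- sort(unique(records$provenance))
  alive <- records[records$alive, , drop = FALSE]
  n_ij <- table(factor(alive$block, levels = blocks),
                factor(alive$provenance, levels = provs))
  n_ij <- matrix(as.integer(n_ij), nrow = length(blocks),
                 dimnames = list(block = blocks, provenance = provs))
  planted <- table(factor(records$block, levels = blocks),
                   factor(records$provenance, levels = provs))
  if (is.null(n_planted)) n_planted <- max(planted)
  single <- provs[colSums(n_ij > 0) <= 1]
  if (length(single)) {
    warning("provenance(s) observed alive in a single block (PB effect confounded): ",
            paste(single, collapse = ", "), call. = FALSE)
  }
  structure(list(p = length(provs), b = length(blocks), n = n_planted,
                 n_ij = n_ij,
                 empty_plots = which(n_ij == 0, arr.ind = TRUE),
                 single_block_provenances = single),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Provenance trial design: %d provenances x %d blocks, %d planted/plot\n",
              x$p, x$b, x$n))
  cat(sprintf("Surviving trees: %d (%d empty plots); harmonic mean plot size %.3f\n",
              sum(x$n_ij), nrow(x$empty_plots), harmonic_mean_n(x)))
  invisible(x)
}

#' Load one of the bundled reference summary tables
#'
#' Provenance-level reference values for the southern-China
#' *Neolamarckia cadamba* provenance trial analysed by this package:
#' per-provenance growth and wood summaries with Duncan letters
#' (`"growth_summary"`, `"wood_summary"`), variance components with
#' heritabilities (`"variance_components"`), overall/superior means and
#' realized gains (`"gain"`), provenance coordinates and climate
#' (`"locations"`), and fitted trend-surface coefficients
#' (`"trend_surface"`).
#'
#' @param name Table name (see Description).
#' @return A `data.frame`.
#' @export
reference_table <- function(name = c("growth_summary", "wood_summary",
                                     "variance_components", "gain",
                                     "locations", "trend_surface")) {
  name <- match.arg(name)
  file <- switch(name,
                 growth_summary = "growth_summary.csv",
                 wood_summary = "wood_summary.csv",
                 variance_components = "variance_components.csv",
                 gain = "gain_reference.csv",
                 locations = "provenance_locations.csv",
                 trend_surface = "trend_surface_reference.csv")
  path <- system.file("extdata", file, package = "provtrial", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
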