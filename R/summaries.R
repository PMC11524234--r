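#' Per-provenance descriptive statistics for one trait
#'
#' Mean, standard error, minimum, maximum and coefficient of variation
#' (100 x sample SD / mean, using the n-1 denominator) per provenance, plus
#' an `Overall` row whose mean and SE are the unweighted mean of the
#' provenance means and its standard error across provenances — the
#' convention used for the overall thresholds in superior-provenance
#' selection.
#'
#' @param records Growth- or wood-schema records; dead trees are dropped.
#' @param trait Column name of the trait.
#' @return A `data.frame` with columns `provenance`, `n`, `mean`, `se`,
#'   `min`, `max`, `cv`, and a logical `flagged` for provenances with fewer
#'   than 2 observations (CV undefined).
#' @export
provenance_descriptives <- function(records, trait) {
  stopifnot(trait %in% names(records))
  if ("alive" %in% names(records)) records <- records[records$alive, , drop = FALSE]
  records <- records[!is.na(records[[trait]]), , drop = FALSE]
  if (!nrow(records)) stop("no observations for trait ", trait, call. = FALSE)
  sp <- split(records[[trait]], records$provenance)
  rows <- lapply(names(sp), function(pv) {
    x <- sp[[pv]]
    n <- length(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    data.frame(provenance = pv, n = n, mean = mean(x),
               se = if (n >= 2) s / sqrt(n) else NA_real_,
               min = min(x), max = max(x),
               cv = if (n >= 2) 100 * s / mean(x) else NA_real_,
               flagged = n < 2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$provenance), , drop = FALSE]
  pm <- out$mean
  overall <- data.frame(provenance = "Overall", n = sum(out$n),
                        mean = mean(pm),
                        se = stats::sd(pm) / sqrt(length(pm)),
                        min = min(out$min), max = max(out$max),
                        cv = NA_real_, flagged = FALSE,
                        stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, overall)
}

#' Cross-provenance variation summary
#'
#' `mean_cv` is the arithmetic mean of the per-provenance CVs. The fold
#' ratio is max/min for the provenance with the widest absolute range
#' (max - min); provenances with a non-positive minimum are skipped with a
#' warning since their ratio is undefined.
#'
#' @param descriptives Output of [provenance_descriptives()] (the `Overall`
#'   row, if present, is ignored).
#' @return A list with `mean_cv`, `fold_ratio`, `widest_range_provenance`.
#' @export
trait_variation_summary <- function(descriptives) {
  d <- descriptives[descriptives$provenance != "Overall", , drop = FALSE]
  if (!nrow(d)) stop("no provenances", call. = FALSE)
  mean_cv <- mean(d$cv, na.rm = TRUE)
  ok <- d$min > 0
  if (!all(ok)) {
    warning("provenance(s) with non-positive minimum skipped for fold ratio: ",
            paste(d$provenance[!ok], collapse = ", "), call. = FALSE)
  }
  d <- d[ok, , drop = FALSE]
  if (!nrow(d)) {
    return(list(mean_cv = mean_cv, fold_ratio = NA_real_,
                widest_range_provenance = NA_character_))
  }
  widest <- which.max(d$max - d$min)
  list(mean_cv = mean_cv,
       fold_ratio = d$max[widest] / d$min[widest],
       widest_range_provenance = d$provenance[widest])
}

# Duncan step-k critical range: studentized-range quantile at the
# protection level (1 - alpha)^(k - 1) times the standard error of a mean.
.duncan_ranges <- function(ks, df_e, ms_e, n_e, alpha) {
  q <- stats::qtukey((1 - alpha)^(ks - 1), ks, df_e)
  q * sqrt(ms_e / n_e)
}

#' Duncan's multiple range test across provenances
#'
#' One-way (provenance) ANOVA on the trait supplies the residual mean
#' square; provenance means are ranked in descending order and every span of
#' k adjacent means is compared against the critical range
#' \eqn{q^*(\alpha_k, k, df_e)\sqrt{MS_e/n_e}} with Duncan's protection
#' level \eqn{\alpha_k = 1-(1-\alpha)^{k-1}}, where \eqn{q^*} is the
#' studentized-range quantile and \eqn{n_e} the harmonic mean of group
#' sizes (the common convention for unequal plot survival). Maximal
#' homogeneous spans receive one letter each, so provenances sharing a
#' letter are not significantly different and letters are contiguous over
#' the ranked means.
#'
#' @param records Records table (dead trees dropped if an `alive` column is
#'   present).
#' @param trait Trait column name.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `duncan_mrt`: `table` (provenance, n, mean,
#'   letters, sorted by descending mean with ties broken by code), `alpha`,
#'   `ms_e`, `df_e`, `n_e`, `critical_ranges`.
#' @export
duncan_mrt <- function(records, trait, alpha = 0.05) {
  if ("alive" %in% names(records)) records <- records[records$alive, , drop = FALSE]
  records <- records[!is.na(records[[trait]]), , drop = FALSE]
  g <- factor(records$provenance)
  if (nlevels(g) < 2) stop("need at least 2 provenances", call. = FALSE)
  y <- records[[trait]]
  fit <- stats::aov(y ~ g)
  df_e <- fit$df.residual
  if (df_e < 1) stop("no residual degrees of freedom", call. = FALSE)
  ms_e <- sum(stats::residuals(fit)^2) / df_e
  ns <- tapply(y, g, length)
  n_e <- length(ns) / sum(1 / ns)
  means <- tapply(y, g, mean)
  ord <- order(-means, names(means))
  means <- means[ord]
  k <- length(means)

  if (ms_e <= 0) {
    # degenerate: distinct groups unless exactly equal
    grp <- match(means, unique(means))
    letters_out <- letters[grp]
  } else {
    ranges <- c(0, .duncan_ranges(2:k, df_e, ms_e, n_e, alpha))
    # maximal homogeneous spans: [i, j] homogeneous if the endpoint
    # difference is below the critical range for its span length
    ends <- integer(k)
    for (i in seq_len(k)) {
      j <- i
      while (j < k && (means[i] - means[j + 1]) <= ranges[j + 2 - i]) j <- j + 1
      ends[i] <- j
    }
    spans <- unique(do.call(rbind, lapply(seq_len(k), function(i) c(i, ends[i]))))
    keep <- vapply(seq_len(nrow(spans)), function(r) {
      !any(spans[, 1] <= spans[r, 1] & spans[, 2] >= spans[r, 2] &
             (spans[, 1] < spans[r, 1] | spans[, 2] > spans[r, 2]))
    }, logical(1))
    spans <- spans[keep, , drop = FALSE]
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    letters_out <- vapply(seq_len(k), function(i) {
      paste0(letters[which(spans[, 1] <= i & spans[, 2] >= i)], collapse = "")
    }, character(1))
  }
  tab <- data.frame(provenance = names(means), n = as.integer(ns[ord]),
                    mean = as.numeric(means), letters = letters_out,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, ms_e = ms_e, df_e = df_e,
                 n_e = n_e),
            class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, MS_e = %.4g, df = %d)\n",
              x$alpha, x$ms_e, x$df_e))
  print(x$table, row.names = FALSE)
  invisible(x)
}
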