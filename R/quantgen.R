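#' Provenance heritability
#'
#' \eqn{h^2 = V_P / (V_e/(n_h b) + V_{PB}/b + V_P)}: the fraction of
#' among-provenance-mean variance attributable to provenance effects, with
#' the harmonic-mean plot size \eqn{n_h} correcting for unequal survival.
#' For the wood-trait model (no block replication) `v_pb` is 0.
#'
#' @param v_p Provenance variance (or a `varcomp` object, in which case the
#'   remaining component arguments are taken from it).
#' @param v_pb Provenance-by-block interaction variance (default 0).
#' @param v_e Residual variance.
#' @param n_h Harmonic-mean number of trees per plot (see
#'   [harmonic_mean_n()]).
#' @param b Number of blocks.
#' @return Heritability in `[0, 1]`.
#' @examples
#' provenance_heritability(0.47, 0.08, 8.97, n_h = 4, b = 10)  # 0.67
#' @export
provenance_heritability <- function(v_p, v_pb = 0, v_e, n_h, b) {
  if (inherits(v_p, "varcomp")) {
    vc <- v_p
    v_pb <- vc_estimate(vc, "v_pb")
    v_e <- vc_estimate(vc, "v_e")
    v_p <- vc_estimate(vc, "v_p")
  }
  stopifnot(v_p >= 0, v_pb >= 0, v_e >= 0, n_h > 0, b >= 1)
  denom <- v_e / (n_h * b) + v_pb / b + v_p
  if (denom == 0) stop("all variance components are zero", call. = FALSE)
  v_p / denom
}

#' Genetic variation coefficient
#'
#' \eqn{CV_G = 100\sqrt{V_P}/\bar X}: exploitable genetic variation on a
#' scale-free percent scale.
#'
#' @param v_p Provenance variance (>= 0).
#' @param trait_mean Trait phenotypic mean (> 0).
#' @return Percent.
#' @export
genetic_cv <- function(v_p, trait_mean) {
  if (trait_mean <= 0) stop("trait_mean must be positive", call. = FALSE)
  if (v_p < 0) stop("v_p must be non-negative", call. = FALSE)
  100 * sqrt(v_p) / trait_mean
}

.delta_se_rg <- function(cov_p, v1, v2, se_cov_inputs) {
  # r = (Vs - V1 - V2) / (2 sqrt(V1 V2)) with Vs = V1 + V2 + 2 cov
  r <- cov_p / sqrt(v1 * v2)
  g <- c(vs = 1 / (2 * sqrt(v1 * v2)),
         v1 = -1 / (2 * sqrt(v1 * v2)) - r / (2 * v1),
         v2 = -1 / (2 * sqrt(v1 * v2)) - r / (2 * v2))
  sqrt(sum(g^2 * se_cov_inputs^2))
}

#' Genetic correlation between two traits
#'
#' \eqn{r_g = Cov_{P}(1,2) / \sqrt{V_{P1} V_{P2}}} from the provenance
#' covariance component. The SE is a delta-method approximation propagating
#' the average-information SEs of the three provenance variances behind the
#' variance-of-sum identity, treating them as independent. If either
#' provenance variance is at the zero boundary the correlation is NE.
#'
#' @param cc A `covcomp` from [fit_bivariate_reml()].
#' @return A list with `estimate`, `se`, `ne`.
#' @export
genetic_correlation <- function(cc) {
  stopifnot(inherits(cc, "covcomp"))
  if (cc$ne) return(list(estimate = NA_real_, se = NA_real_, ne = TRUE))
  v1 <- vc_estimate(cc$fit1, "v_p")
  v2 <- vc_estimate(cc$fit2, "v_p")
  if (v1 <= 0 || v2 <= 0) return(list(estimate = NA_real_, se = NA_real_, ne = TRUE))
  r <- cc$cov_p / sqrt(v1 * v2)
  ses <- c(cc$fit_sum$components$se[cc$fit_sum$components$component == "v_p"],
           cc$fit1$components$se[cc$fit1$components$component == "v_p"],
           cc$fit2$components$se[cc$fit2$components$component == "v_p"])
  se <- if (anyNA(ses)) NA_real_ else .delta_se_rg(cc$cov_p, v1, v2, ses)
  list(estimate = max(min(r, 1), -1), se = se, ne = FALSE)
}

#' Phenotypic correlation between two traits
#'
#' \eqn{r_P = (Cov_P + Cov_e) / \sqrt{(V_{P1}+V_{e1})(V_{P2}+V_{e2})}}.
#' The provenance-by-block component does not enter this expression; the
#' phenotypic variance here is the provenance plus residual variance.
#'
#' @param cc A `covcomp` from [fit_bivariate_reml()].
#' @return A list with `estimate`, `se` (delta-method approximation), `ne`.
#' @export
phenotypic_correlation <- function(cc) {
  stopifnot(inherits(cc, "covcomp"))
  v1 <- vc_estimate(cc$fit1, "v_p") + vc_estimate(cc$fit1, "v_e")
  v2 <- vc_estimate(cc$fit2, "v_p") + vc_estimate(cc$fit2, "v_e")
  if (v1 <= 0 || v2 <= 0) stop("zero total variance", call. = FALSE)
  cov_p <- if (cc$ne) 0 else cc$cov_p   # NE provenance covariance counts as 0
  r <- (cov_p + cc$cov_e) / sqrt(v1 * v2)
  se_tot <- function(f) {
    s <- f$components$se[f$components$component %in% c("v_p", "v_e")]
    if (anyNA(s)) NA_real_ else sqrt(sum(s^2))
  }
  s1 <- se_tot(cc$fit1); s2 <- se_tot(cc$fit2); ss <- se_tot(cc$fit_sum)
  se <- if (anyNA(c(s1, s2, ss))) NA_real_ else
    .delta_se_rg((cov_p + cc$cov_e), v1, v2, c(ss, s1, s2))
  list(estimate = max(min(r, 1), -1), se = se, ne = FALSE)
}

#' Full genetic/phenotypic correlation matrix
#'
#' Pairwise [fit_bivariate_reml()] across a trait list; genetic correlations
#' above the diagonal, phenotypic below.
#'
#' @param records Records with all trait columns.
#' @param traits Character vector of trait column names.
#' @param model `"growth"` or `"wood"`.
#' @param ... Passed to [fit_bivariate_reml()].
#' @return A list with matrices `r_g`, `r_g_se`, `r_p`, `r_p_se`, and a
#'   combined display matrix `table` (genetic above, phenotypic below).
#' @export
correlation_matrix <- function(records, traits, model = c("growth", "wood"),
                               ...) {
  model <- match.arg(model)
  k <- length(traits)
  rg <- rp <- rg_se <- rp_se <- matrix(NA_real_, k, k,
                                       dimnames = list(traits, traits))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cc <- fit_bivariate_reml(records, traits[i], traits[j], model, ...)
      g <- genetic_correlation(cc); p <- phenotypic_correlation(cc)
      rg[i, j] <- g$estimate; rg_se[i, j] <- g$se
      rp[j, i] <- p$estimate; rp_se[j, i] <- p$se
    }
  }
  display <- rg
  display[lower.tri(display)] <- rp[lower.tri(rp)]
  list(r_g = rg, r_g_se = rg_se, r_p = rp, r_p_se = rp_se, table = display)
}

#' Realized gain of truncation selection
#'
#' \eqn{G = 100 (\bar X_i - \bar X)/\bar X}: percent change of the selected
#' provenances' mean over the overall mean. Scale-invariant.
#'
#' @param superior_mean Mean of the selected (superior) provenances.
#' @param overall_mean Overall trait mean (non-zero).
#' @return Percent gain. Vectorized.
#' @examples
#' realized_gain(0.09, 0.08)  # 12.5
#' @export
realized_gain <- function(superior_mean, overall_mean) {
  if (any(overall_mean == 0)) stop("overall_mean must be non-zero", call. = FALSE)
  100 * (superior_mean - overall_mean) / overall_mean
}

#' Two-trait superior-provenance selection
#'
#' Selects the provenances whose means strictly exceed the overall means of
#' both selection traits (the overall mean being the unweighted mean of the
#' provenance means), then reports realized gains for every trait using the
#' unweighted mean of the selected provenances' means.
#'
#' @param provenance_means `data.frame` with a `provenance` column and one
#'   numeric column per trait (one row per provenance).
#' @param trait_a,trait_b Names of the two selection traits.
#' @param purpose Label for the report (e.g. "wood products", "pulpwood").
#' @return An object of class `gain_report`: `purpose`, `selection_traits`,
#'   `superior` (selected provenance codes, possibly empty), and `table`
#'   with per-trait `overall_mean`, `superior_mean`, `gain`.
#' @export
select_superior <- function(provenance_means, trait_a, trait_b,
                            purpose = paste(trait_a, "+", trait_b)) {
  stopifnot(all(c("provenance", trait_a, trait_b) %in% names(provenance_means)))
  traits <- setdiff(names(provenance_means), "provenance")
  overall <- vapply(provenance_means[traits], mean, numeric(1))
  sel <- provenance_means[[trait_a]] > overall[[trait_a]] &
    provenance_means[[trait_b]] > overall[[trait_b]]
  superior <- provenance_means$provenance[sel]
  if (any(sel)) {
    sup_mean <- vapply(provenance_means[sel, traits, drop = FALSE], mean,
                       numeric(1))
    gain <- realized_gain(sup_mean, overall)
  } else {
    sup_mean <- gain <- stats::setNames(rep(NA_real_, length(traits)), traits)
  }
  structure(list(purpose = purpose,
                 selection_traits = c(trait_a, trait_b),
                 superior = superior,
                 table = data.frame(trait = traits,
                                    overall_mean = unname(overall),
                                    superior_mean = unname(sup_mean),
                                    gain = unname(gain),
                                    stringsAsFactors = FALSE)),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("Superior-provenance selection (%s) on %s and %s\n",
              x$purpose, x$selection_traits[1], x$selection_traits[2]))
  if (length(x$superior)) {
    cat("Selected:", paste(x$superior, collapse = ", "), "\n")
    tab <- x$table
    tab$overall_mean <- signif(tab$overall_mean, 6)
    tab$superior_mean <- signif(tab$superior_mean, 6)
    tab$gain <- round(tab$gain, 2)
    print(tab, row.names = FALSE)
  } else {
    cat("No provenance passes both thresholds.\n")
  }
  invisible(x)
}
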