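#' Harmonic-mean plot size of an unbalanced trial
#'
#' \eqn{n_h = m / \sum_{ij} (1/n_{ij})} over the m non-empty plots: the
#' harmonic mean of surviving plot counts, which replaces the planted plot
#' size in provenance heritability when mortality unbalances the design.
#' Empty plots are excluded from the sum with the plot count reduced
#' accordingly (the formula is undefined for them).
#'
#' @param design A `trial_design` from [validate_trial()], or a numeric
#'   matrix/vector of per-plot survivor counts `n_ij`.
#' @return The harmonic-mean number of trees per plot.
#' @examples
#' harmonic_mean_n(c(2, 4, 4, 4))  # 3.2
#' @export
harmonic_mean_n <- function(design) {
  n_ij <- if (inherits(design, "trial_design")) design$n_ij else design
  n_ij <- as.numeric(n_ij)
  counted <- n_ij > 0
  if (!any(counted)) stop("all plots are empty", call. = FALSE)
  sum(counted) / sum(1 / n_ij[counted])
}

# ---- REML engine -----------------------------------------------------------
# Restricted maximum likelihood for y = Xb + sum_k Z_k u_k + e with
# u_k ~ N(0, sigma_k^2 I) and e ~ N(0, sigma_e^2 I). Average-information
# updates accelerate a monotone EM baseline; any AI step that would lower
# the restricted loglik or leave the parameter space falls back to EM, so
# the loglik trace is non-decreasing. Components pinned at the zero
# boundary for several consecutive iterations are dropped and flagged
# (reported as 0 with `boundary = TRUE`, the "not estimated, assumed zero"
# convention), and iteration continues without them.

.reml_state <- function(sigma, G, X, y, n, K) {
  V <- diag(sigma[K + 1L], n)
  for (k in seq_len(K)) if (sigma[k] > 0) V <- V + sigma[k] * G[[k]]
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(ll = -Inf))
  Vinv <- chol2inv(L)
  ViX <- Vinv %*% X
  XtViX <- crossprod(X, ViX)
  ldx <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  P <- Vinv - ViX %*% solve(XtViX, t(ViX))
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(L))) + ldx + sum(y * Py))
  list(ll = ll, P = P, Py = Py)
}

.reml_engine <- function(y, X, Zlist, tol = 1e-8, loglik_tol = 1e-10,
                         max_iter = 500L, pin_iters = 5L) {
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)
  K <- length(Zlist)
  G <- lapply(Zlist, tcrossprod)
  q <- vapply(Zlist, ncol, integer(1))
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("response is constant", call. = FALSE)

  sigma <- c(rep(vy / (2 * K), K), vy / 2)
  active <- rep(TRUE, K)
  pinned <- integer(K)
  pin_floor <- 1e-7 * vy
  trace <- numeric(0)
  st <- .reml_state(sigma, G, X, y, n, K)
  if (!is.finite(st$ll)) stop("initial covariance not positive definite", call. = FALSE)

  grad_score <- function(st, sigma) {
    # score and AI over active random components + residual
    idx <- c(which(active), K + 1L)
    W <- matrix(0, n, length(idx))
    score <- numeric(length(idx))
    for (j in seq_along(idx)) {
      k <- idx[j]
      if (k <= K) {
        W[, j] <- G[[k]] %*% st$Py
        trPG <- sum(st$P * G[[k]])
      } else {
        W[, j] <- st$Py
        trPG <- sum(diag(st$P))
      }
      score[j] <- 0.5 * (sum(st$Py * W[, j]) - trPG)
    }
    AI <- 0.5 * crossprod(W, st$P %*% W)
    list(idx = idx, score = score, AI = AI)
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    trace <- c(trace, st$ll)
    gs <- grad_score(st, sigma)
    qs <- c(q, n)[gs$idx]

    # damped AI step: cap the step length so no component crosses zero
    # (a capped component lands at a tenth of its current value, which
    # walks a boundary component down geometrically), then halve on any
    # loglik decrease; monotone EM is the fallback of last resort
    cand <- sigma
    shrinking <- FALSE
    accepted <- FALSE
    delta <- tryCatch(solve(gs$AI, gs$score), error = function(e) NULL)
    if (!is.null(delta)) {
      cur <- sigma[gs$idx]
      tiny <- cur <= 10 * pin_floor
      crossing <- !tiny & (cur + delta <= 0)
      shrinking <- any(crossing | (tiny & delta < 0))
      h <- 1
      if (any(crossing)) h <- min(0.9 * cur[crossing] / -delta[crossing])
      for (try in 1:6) {
        prop <- cur + h * delta
        prop[tiny & prop < pin_floor / 2] <- pin_floor / 2
        if (all(prop > 0)) {
          cand[gs$idx] <- prop
          st_cand <- .reml_state(cand, G, X, y, n, K)
          if (is.finite(st_cand$ll) && st_cand$ll >= st$ll - 1e-8) {
            accepted <- TRUE
            break
          }
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      # monotone EM fallback
      cand <- sigma
      cand[gs$idx] <- pmax(sigma[gs$idx] + 2 * sigma[gs$idx]^2 / qs * gs$score,
                           1e-12 * vy)
      st_cand <- .reml_state(cand, G, X, y, n, K)
    }

    rel_change <- max(abs(cand - sigma) / pmax(abs(sigma), pin_floor))
    ll_change <- st_cand$ll - st$ll
    sigma <- cand
    st <- st_cand

    # boundary bookkeeping: drop a component pinned near zero
    for (k in which(active)) {
      pinned[k] <- if (sigma[k] < pin_floor) pinned[k] + 1L else 0L
      if (pinned[k] >= pin_iters) {
        active[k] <- FALSE
        sigma[k] <- 0
        st <- .reml_state(sigma, G, X, y, n, K)
        shrinking <- FALSE
      }
    }

    # while a component is being walked down to the boundary the loglik
    # plateaus; do not let that plateau read as convergence
    plateau_ok <- !shrinking || iter >= max_iter %/% 2L
    if (rel_change < tol || (plateau_ok && abs(ll_change) < loglik_tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  # components that converged essentially at zero are boundary cases
  for (k in which(active)) {
    if (sigma[k] < 1e-6 * vy) {
      active[k] <- FALSE
      sigma[k] <- 0
      st <- .reml_state(sigma, G, X, y, n, K)
    }
  }
  trace <- c(trace, st$ll)
  if (!converged) {
    gs <- grad_score(st, sigma)
    stop(sprintf(paste0("REML did not converge in %d iterations ",
                        "(gradient norm %.3e, last estimates: %s)"),
                 max_iter, sqrt(sum(gs$score^2)),
                 paste(signif(sigma, 6), collapse = ", ")), call. = FALSE)
  }

  # SEs from the inverse average information over all components, evaluated
  # at the optimum (dropped components held at 0 so their SE is still
  # reported, mirroring the 0.00(SE) convention)
  active_all <- rep(TRUE, K)
  tmp <- active; active <- active_all
  gs_full <- grad_score(st, sigma)
  active <- tmp
  se <- rep(NA_real_, K + 1L)
  covm <- tryCatch(solve(gs_full$AI), error = function(e) {
    sv <- svd(gs_full$AI)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  se[gs_full$idx] <- sqrt(pmax(diag(covm), 0))

  list(sigma2 = sigma, se = se, boundary = c(!active, FALSE),
       loglik = st$ll, loglik_trace = trace, iterations = iter,
       converged = converged, n = n, q = q)
}

# ---- model-facing wrappers -------------------------------------------------

.design_matrices <- function(records, trait, model) {
  if ("alive" %in% names(records)) records <- records[records$alive, , drop = FALSE]
  records <- records[!is.na(records[[trait]]), , drop = FALSE]
  y <- records[[trait]]
  prov <- factor(records$provenance)
  if (nlevels(prov) < 2) stop("need at least 2 provenances", call. = FALSE)
  if (model == "growth") {
    block <- factor(records$block)
    X <- if (nlevels(block) > 1) stats::model.matrix(~block) else
      matrix(1, length(y), 1)
    Zp <- stats::model.matrix(~ 0 + prov)
    Zpb <- stats::model.matrix(~ 0 + block:prov)
    Zpb <- Zpb[, colSums(Zpb) > 0, drop = FALSE]  # only realized plots
    list(y = y, X = X, Z = list(v_p = Zp, v_pb = Zpb), records = records)
  } else {
    list(y = y, X = matrix(1, length(y), 1),
         Z = list(v_p = stats::model.matrix(~ 0 + prov)), records = records)
  }
}

#' REML variance components for one trait of a provenance trial
#'
#' Fits the trial mixed model \eqn{y = X\beta + Zu + \epsilon} by restricted
#' maximum likelihood on the (generally unbalanced) individual-tree data.
#' Under `model = "growth"` the fixed effects are intercept + block and the
#' random terms are provenance and provenance-by-block; under
#' `model = "wood"` (per-tree core samples without block replication) the
#' provenance-by-block term is omitted structurally and the fixed part is
#' the intercept alone. Estimation is EM-REML with average-information
#' acceleration; the restricted log-likelihood is non-decreasing across
#' iterations. Components that converge to the zero boundary are dropped,
#' reported as 0 and flagged (`boundary = TRUE`, i.e. "not estimated and
#' assumed to be zero"); standard errors come from the inverse
#' average-information matrix at the optimum.
#'
#' @param records Growth- or wood-schema records.
#' @param trait Trait column name.
#' @param model `"growth"` (block fixed effect + provenance + provenance x
#'   block) or `"wood"` (provenance only).
#' @param tol Relative parameter-change convergence tolerance.
#' @param loglik_tol Log-likelihood change convergence tolerance.
#' @param max_iter Maximum iterations before an error is raised.
#' @return An object of class `varcomp`: `components` (data.frame with
#'   `component` in v_p/v_pb/v_e, `estimate`, `se`, `boundary`), `loglik`,
#'   `loglik_trace`, `iterations`, `n`, `trait`, `model`.
#' @export
fit_lmm_reml <- function(records, trait, model = c("growth", "wood"),
                         tol = 1e-8, loglik_tol = 1e-10, max_iter = 500L) {
  model <- match.arg(model)
  dm <- .design_matrices(records, trait, model)
  if (length(dm$y) < ncol(dm$X) + length(dm$Z)) {
    stop("too few observations for the model", call. = FALSE)
  }
  fit <- .reml_engine(dm$y, dm$X, dm$Z, tol = tol, loglik_tol = loglik_tol,
                      max_iter = max_iter)
  comp_names <- c(names(dm$Z), "v_e")
  components <- data.frame(component = comp_names,
                           estimate = fit$sigma2,
                           se = fit$se,
                           boundary = fit$boundary,
                           stringsAsFactors = FALSE)
  structure(list(trait = trait, model = model, components = components,
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, n = fit$n),
            class = "varcomp")
}

#' Extract a variance-component estimate
#'
#' @param vc A `varcomp` object.
#' @param component One of `"v_p"`, `"v_pb"`, `"v_e"`. A `v_pb` request on a
#'   wood-model fit returns 0.
#' @return The REML estimate (0 for boundary-flagged components).
#' @export
vc_estimate <- function(vc, component) {
  stopifnot(inherits(vc, "varcomp"))
  i <- match(component, vc$components$component)
  if (is.na(i)) {
    if (component == "v_pb") return(0)
    stop("unknown component: ", component, call. = FALSE)
  }
  vc$components$estimate[i]
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components for '%s' (%s model, n = %d, %d iterations)\n",
              x$trait, x$model, x$n, x$iterations))
  tab <- x$components
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$flag <- ifelse(tab$boundary, "NE", "")
  print(tab[, c("component", "estimate", "se", "flag")], row.names = FALSE)
  cat(sprintf("restricted loglik: %.4f\n", x$loglik))
  invisible(x)
}

#' Provenance and error covariance components for a trait pair
#'
#' Estimates the between-trait provenance and residual covariances from
#' three univariate REML fits via the variance-of-sum identity
#' \eqn{Cov(a,b) = [Var(a+b) - Var(a) - Var(b)]/2} applied component-wise,
#' using only trees measured for both traits. Covariances are projected so
#' the implied correlations lie in `[-1, 1]`. If either marginal provenance
#' variance is at the zero boundary the provenance covariance is flagged NE
#' (not estimated, assumed zero).
#'
#' @param records Records with both trait columns on the same trees.
#' @param trait1,trait2 Trait column names.
#' @param model `"growth"` or `"wood"` (see [fit_lmm_reml()]).
#' @param ... Passed to [fit_lmm_reml()].
#' @return An object of class `covcomp`: `traits`, `cov_p`, `cov_e`,
#'   `ne` (provenance covariance not estimable), and the three marginal
#'   `varcomp` fits (`fit1`, `fit2`, `fit_sum`).
#' @export
fit_bivariate_reml <- function(records, trait1, trait2,
                               model = c("growth", "wood"), ...) {
  model <- match.arg(model)
  keep <- !is.na(records[[trait1]]) & !is.na(records[[trait2]])
  if ("alive" %in% names(records)) keep <- keep & records$alive
  rec <- records[keep, , drop = FALSE]
  rec$.sum <- rec[[trait1]] + rec[[trait2]]
  f1 <- fit_lmm_reml(rec, trait1, model, ...)
  f2 <- fit_lmm_reml(rec, trait2, model, ...)
  fs <- fit_lmm_reml(rec, ".sum", model, ...)
  half_diff <- function(comp) {
    (vc_estimate(fs, comp) - vc_estimate(f1, comp) - vc_estimate(f2, comp)) / 2
  }
  clamp <- function(cv, v1, v2) {
    bound <- sqrt(v1 * v2)
    max(min(cv, bound), -bound)
  }
  ne <- any(f1$components$boundary[f1$components$component == "v_p"],
            f2$components$boundary[f2$components$component == "v_p"])
  vp1 <- vc_estimate(f1, "v_p"); vp2 <- vc_estimate(f2, "v_p")
  ve1 <- vc_estimate(f1, "v_e"); ve2 <- vc_estimate(f2, "v_e")
  cov_p <- if (ne) NA_real_ else clamp(half_diff("v_p"), vp1, vp2)
  cov_e <- clamp(half_diff("v_e"), ve1, ve2)
  structure(list(traits = c(trait1, trait2), cov_p = cov_p, cov_e = cov_e,
                 ne = ne, fit1 = f1, fit2 = f2, fit_sum = fs),
            class = "covcomp")
}

#' @export
print.covcomp <- function(x, ...) {
  cat(sprintf("Covariance components %s ~ %s:\n", x$traits[1], x$traits[2]))
  cat(sprintf("  provenance: %s   error: %.4g\n",
              if (x$ne) "NE" else signif(x$cov_p, 4), x$cov_e))
  invisible(x)
}
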