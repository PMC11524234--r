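# Draw n rows from MVN(0, Sigma) via an eigen factor, so that positive
# semi-definite (including singular) covariance matrices are accepted.
.mvn <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  k <- nrow(Sigma)
  if (k == 1L) return(matrix(stats::rnorm(n, sd = sqrt(Sigma[1, 1])), ncol = 1))
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  fac <- e$vectors %*% diag(sqrt(ev), k)
  matrix(stats::rnorm(n * k), nrow = n) %*% t(fac)
}

.check_psd <- function(M, name) {
  M <- as.matrix(M)
  if (!isSymmetric(M, tol = 1e-8)) stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " must be positive semi-definite", call. = FALSE)
  }
  invisible(M)
}

#' Configuration for a synthetic provenance trial
#'
#' Defines the data-generating process of the randomized-complete-block
#' mixed model \eqn{y = X\beta + Zu + \epsilon}: fixed block effects, random
#' provenance effects drawn jointly across traits from `G_P`, independent
#' provenance-by-block effects with per-trait variance `V_PB`, and residuals
#' drawn jointly from `R`. Survival is i.i.d. Bernoulli per planted tree,
#' which is what makes the simulated design unbalanced.
#'
#' Defaults reproduce the structure of the motivating field trial: a
#' 10-provenance x 10-block design with 5-tree plots, survival 0.8, two
#' growth traits (`dbh` in cm, `height` in m) with grand means 12.52 and
#' 11.98, provenance/interaction/residual variances (0.47, 0.08, 8.97) and
#' (0.23, 0.26, 5.46), genetic correlation 0.97 and a residual covariance
#' chosen so the phenotypic correlation is about 0.87.
#'
#' @param p,b,n Provenances, blocks, planted trees per plot.
#' @param traits Character vector of trait names.
#' @param grand_mean Named numeric vector of trait grand means.
#' @param block_effects Optional fixed vector of block effects (length `b`);
#'   if `NULL`, drawn once per simulation as N(0, `block_sd`^2) and reported
#'   in the truth ledger (blocks stay fixed effects in the analysis model).
#' @param block_sd SD used to draw block effects when `block_effects` is NULL.
#' @param G_P Provenance covariance matrix across traits (diagonal = V_P).
#' @param V_PB Per-trait provenance-by-block variance (0 for the wood model).
#' @param R Residual covariance matrix across traits (diagonal = V_e).
#' @param survival Probability a planted tree is alive, in (0, 1].
#' @param seed Optional RNG seed; identical seed implies identical output.
#' @param coords Optional provenance coordinate table (`code`, `latitude`,
#'   `longitude`) used with `surface` to impose a geographic mean structure.
#' @param surface Optional length-6 coefficient vector of the quadratic
#'   trend surface added to the first trait's provenance means.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(p = 10, b = 10, n = 5,
                              traits = c("dbh", "height"),
                              grand_mean = c(dbh = 12.52, height = 11.98),
                              block_effects = NULL, block_sd = 1,
                              G_P = NULL, V_PB = NULL, R = NULL,
                              survival = 0.8, seed = NULL,
                              coords = NULL, surface = NULL) {
  k <- length(traits)
  if (is.null(G_P)) {
    if (!identical(traits, c("dbh", "height"))) {
      stop("G_P must be supplied for non-default traits", call. = FALSE)
    }
    g12 <- 0.97 * sqrt(0.47 * 0.23)
    G_P <- matrix(c(0.47, g12, g12, 0.23), 2, 2)
    V_PB <- c(dbh = 0.08, height = 0.26)
    r12 <- 0.865 * sqrt(8.97 * 5.46)
    R <- matrix(c(8.97, r12, r12, 5.46), 2, 2)
  }
  G_P <- as.matrix(G_P); R <- as.matrix(R)
  if (is.null(V_PB)) V_PB <- stats::setNames(rep(0, k), traits)
  V_PB <- rep_len(as.numeric(V_PB), k)
  if (length(grand_mean) == 1L) grand_mean <- rep(grand_mean, k)
  stopifnot(nrow(G_P) == k, nrow(R) == k, length(grand_mean) == k)
  .check_psd(G_P, "G_P"); .check_psd(R, "R")
  if (any(V_PB < 0)) stop("V_PB must be non-negative", call. = FALSE)
  if (survival <= 0 || survival > 1) stop("survival must be in (0, 1]", call. = FALSE)
  if (!is.null(block_effects) && length(block_effects) != b) {
    stop("block_effects must have length b", call. = FALSE)
  }
  structure(list(p = p, b = b, n = n, traits = traits,
                 grand_mean = stats::setNames(as.numeric(grand_mean), traits),
                 block_effects = block_effects, block_sd = block_sd,
                 G_P = G_P, V_PB = stats::setNames(V_PB, traits), R = R,
                 survival = survival, seed = seed,
                 coords = coords, surface = surface),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [simulation_config()]; `G_P` and `R` may be
#' given as matrices (list of rows) or, for one trait, scalars.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_simulation_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    # keep YAML-1.1 boolean-like scalars such as the key "n" literal
    yaml::read_yaml(path, handlers = list("bool#no" = identity,
                                          "bool#yes" = identity))
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_cov <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    if (is.null(dim(v)) && length(v) == 1) v <- matrix(as.numeric(v))
    as.matrix(v)
  }
  vals$G_P <- as_cov(vals$G_P)
  vals$R <- as_cov(vals$R)
  for (nm in c("grand_mean", "V_PB", "block_effects")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(simulation_config, vals)
}

#' Simulate a provenance trial
#'
#' Draws a full trial under the configured mixed model. The phenotype of
#' tree k of provenance j in block i is
#' `grand_mean + block_i + prov_j + pb_ij + e_ijk`, with provenance effects
#' MVN(0, `G_P`) across traits, interaction effects independent N(0, `V_PB`)
#' per trait, and residuals MVN(0, `R`). Draw order is fixed (block effects,
#' provenance effects, interaction effects, residuals, survival) so a seed
#' fully determines the output. Dead trees keep their design position with
#' NA phenotypes.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list of class `sim_trial`: `records` (growth-style table with
#'   one column per trait) and `truth` (block, provenance, interaction
#'   effects and the config) for oracle tests.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$p; b <- config$b; n <- config$n
  k <- length(config$traits)
  provs <- sprintf("P%02d", seq_len(p))
  blocks <- seq_len(b)

  blk <- config$block_effects
  if (is.null(blk)) blk <- stats::rnorm(b, sd = config$block_sd)
  prov_eff <- .mvn(p, config$G_P)
  dimnames(prov_eff) <- list(provs, config$traits)
  if (!is.null(config$coords) && !is.null(config$surface)) {
    co <- config$coords
    prov_eff[, 1] <- prov_eff[, 1] +
      .eval_poly(config$surface, co$latitude, co$longitude)
  }
  pb_eff <- array(0, dim = c(b, p, k),
                  dimnames = list(NULL, provs, config$traits))
  for (t in seq_len(k)) {
    if (config$V_PB[t] > 0) {
      pb_eff[, , t] <- matrix(stats::rnorm(b * p, sd = sqrt(config$V_PB[t])), b, p)
    }
  }
  idx <- expand.grid(tree = seq_len(n), provenance = provs, block = blocks,
                     stringsAsFactors = FALSE)
  N <- nrow(idx)
  resid <- .mvn(N, config$R)
  alive <- if (config$survival >= 1) rep(TRUE, N) else
    stats::runif(N) < config$survival

  pheno <- matrix(NA_real_, N, k, dimnames = list(NULL, config$traits))
  pj <- match(idx$provenance, provs)
  for (t in seq_len(k)) {
    pheno[, t] <- config$grand_mean[t] + blk[idx$block] + prov_eff[pj, t] +
      pb_eff[cbind(idx$block, pj, t)] + resid[, t]
  }
  pheno[!alive, ] <- NA_real_
  records <- data.frame(provenance = idx$provenance, block = idx$block,
                        tree = idx$tree, alive = alive, pheno,
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 truth = list(block_effects = blk, prov_effects = prov_eff,
                              pb_effects = pb_eff, config = config)),
            class = "sim_trial")
}

#' Simulate per-tree wood samples
#'
#' One record per cored tree under the wood-trait model: provenance effect
#' plus residual only (cored trees have no block replication, so no
#' provenance-by-block term is generated or estimable).
#'
#' @param config A `sim_config`; `V_PB` is ignored.
#' @param trees_per_provenance Cored trees per provenance (>= 1).
#' @return A list of class `sim_trial` with `records` (columns `provenance`,
#'   `tree`, one per trait) and `truth`.
#' @export
simulate_wood_samples <- function(config, trees_per_provenance = 5) {
  stopifnot(inherits(config, "sim_config"), trees_per_provenance >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$p; k <- length(config$traits)
  provs <- sprintf("P%02d", seq_len(p))
  prov_eff <- .mvn(p, config$G_P)
  dimnames(prov_eff) <- list(provs, config$traits)
  idx <- expand.grid(tree = seq_len(trees_per_provenance), provenance = provs,
                     stringsAsFactors = FALSE)
  resid <- .mvn(nrow(idx), config$R)
  pj <- match(idx$provenance, provs)
  pheno <- matrix(config$grand_mean, nrow(idx), k, byrow = TRUE) +
    prov_eff[pj, , drop = FALSE] + resid
  colnames(pheno) <- config$traits
  records <- data.frame(provenance = idx$provenance, tree = idx$tree, pheno,
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 truth = list(prov_effects = prov_eff, config = config)),
            class = "sim_trial")
}
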