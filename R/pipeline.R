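#' Run the full provenance-trial analysis pipeline
#'
#' Orchestrates ingest (or simulation), derived traits, per-provenance
#' summaries with Duncan letters, REML variance components with
#' heritability and genetic variation coefficients, genetic/phenotypic
#' correlations, superior-provenance selection with realized gains, and
#' trend-surface fits, writing one CSV per report table plus a JSON
#' manifest. Identical config and seed give a byte-identical bundle.
#'
#' @param config A list with entries:
#'   \describe{
#'     \item{simulation}{a `sim_config` for the growth trial, or `NULL`}
#'     \item{wood_simulation}{optional `sim_config` for per-tree wood samples}
#'     \item{growth_table, wood_table, locations_table}{paths to CSV inputs,
#'       used when the corresponding simulation entry is absent}
#'     \item{growth_traits, wood_traits}{trait column names to analyse
#'       (defaults: simulated trait names, plus `volume` when `dbh` and
#'       `height` are present)}
#'     \item{alpha}{Duncan test level, default 0.05}
#'     \item{selection}{named list of length-2 trait vectors, e.g.
#'       `list(wood_products = c("volume", "wbd"))`}
#'     \item{correlation_traits}{traits for the correlation matrix (default
#'       the growth traits)}
#'     \item{grid_n}{trend-surface lattice resolution (default 25)}
#'     \item{seed}{RNG seed for the whole run}
#'   }
#' @param output_dir Writable output directory (created if needed).
#' @param verbose Print one line per stage.
#' @return The manifest, invisibly (list with seed, stages, tables, rows).
#' @export
run_pipeline <- function(config, output_dir, verbose = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("provtrial")),
                   seed = config$seed, stages = list(), tables = list())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      .write_manifest(manifest, output_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    say("stage %s done (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  emit <- function(df, file) {
    path <- file.path(output_dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
    manifest$tables[[file]] <<- nrow(df)
    path
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  alpha <- config$alpha %||% 0.05

  # ingest / simulate ---------------------------------------------------
  growth <- stage("ingest_growth", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- config$seed %||% sim$seed
      simulate_trial(sim)$records
    } else if (!is.null(config$growth_table)) {
      read_trial_table(config$growth_table, "growth")
    } else NULL
  })
  wood <- stage("ingest_wood", {
    if (!is.null(config$wood_simulation)) {
      sim <- config$wood_simulation
      if (!is.null(config$seed)) sim$seed <- config$seed + 1L
      simulate_wood_samples(sim, trees_per_provenance = sim$n)$records
    } else if (!is.null(config$wood_table)) {
      read_trial_table(config$wood_table, "wood")
    } else NULL
  })
  locations <- if (!is.null(config$locations_table)) {
    read_trial_table(config$locations_table, "provenance")
  } else config$locations
  if (is.null(growth) && is.null(wood)) {
    stop("config must provide growth or wood data (simulation or table)",
         call. = FALSE)
  }

  # derive ---------------------------------------------------------------
  growth <- stage("derive", {
    if (!is.null(growth) && all(c("dbh", "height") %in% names(growth))) {
      growth <- derive_volume(growth)
    }
    if (!is.null(wood) && all(c("fl", "fd", "vl", "vd") %in% names(wood))) {
      wood <- trait_ratios(wood)
    }
    growth
  })
  g_traits <- config$growth_traits %||%
    if (!is.null(growth)) intersect(c("dbh", "height", "volume"), names(growth))
  w_traits <- config$wood_traits %||%
    if (!is.null(wood)) setdiff(names(wood), c("provenance", "tree"))

  # summaries ------------------------------------------------------------
  summarize_domain <- function(records, traits) {
    do.call(rbind, lapply(traits, function(tr) {
      d <- provenance_descriptives(records, tr)
      mrt <- duncan_mrt(records, tr, alpha)
      d$letters <- mrt$table$letters[match(d$provenance, mrt$table$provenance)]
      cbind(trait = tr, d)
    }))
  }
  if (!is.null(growth)) {
    t1 <- stage("summarize_growth", summarize_domain(growth, g_traits))
    emit(t1, "table1_growth_summary.csv")
  }
  if (!is.null(wood)) {
    t2 <- stage("summarize_wood", summarize_domain(wood, w_traits))
    emit(t2, "table2_wood_summary.csv")
  }

  # variance components --------------------------------------------------
  t3 <- stage("varcomp", {
    rows <- list()
    if (!is.null(growth)) {
      des <- validate_trial(growth)
      n_h <- harmonic_mean_n(des)
      for (tr in g_traits) {
        vc <- fit_lmm_reml(growth, tr, "growth")
        rows[[tr]] <- .varcomp_row(vc, tr, "growth", n_h, des$b,
                                   mean(growth[[tr]][growth$alive], na.rm = TRUE))
      }
    }
    if (!is.null(wood)) {
      n_per <- table(wood$provenance)
      n_h_w <- length(n_per) / sum(1 / n_per)
      for (tr in w_traits) {
        vc <- fit_lmm_reml(wood, tr, "wood")
        rows[[tr]] <- .varcomp_row(vc, tr, "wood", n_h_w, 1,
                                   mean(wood[[tr]], na.rm = TRUE))
      }
    }
    do.call(rbind, rows)
  })
  emit(t3, "table3_variance_components.csv")

  # correlations ----------------------------------------------------------
  corr_traits <- config$correlation_traits %||% g_traits
  if (!is.null(growth) && length(corr_traits) >= 2) {
    t4 <- stage("correlate", {
      cm <- correlation_matrix(growth, corr_traits, "growth")
      out <- as.data.frame(cm$table)
      cbind(trait = rownames(out), out)
    })
    emit(t4, "table4_correlations.csv")
  }

  # selection -------------------------------------------------------------
  sel_pairs <- config$selection
  if (!is.null(sel_pairs)) {
    t6 <- stage("select", {
      pm <- .provenance_mean_table(growth, wood, g_traits, w_traits)
      do.call(rbind, lapply(names(sel_pairs), function(nm) {
        gr <- select_superior(pm, sel_pairs[[nm]][1], sel_pairs[[nm]][2],
                              purpose = nm)
        cbind(purpose = nm,
              superior = paste(gr$superior, collapse = ";"),
              gr$table)
      }))
    })
    emit(t6, "table6_selection_gains.csv")
  }

  # trend surface ---------------------------------------------------------
  if (!is.null(locations)) {
    t5 <- stage("trend", {
      fit_domain <- function(records, traits) {
        rec <- attach_coordinates(records, locations)
        do.call(rbind, lapply(traits, function(tr) {
          ts <- fit_trend_surface(rec, trait = tr)
          lattice <- evaluate_surface(ts, grid_n = config$grid_n %||% 25)
          emit(lattice, sprintf("surface_%s.csv", tr))
          data.frame(trait = tr, t(ts$coefficients), r2 = ts$r2,
                     p_value = ts$p_value, n = ts$n)
        }))
      }
      rows <- list()
      if (!is.null(growth)) rows$g <- fit_domain(growth, g_traits)
      if (!is.null(wood)) rows$w <- fit_domain(wood, w_traits)
      do.call(rbind, rows)
    })
    emit(t5, "table5_trend_surface.csv")
  }

  .write_manifest(manifest, output_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.varcomp_row <- function(vc, trait, model, n_h, b, trait_mean) {
  est <- function(cn) {
    i <- match(cn, vc$components$component)
    if (is.na(i)) c(NA_real_, NA_real_, NA) else
      c(vc$components$estimate[i], vc$components$se[i], vc$components$boundary[i])
  }
  vp <- est("v_p"); vpb <- est("v_pb"); ve <- est("v_e")
  h2 <- if (vp[3] == 1 || is.na(vp[1])) NA_real_ else
    provenance_heritability(vp[1], if (is.na(vpb[1])) 0 else vpb[1], ve[1],
                            n_h = n_h, b = b)
  cvg <- if (vp[3] == 1 || is.na(vp[1])) NA_real_ else genetic_cv(vp[1], trait_mean)
  data.frame(trait = trait, model = model,
             v_p = vp[1], v_p_se = vp[2], v_p_ne = as.logical(vp[3]),
             v_pb = vpb[1], v_pb_se = vpb[2],
             v_e = ve[1], v_e_se = ve[2],
             n_h = n_h, h2 = h2, cv_g = cvg, stringsAsFactors = FALSE)
}

.provenance_mean_table <- function(growth, wood, g_traits, w_traits) {
  mean_by_prov <- function(records, traits) {
    if (is.null(records)) return(NULL)
    if ("alive" %in% names(records)) records <- records[records$alive, , drop = FALSE]
    agg <- stats::aggregate(records[traits], by = list(provenance = records$provenance),
                            FUN = mean, na.rm = TRUE)
    agg
  }
  g <- mean_by_prov(growth, g_traits)
  w <- mean_by_prov(wood, w_traits)
  if (is.null(g)) return(w)
  if (is.null(w)) return(g)
  merge(g, w, by = "provenance")
}

.write_manifest <- function(manifest, output_dir) {
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
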