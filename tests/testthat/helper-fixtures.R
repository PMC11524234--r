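# shared fixture builders; everything is generated in code

make_growth_records <- function(p = 2, b = 2, n = 3, seed = 1,
                                survival = 1, v_p = 0.5, v_pb = 0.1,
                                v_e = 2, mean_ = 12) {
  cfg <- simulation_config(p = p, b = b, n = n, traits = "dbh",
                           grand_mean = c(dbh = mean_),
                           G_P = matrix(v_p), V_PB = v_pb,
                           R = matrix(v_e), survival = survival, seed = seed)
  sim <- simulate_trial(cfg)
  rec <- sim$records
  rec$height <- rec$dbh * 0.9  # keep the growth schema complete
  rec
}

make_oneway_records <- function(p = 8, n = 10, v_p = 1, v_e = 2,
                                mean_ = 10, seed = 1) {
  set.seed(seed)
  prov <- rep(sprintf("P%02d", seq_len(p)), each = n)
  eff <- rnorm(p, sd = sqrt(v_p))
  data.frame(provenance = prov, tree = rep(seq_len(n), p),
             y = mean_ + eff[match(prov, unique(prov))] +
               rnorm(p * n, sd = sqrt(v_e)),
             stringsAsFactors = FALSE)
}

write_growth_fixture <- function(path) {
  df <- data.frame(provenance = c("AA", "AA", "BB", "BB"),
                   block = c(1, 2, 1, 2),
                   tree = c(1, 1, 1, 1),
                   alive = c(TRUE, TRUE, TRUE, FALSE),
                   dbh = c(10.2, 11.5, 9.8, NA),
                   height = c(9.1, 10.0, 8.5, NA))
  write.csv(df, path, row.names = FALSE)
  df
}

# provenance-level reference means of the traits used for selection
reference_selection_means <- function() {
  g <- reference_table("growth_summary")
  w <- reference_table("wood_summary")
  v <- g[g$trait == "V", c("provenance", "mean")]
  names(v)[2] <- "V"
  wbd <- w[w$trait == "WBD", c("provenance", "mean")]
  names(wbd)[2] <- "WBD"
  fl <- w[w$trait == "FL", c("provenance", "mean")]
  names(fl)[2] <- "FL"
  Reduce(function(a, b) merge(a, b, by = "provenance"), list(v, wbd, fl))
}
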