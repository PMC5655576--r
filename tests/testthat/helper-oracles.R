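# Shared fixtures and independent oracles.

# Brute-force pairwise agreement: expand a count row into an explicit
# rating vector and count agreeing rater pairs directly.
pairwise_agreement_bruteforce <- function(counts) {
  ratings <- rep(seq_along(counts), counts)
  pairs <- utils::combn(length(ratings), 2L)
  mean(ratings[pairs[1L, ]] == ratings[pairs[2L, ]])
}

# Fleiss' kappa from first principles on a long rating table:
# brute-force Pr per scenario plus marginal chance agreement.
fleiss_kappa_bruteforce <- function(ratings, scenario_ids) {
  per_pr <- vapply(scenario_ids, function(s) {
    r <- as.character(ratings$rating[ratings$scenario_id == s])
    pairs <- utils::combn(length(r), 2L)
    mean(r[pairs[1L, ]] == r[pairs[2L, ]])
  }, numeric(1))
  keep <- ratings$scenario_id %in% scenario_ids
  pc <- prop.table(table(factor(as.character(ratings$rating[keep]),
                                levels = c("S", "M-DA", "S-DA"))))
  pe <- sum(pc^2)
  (mean(per_pr) - pe) / (1 - pe)
}

# A complete, valid single-patient record with every parameter at its
# mildest; fields can be overridden per test.
make_patient <- function(...) {
  p <- data.frame(
    igf_value = 150, igf_lln = 100, igf_uln = 200,
    tumor_visible = FALSE, tumor_change_pct = NA_real_,
    tumor_invasive = FALSE, vision_worse = FALSE,
    diabetes = "none", sleep_apnea = "absent", cardiac = "absent",
    stringsAsFactors = FALSE
  )
  for (i in 1:5) p[[paste0("sss_", i)]] <- 0L
  for (i in 1:22) p[[paste0("qol_", i)]] <- 5L
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Small deterministic long-format rating table from a count matrix.
ratings_from_counts <- function(counts, scenario_ids) {
  rows <- do.call(rbind, lapply(seq_along(scenario_ids), function(i) {
    data.frame(
      rater_id = seq_len(sum(counts[i, ])),
      scenario_id = scenario_ids[i],
      rating = rep(c("S", "M-DA", "S-DA"), counts[i, ])
    )
  }))
  rows
}
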