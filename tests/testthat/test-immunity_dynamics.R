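test_that("phase assignment follows the acquisition-sample rule", {
  tps <- 1:6
  sp <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  ph <- phase_assignment(tps, sp)
  expect_equal(ph, c("before", "before", "acquisition", "after_no_spacer",
                     "after_with_spacer", "after_no_spacer"))
  # spacer retained everywhere after acquisition: no after_no_spacer
  ph2 <- phase_assignment(1:4, c(FALSE, TRUE, TRUE, TRUE))
  expect_false("after_no_spacer" %in% ph2)
  # phases partition the retained samples
  expect_length(ph, length(tps))
})

test_that("max-normalization preserves zeros and scale-invariance", {
  expect_equal(normalize_by_max(c(2, 4, 0, 1)), c(0.5, 1, 0, 0.25))
  expect_equal(normalize_by_max(c(3, 3, 3)), c(1, 1, 1))
  x <- c(0.1, 5, 0, 2)
  expect_equal(normalize_by_max(x * 17), normalize_by_max(x))
  expect_error(normalize_by_max(c(0, 0)), "all-zero")
})

test_that("abundance arithmetic follows the reads/length/total formula", {
  expect_equal(target_abundance_series(100L, 1e6, 5000L, 5034L, 20000L,
                                       flank = 2000L),
               100 / 4034 / 1e6)
  # clipping at a contig end shortens the normalization length
  expect_equal(target_abundance_series(100L, 1e6, 500L, 534L, 20000L,
                                       flank = 2000L),
               100 / (534 + 2000) / 1e6)
  # undetected samples are zeroed
  expect_equal(target_abundance_series(c(10L, 20L), c(1e6, 1e6),
                                       5000L, 5034L, 20000L,
                                       detected = c(TRUE, FALSE))[2], 0)
  expect_error(target_abundance_series(10L, 0L, 0L, 34L, 1000L),
               "zero total reads")
})

test_that("episode selection enforces both eligibility conditions", {
  cfg <- sim_config(n_subjects = 3L, n_lineages_per_subject = 3L,
                    detection_prob = 1, truncation_prob = 0, loss_rate = 0,
                    local_frac = 0, gain_rate = 0.5, rng_seed = 501L)
  truth <- simulate_community(cfg)
  ds <- emit_observed_dataset(truth)
  lin <- build_all_lineages(ds$arrays)
  tg <- classify_targets(ds)
  eps <- select_episodes(ds, lin, tg$local_hits)

  # with perfect detection and local_frac 0, every episode corresponds
  # to a planted acquisition observed in >= 2 samples after the lineage's
  # first sample
  acq <- truth$acquisitions
  for (i in seq_len(nrow(eps))) {
    sc <- canonical_seq(unname(ds$arrays$spacer_seqs[eps$spacer_id[i]]))
    match_row <- which(canonical_seq(acq$spacer_seq) == sc &
                         acq$mge_id == eps$target_id[i] &
                         acq$subject == eps$subject[i])
    expect_gte(length(match_row), 1L)
    expect_gte(sum(eps$spacer_at[[i]]), 2L)
    expect_gt(eps$acquisition_tp[i], min(eps$timepoints[[i]]))
  }
  # and conversely: every planted acquisition with a detected target and
  # >= 2 spacer samples after the lineage start is selected
  canon_eps <- canonical_seq(
    unname(ds$arrays$spacer_seqs[eps$spacer_id]))
  et <- episodes_from_truth(truth)
  for (i in seq_len(nrow(et$episodes))) {
    tid <- et$episodes$target_id[i]
    # target must be assembled at least once to yield a local protospacer
    if (!any(truth$presence$present[
      truth$presence$target_id == tid &
        truth$presence$subject == et$episodes$subject[i]])) next
    sc <- canonical_seq(et$episodes$spacer_id[i])
    expect_true(any(canon_eps == sc & eps$target_id == tid &
                      eps$subject == et$episodes$subject[i]))
  }
})

test_that("planted immunity effect is recovered with pooled statistics", {
  cfg <- sim_config(n_subjects = 6L, n_lineages_per_subject = 4L,
                    n_mge = 60L, mge_len = 300L, gain_rate = 0.5,
                    immunity_multiplier = 0.3, rng_seed = 502L)
  truth <- simulate_community(cfg)
  et <- episodes_from_truth(truth)
  expect_gt(nrow(et$episodes), 50L)
  ps <- phase_statistics(et$episodes, et$abundance,
                         crispr_params(n_bootstraps = 300L))
  s <- ps$summary
  med <- stats::setNames(s$median, s$phase)
  expect_lt(med[["after_with_spacer"]], med[["before"]])
  p <- ps$tests$p[ps$tests$phase_a == "before" &
                    ps$tests$phase_b == "after_with_spacer"]
  expect_lt(p, 1e-4)
  # prevalence drops with the spacer as well (immunity pushes targets
  # below the detection floor)
  expect_lt(s$prevalence[s$phase == "after_with_spacer"],
            s$prevalence[s$phase == "before"])
  # bootstrap CI of a constant sample has zero width
  const_eps <- et$episodes[1, ]
  ab_const <- data.table::copy(et$abundance)
  ab_const[, abundance := ifelse(abundance > 0, 1, 0)]
  ps_const <- phase_statistics(const_eps, ab_const,
                               crispr_params(n_bootstraps = 100L))
  s1 <- ps_const$summary[ps_const$summary$phase == "acquisition", ]
  expect_equal(s1$ci_lo, s1$ci_hi)
})

test_that("diversity analysis separates active and inactive lineages", {
  cfg <- sim_config(n_subjects = 3L, n_lineages_per_subject = 4L,
                    detection_prob = 1, truncation_prob = 0.2,
                    local_frac = 0.2, gain_rate = 0.4, rng_seed = 503L)
  truth <- simulate_community(cfg)
  ds <- emit_observed_dataset(truth)
  lin <- build_all_lineages(ds$arrays)
  tg <- classify_targets(ds)
  dv <- diversity_analysis(ds, lin, tg$local_hits,
                           crispr_params(n_bootstraps = 100L))
  expect_true(all(c("lineage_id", "n_distinct_arrays", "active") %in%
                    names(dv$diversity)))
  # inactive lineages carry no locally adapted spacer by definition
  adapted <- tg$assignments$spacer_id[tg$assignments$locally_adapted]
  memb <- lin$membership
  arr <- ds$arrays$arrays
  for (i in seq_len(nrow(dv$diversity))) {
    l <- dv$diversity$lineage_id[i]
    ids <- memb$array_id[memb$lineage_id == l]
    sps <- unique(unlist(arr$spacers[arr$array_id %in% ids]))
    has_adapted <- any(sps %in% adapted)
    expect_equal(dv$diversity$active[i], has_adapted)
  }
  if (!is.null(dv$sweep)) {
    expect_true(dv$sweep$observed_pct >= 0 &&
                  dv$sweep$observed_pct <= 100)
    expect_lte(dv$sweep$expected_ci_lo, dv$sweep$expected_pct)
    expect_gte(dv$sweep$expected_ci_hi, dv$sweep$expected_pct)
  }
})
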