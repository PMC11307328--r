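test_that("array-size sampling follows the truncated power law", {
  expect_length(sample_array_sizes(0, 2, 100), 0L)
  expect_error(sample_array_sizes(10, 0.9, Inf), "non-normalizable")

  set.seed(11)
  x <- sample_array_sizes(1e5, 2.0, 100)
  expect_true(all(x >= 1))
  # oracle: mean by direct summation of the normalized mass function
  k <- 1:1e4
  w <- k^(-2) * exp(-k / 100)
  mu <- sum(k * w) / sum(w)
  expect_lt(abs(mean(x) - mu) / mu, 0.02)

  # extreme damping: all draws collapse to 1
  set.seed(1)
  expect_true(all(sample_array_sizes(100, 2.0, 1e-6) == 1L))
})

test_that("truncated power-law MLE recovers parameters and is maximal", {
  set.seed(12)
  x <- sample_array_sizes(2e4, 2.0, 100)
  fit <- fit_truncated_powerlaw(x)
  expect_gt(fit$alpha_hat, 1.85)
  expect_lt(fit$alpha_hat, 2.15)
  expect_gte(fit$loglik, fit$loglik_fun(2.0, 100))
  expect_false(fit$boundary)

  # pure power-law regime pushes the cutoff to the boundary with a flag
  set.seed(13)
  y <- sample_array_sizes(5000, 2.5, 1e9)
  fit2 <- fit_truncated_powerlaw(y, cutoff_max = 1e3)
  expect_true(fit2$boundary)

  expect_error(fit_truncated_powerlaw(rep(3L, 200)), "degenerate")
  expect_error(fit_truncated_powerlaw(1:50), ">= 100")
})

test_that("lineage evolution gains at the leader end and never rearranges", {
  set.seed(21)
  pool <- generate_mge_pool(sim_config(n_mge = 10L, mge_len = 500L))
  init <- rand_dna(5, 34)

  still <- evolve_lineage(init, 8L, gain_rate = 0, loss_rate = 0,
                          pool$protospacers)
  for (t in 1:8) expect_identical(still$arrays[[t]], init)
  expect_equal(nrow(still$acquisitions), 0L)

  ev <- evolve_lineage(init, 10L, gain_rate = 1, loss_rate = 0.1,
                       pool$protospacers)
  for (t in 2:10) {
    prev <- ev$arrays[[t - 1L]]
    cur <- ev$arrays[[t]]
    shared <- intersect(prev, cur)
    # surviving shared spacers preserve relative order
    expect_identical(cur[cur %in% shared], prev[prev %in% shared])
  }
  # gains are prepended: the pre-existing block is a suffix
  ev2 <- evolve_lineage(init, 6L, gain_rate = 2, loss_rate = 0,
                        pool$protospacers)
  for (t in 2:6) {
    cur <- ev2$arrays[[t]]
    expect_identical(cur[(length(cur) - 4L):length(cur)], init)
  }

  # Poisson count of gains over 9 transitions at rate 1: CI check.
  # A large protospacer pool keeps the duplicate-skip rule negligible.
  set.seed(22)
  big_pool <- generate_mge_pool(sim_config(n_mge = 300L, mge_len = 500L,
                                           n_proto_per_mge = 5L))
  gains <- replicate(60, {
    e <- evolve_lineage(init, 10L, gain_rate = 1, loss_rate = 0,
                        big_pool$protospacers)
    length(e$arrays[[10L]]) - 5L
  })
  expect_equal(mean(gains), 9, tolerance = 0.15)
})

test_that("MGE pool respects class mix, tags and strand balance", {
  set.seed(31)
  cfg <- sim_config(n_mge = 50L, mge_len = 400L,
                    mge_class_mix = c(lytic_or_nonlysogenic_phage = 0,
                                      lysogenic_phage = 0, plasmid = 1,
                                      other_mge = 0),
                    crass_frac = 0)
  pool <- generate_mge_pool(cfg)
  expect_true(all(pool$mge$class == "plasmid"))
  expect_true(all(!pool$mge$crass_like))
  expect_error(sim_config(mge_class_mix = c(lytic_or_nonlysogenic_phage = 0.6,
                                            lysogenic_phage = 0.6,
                                            plasmid = 0, other_mge = 0)),
               "sum to 1")

  # strand balance of planted protospacers ~ Binomial(n, 0.5)
  set.seed(32)
  big <- generate_mge_pool(sim_config(n_mge = 400L, mge_len = 500L,
                                      n_proto_per_mge = 9L))
  n <- nrow(big$protospacers)
  frac_minus <- mean(big$protospacers$strand == "-")
  ci <- 3 * sqrt(0.25 / n)
  expect_lt(abs(frac_minus - 0.5), ci)
  # minus-strand protospacers store the reverse complement as spacer
  i <- which(big$protospacers$strand == "-")[1L]
  row <- big$protospacers[i, ]
  window <- substr(big$mge$seq[big$mge$mge_id == row$mge_id],
                   row$start + 1L, row$end)
  expect_identical(row$spacer_seq, revcomp(window))
})

test_that("abundance simulation plants exact multiplicative effects", {
  mge <- c("M1", "M2")
  subj <- "S01"
  sp <- array(FALSE, c(2, 1, 4)); acqf <- array(FALSE, c(2, 1, 4))
  sp[1, 1, 3:4] <- TRUE     # M1 has a cognate spacer at t3, t4
  acqf[1, 1, 2] <- TRUE     # acquired at t2
  set.seed(41)
  res <- simulate_abundances(mge, subj, 4L, sp, acqf,
                             immunity_multiplier = 0.3,
                             acquisition_boost = 2.0, noise_sd = 0)
  ab <- res$abundance
  b <- res$baseline
  get <- function(m, t) ab$abundance[ab$target_id == m & ab$sample == t]
  expect_equal(get("M1", 1), b["M1", 1])
  expect_equal(get("M1", 2), 2.0 * b["M1", 1])
  expect_equal(get("M1", 3), 0.3 * b["M1", 1])
  expect_equal(get("M1", 4), 0.3 * b["M1", 1])
  expect_equal(get("M2", 2), b["M2", 1])

  # neutral parameters reproduce baseline exactly
  set.seed(42)
  res0 <- simulate_abundances(mge, subj, 4L, sp, acqf,
                              immunity_multiplier = 1, acquisition_boost = 1,
                              noise_sd = 0)
  expect_true(all(abs(res0$abundance$abundance -
                        res0$baseline[res0$abundance$target_id, 1]) < 1e-12))

  # multiplier zero wipes with-spacer samples
  set.seed(43)
  resz <- simulate_abundances(mge, subj, 4L, sp, acqf,
                              immunity_multiplier = 0, acquisition_boost = 1,
                              noise_sd = 0)
  abz <- resz$abundance
  expect_equal(abz$abundance[abz$target_id == "M1" & abz$sample %in% 3:4],
               c(0, 0))
})

test_that("observation layer: identity at detection 1, truncation is terminal", {
  cfg <- sim_config(n_subjects = 2L, n_lineages_per_subject = 3L,
                    detection_prob = 1, truncation_prob = 0,
                    orient_known_prob = 1, rng_seed = 51L)
  truth <- simulate_community(cfg)
  ds <- emit_observed_dataset(truth)
  arr <- ds$arrays$arrays
  # every (lineage, sample) true array is observed, content preserved
  n_true <- sum(vapply(truth$lineages, function(l)
    sum(vapply(l$arrays, function(a) !is.null(a) && length(a) > 0,
               logical(1))), integer(1)))
  expect_equal(nrow(arr), n_true)
  for (i in seq_len(nrow(arr))) {
    lid <- ds$truth_membership$lineage_id[
      ds$truth_membership$array_id == arr$array_id[i]]
    true_arr <- truth$lineages[[lid]]$arrays[[arr$timepoint[i]]]
    obs <- unname(ds$arrays$spacer_seqs[arr$spacers[[i]]])
    if (arr$orientation[i] == "reverse") obs <- rev(revcomp(obs))
    expect_identical(obs, true_arr)
  }

  # truncation removes a contiguous terminal run
  cfg2 <- sim_config(n_subjects = 2L, n_lineages_per_subject = 3L,
                     detection_prob = 1, truncation_prob = 1,
                     orient_known_prob = 1, rng_seed = 52L)
  truth2 <- simulate_community(cfg2)
  ds2 <- emit_observed_dataset(truth2)
  arr2 <- ds2$arrays$arrays
  ok <- 0L
  for (i in seq_len(nrow(arr2))) {
    lid <- ds2$truth_membership$lineage_id[
      ds2$truth_membership$array_id == arr2$array_id[i]]
    true_arr <- truth2$lineages[[lid]]$arrays[[arr2$timepoint[i]]]
    obs <- unname(ds2$arrays$spacer_seqs[arr2$spacers[[i]]])
    if (arr2$orientation[i] == "reverse") obs <- rev(revcomp(obs))
    k <- length(obs)
    is_prefix <- identical(obs, true_arr[seq_len(k)])
    is_suffix <- identical(obs,
                           true_arr[(length(true_arr) - k + 1L):
                                      length(true_arr)])
    expect_true(is_prefix || is_suffix)
    ok <- ok + 1L
  }
  expect_gt(ok, 0L)
})

test_that("detection dropout matches its binomial rate", {
  cfg <- sim_config(n_subjects = 6L, n_lineages_per_subject = 6L,
                    n_samples_per_subject = 15L,
                    detection_prob = 0.8, truncation_prob = 0,
                    rng_seed = 53L)
  truth <- simulate_community(cfg)
  ds <- emit_observed_dataset(truth)
  n_true <- sum(vapply(truth$lineages, function(l)
    sum(vapply(l$arrays, function(a) !is.null(a) && length(a) > 0,
               logical(1))), integer(1)))
  frac <- nrow(ds$arrays$arrays) / n_true
  se <- sqrt(0.8 * 0.2 / n_true)
  expect_lt(abs(frac - 0.8), 3.5 * se)
})

test_that("the generator is reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 2L, n_lineages_per_subject = 2L,
                    rng_seed = 61L)
  a <- emit_observed_dataset(simulate_community(cfg))
  b <- emit_observed_dataset(simulate_community(cfg))
  expect_identical(a$arrays$arrays$array_id, b$arrays$arrays$array_id)
  expect_identical(a$arrays$spacer_seqs, b$arrays$spacer_seqs)
  expect_identical(a$abundance, b$abundance)
})
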