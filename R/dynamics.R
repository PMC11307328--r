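# Longitudinal immunity dynamics. An acquisition episode is one
# spacer-protospacer pair followed through a subject's timeline together
# with its CRISPR lineage. Episodes are eligible when the spacer first
# appears strictly later than its lineage (so a pre-acquisition baseline
# exists) and is present in at least `min_spacer_samples` samples;
# samples where the lineage is not detected are excluded throughout.
# Phase statistics compare max-normalized target abundance and target
# prevalence across the four phases (before, acquisition, after with
# spacer, after without spacer).

#' Normalize an abundance series by its maximum
#'
#' @param series numeric vector with at least one positive value.
#' @return series / max(series); zeros are preserved, the maximum maps
#'   to 1.
#' @export
normalize_by_max <- function(series) {
  m <- max(series)
  if (!is.finite(m) || m <= 0) {
    stop("all-zero (or invalid) series cannot be max-normalized",
         call. = FALSE)
  }
  series / m
}

#' Assign phases to an episode's retained samples
#'
#' @param timepoints integer timepoints at which the lineage is present
#'   (sorted).
#' @param spacer_at logical vector: spacer present at each timepoint.
#' @return character vector of phase labels per retained timepoint:
#'   `before` (earlier than the acquisition sample), `acquisition` (the
#'   first sample with the spacer), `after_with_spacer`,
#'   `after_no_spacer`.
#' @export
phase_assignment <- function(timepoints, spacer_at) {
  stopifnot(length(timepoints) == length(spacer_at), any(spacer_at))
  acq <- timepoints[which(spacer_at)[1L]]
  ifelse(timepoints < acq, "before",
         ifelse(timepoints == acq, "acquisition",
                ifelse(spacer_at, "after_with_spacer", "after_no_spacer")))
}

#' Select eligible acquisition episodes
#'
#' Builds one episode per (spacer, lineage, target) triple from the local
#' hit table, keeping triples where (1) the spacer's first appearance in
#' the lineage is strictly later than the lineage's first appearance and
#' (2) the spacer is present in at least `min_spacer_samples` retained
#' samples. When one (spacer, target) pair is carried by several
#' lineages, the lineage observed earliest (ties: lexicographic id) is
#' kept so each pair yields one episode.
#'
#' @param ds a `crispr_dataset` (contigs must carry a `target_id`
#'   column linking protospacer-bearing contigs to abundance targets).
#' @param lineage_result output of [build_all_lineages()].
#' @param local_hits filtered local hit table.
#' @param params a [crispr_params()] object.
#' @return `data.table` of episodes: `episode_id`, `spacer_id`,
#'   `lineage_id`, `target_id`, `subject`, `acquisition_tp`, plus
#'   list-columns `timepoints`, `spacer_at`, `target_at`, `phase`.
#' @export
select_episodes <- function(ds, lineage_result, local_hits,
                            params = crispr_params()) {
  empty <- data.table::data.table(
    episode_id = character(0), spacer_id = character(0),
    lineage_id = character(0), target_id = character(0),
    subject = character(0), acquisition_tp = integer(0)
  )
  if (nrow(local_hits) == 0L) return(empty)
  ctg <- ds$contigs
  if (!"target_id" %in% names(ctg)) {
    stop("contigs need a target_id column for episode selection",
         call. = FALSE)
  }
  tmap <- stats::setNames(ctg$target_id, ctg$contig_id)
  hits <- data.table::as.data.table(local_hits)
  hits[, target_id := unname(tmap[subject_id])]
  pairs <- unique(hits[!is.na(target_id),
                       c("spacer_id", "subject", "target_id")])
  if (nrow(pairs) == 0L) return(empty)

  arr <- ds$arrays$arrays
  memb <- lineage_result$membership
  lin_of_array <- stats::setNames(memb$lineage_id, memb$array_id)
  # strand-insensitive spacer content per (lineage, timepoint)
  canon_map <- stats::setNames(
    canonical_seq(unname(ds$arrays$spacer_seqs)),
    names(ds$arrays$spacer_seqs))
  occ <- data.table::data.table(
    lineage_id = rep(unname(lin_of_array[arr$array_id]),
                     lengths(arr$spacers)),
    timepoint = rep(arr$timepoint, lengths(arr$spacers)),
    canon = unname(canon_map[unlist(arr$spacers)])
  )
  occ <- unique(occ)
  lin_presence <- unique(data.table::data.table(
    lineage_id = unname(lin_of_array[arr$array_id]),
    subject = arr$subject, timepoint = arr$timepoint))

  # target presence per (target, subject, timepoint) from the observed
  # abundance table (undetected samples are zero)
  ab <- ds$abundance

  episodes <- list()
  eid <- 0L
  for (r in seq_len(nrow(pairs))) {
    sid <- pairs$spacer_id[r]
    subj <- pairs$subject[r]
    tid <- pairs$target_id[r]
    sc <- canon_map[[sid]]
    lins <- unique(occ$lineage_id[occ$canon == sc])
    lins <- intersect(lins,
                      lin_presence$lineage_id[lin_presence$subject == subj])
    if (!length(lins)) next
    # first appearance of each candidate lineage
    lin_first <- vapply(lins, function(l) {
      min(lin_presence$timepoint[lin_presence$lineage_id == l])
    }, numeric(1))
    best <- NULL
    for (l in lins[order(lin_first, lins)]) {
      tps <- sort(unique(
        lin_presence$timepoint[lin_presence$lineage_id == l]))
      sp_at <- vapply(tps, function(t) {
        any(occ$lineage_id == l & occ$timepoint == t & occ$canon == sc)
      }, logical(1))
      if (!any(sp_at)) next
      acq_tp <- tps[which(sp_at)[1L]]
      if (acq_tp <= min(tps)) next              # no pre-acquisition baseline
      if (sum(sp_at) < params$min_spacer_samples) next
      best <- list(lineage = l, tps = tps, sp_at = sp_at, acq = acq_tp)
      break
    }
    if (is.null(best)) next
    tg_present <- function(tset) vapply(tset, function(t) {
      v <- ab$abundance[ab$target_id == tid & ab$subject == subj &
                          ab$sample == t]
      length(v) > 0 && any(v > 0)
    }, logical(1))
    tg_at <- tg_present(best$tps)
    # full subject timeline for state-string encoding
    all_tps <- sort(unique(ds$samples$timepoint[ds$samples$subject == subj]))
    tl_lineage <- all_tps %in% best$tps
    tl_spacer <- all_tps %in% best$tps[best$sp_at]
    tl_target <- tg_present(all_tps)
    eid <- eid + 1L
    episodes[[eid]] <- data.table::data.table(
      episode_id = sprintf("E%04d", eid), spacer_id = sid,
      lineage_id = best$lineage, target_id = tid, subject = subj,
      acquisition_tp = best$acq,
      timepoints = list(best$tps), spacer_at = list(best$sp_at),
      target_at = list(tg_at),
      phase = list(phase_assignment(best$tps, best$sp_at)),
      tl_timepoints = list(all_tps), tl_lineage = list(tl_lineage),
      tl_spacer = list(tl_spacer), tl_target = list(tl_target)
    )
  }
  if (!length(episodes)) return(empty)
  data.table::rbindlist(episodes)
}

#' Per-sample relative abundance of a target's neighborhood
#'
#' Real-data adapter: abundance = mapped reads / mapped length / total
#' reads in the sample, with the 4 kb neighborhood clipped at contig ends
#' (the normalization uses the clipped length). The default synthetic
#' path consumes a precomputed abundance table instead.
#'
#' @param reads integer vector of mapped reads per sample.
#' @param total_reads integer vector of total reads per sample.
#' @param proto_start,proto_end protospacer coordinates on the contig.
#' @param contig_len contig length.
#' @param flank neighborhood flank in nt (default 2000).
#' @param detected logical per sample; undetected samples are set to 0.
#' @return numeric vector of relative abundances.
#' @export
target_abundance_series <- function(reads, total_reads, proto_start,
                                    proto_end, contig_len, flank = 2000L,
                                    detected = rep(TRUE, length(reads))) {
  stopifnot(length(reads) == length(total_reads))
  if (any(total_reads <= 0)) {
    stop("sample with zero total reads: abundance undefined", call. = FALSE)
  }
  lo <- max(0L, proto_start - flank)
  hi <- min(contig_len, proto_end + flank)
  len <- hi - lo
  out <- reads / len / total_reads
  out[!detected] <- 0
  out
}

# percentile bootstrap CI of the median
.boot_median_ci <- function(x, n_boot, level) {
  if (length(x) == 0L) return(c(NA_real_, NA_real_))
  meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(x, replace = TRUE))
  }, numeric(1))
  stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}

#' Phase statistics over a set of episodes
#'
#' Pools max-normalized target abundances per phase across episodes
#' (each target's series is normalized by its maximum over the subject's
#' whole timeline); reports the median with a percentile bootstrap CI,
#' target prevalence with a Clopper-Pearson CI, two-sided Mann-Whitney
#' tests for all phase pairs with data, and Fisher's exact tests on
#' prevalence.
#'
#' @param episodes episode table from [select_episodes()].
#' @param abundance abundance table (`target_id`, `subject`, `sample`,
#'   `abundance`; `sample` is the integer timepoint).
#' @param params a [crispr_params()] object (bootstraps, CI level).
#' @return list with `summary` (per-phase `data.table`), `tests`
#'   (abundance rank tests), `prevalence_tests` (Fisher), and `pooled`
#'   (per-sample rows with phase and normalized abundance).
#' @export
phase_statistics <- function(episodes, abundance,
                             params = crispr_params()) {
  phases <- c("before", "acquisition", "after_with_spacer",
              "after_no_spacer")
  ab <- data.table::as.data.table(abundance)
  pooled <- list()
  for (i in seq_len(nrow(episodes))) {
    tid <- episodes$target_id[i]; subj <- episodes$subject[i]
    series <- ab[ab$target_id == tid & ab$subject == subj, ]
    if (nrow(series) == 0L || max(series$abundance) <= 0) next
    norm <- stats::setNames(normalize_by_max(series$abundance),
                            series$sample)
    tps <- episodes$timepoints[[i]]
    pooled[[length(pooled) + 1L]] <- data.table::data.table(
      episode_id = episodes$episode_id[i],
      timepoint = tps,
      phase = episodes$phase[[i]],
      norm_abundance = unname(norm[as.character(tps)]),
      target_present = episodes$target_at[[i]]
    )
  }
  pooled <- if (length(pooled)) data.table::rbindlist(pooled) else
    data.table::data.table(episode_id = character(0),
                           timepoint = integer(0), phase = character(0),
                           norm_abundance = numeric(0),
                           target_present = logical(0))
  summary <- data.table::data.table(phase = phases, n = 0L,
                                    median = NA_real_, ci_lo = NA_real_,
                                    ci_hi = NA_real_,
                                    prevalence = NA_real_,
                                    prev_ci_lo = NA_real_,
                                    prev_ci_hi = NA_real_)
  for (i in seq_along(phases)) {
    x <- pooled$norm_abundance[pooled$phase == phases[i]]
    pres <- pooled$target_present[pooled$phase == phases[i]]
    data.table::set(summary, i, "n", length(x))
    if (length(x)) {
      ci <- .boot_median_ci(x, params$n_bootstraps, params$ci_level)
      data.table::set(summary, i, "median", stats::median(x))
      data.table::set(summary, i, "ci_lo", ci[1])
      data.table::set(summary, i, "ci_hi", ci[2])
      pci <- clopper_pearson(sum(pres), length(pres), params$ci_level)
      data.table::set(summary, i, "prevalence", mean(pres))
      data.table::set(summary, i, "prev_ci_lo", pci[["lower"]])
      data.table::set(summary, i, "prev_ci_hi", pci[["upper"]])
    }
  }
  tests <- list(); ptests <- list()
  for (a in seq_along(phases)) for (b in seq_along(phases)) {
    if (b <= a) next
    xa <- pooled$norm_abundance[pooled$phase == phases[a]]
    xb <- pooled$norm_abundance[pooled$phase == phases[b]]
    if (length(xa) && length(xb)) {
      wt <- suppressWarnings(stats::wilcox.test(xa, xb))
      tests[[length(tests) + 1L]] <- data.table::data.table(
        phase_a = phases[a], phase_b = phases[b],
        statistic = unname(wt$statistic), p = wt$p.value)
      pa <- pooled$target_present[pooled$phase == phases[a]]
      pb <- pooled$target_present[pooled$phase == phases[b]]
      ft <- stats::fisher.test(matrix(c(sum(pa), sum(!pa),
                                        sum(pb), sum(!pb)), 2L))
      ptests[[length(ptests) + 1L]] <- data.table::data.table(
        phase_a = phases[a], phase_b = phases[b],
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  list(summary = summary,
       tests = if (length(tests)) data.table::rbindlist(tests) else NULL,
       prevalence_tests = if (length(ptests))
         data.table::rbindlist(ptests) else NULL,
       pooled = pooled)
}

#' Lineage diversity and selective-sweep analysis
#'
#' Active lineages carry at least one locally adapted spacer. The
#' analysis reports (i) the number of distinct member arrays per lineage
#' for active vs inactive lineages; (ii) for each active lineage, the
#' number of distinct arrays observed per sample, split by whether any
#' of its targeted MGE is detected in that sample; and (iii) the
#' observed percentage of array occurrences (in active lineages, in
#' MGE-containing samples) that carry a cognate spacer for a co-sampled
#' MGE, against the expectation when arrays are drawn at random from the
#' same pool, with a bootstrap CI.
#'
#' @param ds a `crispr_dataset`.
#' @param lineage_result output of [build_all_lineages()].
#' @param local_hits filtered local hit table.
#' @param params a [crispr_params()] object.
#' @return list with `diversity` (per-lineage table), `split` (arrays
#'   per sample with/without MGE), `sweep` (observed vs randomized
#'   percentages with CI).
#' @export
diversity_analysis <- function(ds, lineage_result, local_hits,
                               params = crispr_params()) {
  arr <- ds$arrays$arrays
  memb <- lineage_result$membership
  lin_of_array <- stats::setNames(memb$lineage_id, memb$array_id)
  ctg <- ds$contigs
  tmap <- stats::setNames(ctg$target_id, ctg$contig_id)
  hits <- data.table::as.data.table(local_hits)
  if (nrow(hits)) hits[, target_id := unname(tmap[subject_id])]

  # spacer (canonical) -> targeted MGE set
  canon_map <- stats::setNames(
    canonical_seq(unname(ds$arrays$spacer_seqs)),
    names(ds$arrays$spacer_seqs))
  sp_targets <- if (nrow(hits)) {
    ht <- hits[!is.na(target_id), ]
    split(ht$target_id, canon_map[ht$spacer_id])
  } else list()

  # per-array targeted MGE set and signature
  arr_sig <- vapply(arr$spacers, function(v) {
    paste(sort(unique(unname(canon_map[v]))), collapse = "|")
  }, character(1))
  arr_targets <- lapply(arr$spacers, function(v) {
    unique(unlist(sp_targets[unname(canon_map[v])]))
  })
  lin_ids <- unname(lin_of_array[arr$array_id])

  lin_targets <- lapply(split(arr_targets, lin_ids), function(l)
    unique(unlist(l)))
  active <- vapply(lin_targets, function(v) length(v) > 0L, logical(1))

  diversity <- data.table::data.table(
    lineage_id = names(lin_targets),
    n_distinct_arrays = vapply(split(arr_sig, lin_ids), function(s)
      length(unique(s)), integer(1)),
    active = active
  )

  ab <- ds$abundance
  mge_present <- function(subj, tp, targets) {
    if (!length(targets)) return(FALSE)
    any(ab$abundance[ab$subject == subj & ab$sample == tp &
                       ab$target_id %in% targets] > 0)
  }

  # (ii) arrays per (active lineage, sample), split by MGE presence
  split_rows <- list()
  occ_rows <- list()
  for (l in names(lin_targets)[active]) {
    sel <- which(lin_ids == l)
    subj <- arr$subject[sel[1L]]
    for (tp in sort(unique(arr$timepoint[sel]))) {
      at <- sel[arr$timepoint[sel] == tp]
      with_mge <- mge_present(subj, tp, lin_targets[[l]])
      split_rows[[length(split_rows) + 1L]] <- data.table::data.table(
        lineage_id = l, timepoint = tp, mge_present = with_mge,
        n_arrays = length(unique(arr_sig[at])))
      if (with_mge) {
        for (i in at) {
          # does this array target an MGE present in this very sample?
          tg <- arr_targets[[i]]
          immune <- length(tg) > 0 && mge_present(subj, tp, tg)
          occ_rows[[length(occ_rows) + 1L]] <- data.table::data.table(
            lineage_id = l, subject = subj, timepoint = tp,
            array_idx = i, immune = immune)
        }
      }
    }
  }
  split_dt <- if (length(split_rows)) data.table::rbindlist(split_rows)
              else NULL
  occ <- if (length(occ_rows)) data.table::rbindlist(occ_rows) else NULL

  sweep <- NULL
  if (!is.null(occ) && nrow(occ) > 0L) {
    observed <- 100 * mean(occ$immune)
    # randomization: draw arrays uniformly from the occurrence pool and
    # pair them with the pool's (subject, timepoint) slots at random;
    # the immune indicator is precomputed for every (array, slot) pair
    idx_pool <- occ$array_idx
    uniq_arr <- unique(idx_pool)
    slot_key <- paste(occ$subject, occ$timepoint)
    uniq_slot <- !duplicated(slot_key)
    slot_ids <- slot_key[uniq_slot]
    slot_subj <- occ$subject[uniq_slot]; slot_tp <- occ$timepoint[uniq_slot]
    imm_mat <- matrix(FALSE, length(uniq_arr), length(slot_ids),
                      dimnames = list(NULL, slot_ids))
    for (ai in seq_along(uniq_arr)) {
      tg <- arr_targets[[uniq_arr[ai]]]
      if (!length(tg)) next
      for (si in seq_along(slot_ids)) {
        imm_mat[ai, si] <- mge_present(slot_subj[si], slot_tp[si], tg)
      }
    }
    arr_row <- match(idx_pool, uniq_arr)
    slot_col <- match(slot_key, slot_ids)
    rand_pct <- vapply(seq_len(params$n_bootstraps), function(b) {
      pick <- arr_row[sample(length(arr_row), replace = TRUE)]
      100 * mean(imm_mat[cbind(pick, slot_col)])
    }, numeric(1))
    a <- (1 - params$ci_level) / 2
    obs_boot <- vapply(seq_len(params$n_bootstraps), function(b) {
      100 * mean(sample(occ$immune, replace = TRUE))
    }, numeric(1))
    sweep <- data.table::data.table(
      observed_pct = observed,
      observed_ci_lo = stats::quantile(obs_boot, a, names = FALSE),
      observed_ci_hi = stats::quantile(obs_boot, 1 - a, names = FALSE),
      expected_pct = mean(rand_pct),
      expected_ci_lo = stats::quantile(rand_pct, a, names = FALSE),
      expected_ci_hi = stats::quantile(rand_pct, 1 - a, names = FALSE),
      n_occurrences = nrow(occ))
  }
  list(diversity = diversity, split = split_dt, sweep = sweep)
}
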