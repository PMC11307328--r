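# Synthetic longitudinal communities with planted ground truth.
#
# The generator emulates the structure of a longitudinal gut-metagenome
# CRISPR study: per-subject host lineages carrying CRISPR arrays that gain
# spacers at the leader end and lose spacers anywhere, an MGE pool with
# designated protospacer windows (half of them reverse-complemented),
# abundance series with a planted immunity effect, and an observation
# layer (detection dropout, assembly truncation, random assembly strand)
# emulating metagenomic incompleteness. All planted events are returned as
# a truth object so recovery can be scored.

#' Simulation configuration
#'
#' Defaults mirror the structure of the study system: array sizes follow a
#' discrete truncated power law with exponent 2 and cutoff 100 spacers;
#' spacers are 34 nt and repeats 31 nt (the average lengths in gut CRISPR
#' assemblies); subjects are sampled at 12 timepoints (the average number
#' of metagenomes per individual in the cohort the pipeline targets);
#' immunity multiplies target abundance by 0.3 while a cognate spacer is
#' present. Gain/loss rates are not quantified in the literature for the
#' gut; defaults are chosen for statistical power and documented as such.
#'
#' @param ... overrides of the default fields (unknown names rejected).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(...) {
  d <- list(
    n_subjects = 5L,
    n_samples_per_subject = 12L,
    n_lineages_per_subject = 5L,
    size_alpha = 2.0,
    size_cutoff = 100,
    spacer_len = 34L,
    repeat_len = 31L,
    gain_rate = 0.4,
    loss_rate = 0.02,
    n_mge = 30L,
    mge_len = 2000L,
    n_proto_per_mge = 3L,
    mge_class_mix = c(lytic_or_nonlysogenic_phage = 0.45,
                      lysogenic_phage = 0.25,
                      plasmid = 0.20,
                      other_mge = 0.10),
    crass_frac = 0.15,
    infant_frac = 0.05,
    local_frac = 0.10,
    immunity_multiplier = 0.3,
    acquisition_boost = 2.0,
    noise_sd = 0.3,
    detection_prob = 0.9,
    truncation_prob = 0.1,
    orient_known_prob = 0.7,
    detection_quantile = 0.10,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(d))
  if (length(unknown)) stop("unknown sim_config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(over)) d[[k]] <- over[[k]]
  if (abs(sum(d$mge_class_mix) - 1) > 1e-9) {
    stop("mge_class_mix must sum to 1", call. = FALSE)
  }
  probs <- c(d$crass_frac, d$infant_frac, d$local_frac, d$detection_prob,
             d$truncation_prob, d$orient_known_prob, d$loss_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (d$size_alpha <= 1 && !is.finite(d$size_cutoff)) {
    stop("size_alpha must exceed 1 when size_cutoff is infinite",
         call. = FALSE)
  }
  if (d$size_cutoff < 0) stop("size_cutoff must be positive", call. = FALSE)
  structure(d, class = "sim_config")
}

# normalized mass function of the discrete truncated power law
# P(k) propto k^(-alpha) exp(-k/cutoff), k = 1..kmax
.tpl_logweights <- function(alpha, cutoff, kmax) {
  k <- seq_len(kmax)
  -alpha * log(k) - k / cutoff
}

#' Sample array sizes from a discrete truncated power law
#'
#' Draws from P(k) proportional to k^(-alpha) * exp(-k / cutoff) on
#' k = 1, 2, ... via an inverse-CDF table truncated where the tail mass is
#' negligible.
#'
#' @param n number of draws.
#' @param alpha power-law exponent (> 1 when cutoff is infinite).
#' @param cutoff exponential cutoff in spacers (>= small positive).
#' @return integer vector of `n` sizes >= 1.
#' @export
sample_array_sizes <- function(n, alpha = 2.0, cutoff = 100) {
  if (n == 0L) return(integer(0))
  if (!is.finite(cutoff) && alpha <= 1) {
    stop("non-normalizable: alpha <= 1 with infinite cutoff", call. = FALSE)
  }
  kmax <- if (is.finite(cutoff)) {
    as.integer(max(1000, min(1e6, ceiling(50 * max(cutoff, 1)))))
  } else 1000000L
  lw <- .tpl_logweights(alpha, cutoff, kmax)
  w <- exp(lw - max(lw))
  sample.int(kmax, size = n, replace = TRUE, prob = w)
}

#' Fit a discrete truncated power law by maximum likelihood
#'
#' Maximizes the log-likelihood of P(k) proportional to
#' k^(-alpha) * exp(-k / cutoff) over a coarse (alpha, cutoff) grid
#' followed by Nelder-Mead refinement on transformed parameters. The
#' normalizing constant is computed by direct summation.
#'
#' @param sizes integer observations, all >= 1, length >= 100.
#' @param cutoff_max upper search bound for the cutoff; an estimate at
#'   this boundary is flagged (pure power-law regime).
#' @return list with `alpha_hat`, `cutoff_hat`, `loglik`, `boundary`
#'   (TRUE when the cutoff estimate sits at the search boundary) and a
#'   `loglik_fun(alpha, cutoff)` closure for inspection.
#' @export
fit_truncated_powerlaw <- function(sizes, cutoff_max = 1e4) {
  if (length(sizes) < 100L) stop("need >= 100 observations", call. = FALSE)
  if (any(sizes < 1)) stop("all sizes must be >= 1", call. = FALSE)
  if (length(unique(sizes)) == 1L) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  n <- length(sizes)
  slog <- sum(log(sizes))
  ssum <- sum(sizes)
  kmax <- max(10L * max(sizes), 1e5L)
  k <- seq_len(kmax)
  lk <- log(k)
  loglik_fun <- function(alpha, cutoff) {
    lw <- -alpha * lk - k / cutoff
    m <- max(lw)
    logZ <- m + log(sum(exp(lw - m)))
    -alpha * slog - ssum / cutoff - n * logZ
  }
  alphas <- seq(1.05, 3.5, by = 0.07)
  cuts <- exp(seq(log(2), log(cutoff_max), length.out = 25))
  grid_ll <- matrix(NA_real_, length(alphas), length(cuts))
  for (i in seq_along(alphas)) for (j in seq_along(cuts)) {
    grid_ll[i, j] <- loglik_fun(alphas[i], cuts[j])
  }
  best <- arrayInd(which.max(grid_ll), dim(grid_ll))
  a0 <- alphas[best[1]]; c0 <- cuts[best[2]]
  obj <- function(par) {
    a <- 1 + exp(par[1]); cc <- min(exp(par[2]), cutoff_max)
    -loglik_fun(a, cc)
  }
  opt <- stats::optim(c(log(a0 - 1), log(c0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 300))
  alpha_hat <- 1 + exp(opt$par[1])
  cutoff_hat <- min(exp(opt$par[2]), cutoff_max)
  list(alpha_hat = alpha_hat, cutoff_hat = cutoff_hat,
       loglik = -opt$value,
       boundary = cutoff_hat >= 0.95 * cutoff_max,
       loglik_fun = loglik_fun)
}

#' Generate an MGE pool with designated protospacer windows
#'
#' Random ACGT sequences with a class drawn from the configured mix,
#' integrase flags consistent with the lysogenic class, crAss-like and
#' infant-gut tags, and `n_proto_per_mge` non-overlapping protospacer
#' windows per record. About half of all planted protospacers are stored
#' reverse-complemented in the MGE (strand `-`): the cognate spacer equals
#' the reverse complement of the MGE window.
#'
#' @param config a [sim_config()].
#' @return list with `mge` (`data.table`: mge_id, seq, class, base_class,
#'   integrase, crass_like, infant_gut) and `protospacers` (`data.table`:
#'   proto_id, mge_id, start, end, strand, spacer_seq).
#' @export
generate_mge_pool <- function(config) {
  n <- config$n_mge
  classes <- sample(names(config$mge_class_mix), n, replace = TRUE,
                    prob = config$mge_class_mix)
  mge <- data.table::data.table(
    mge_id = sprintf("MGE%03d", seq_len(n)),
    seq = random_dna(n, config$mge_len),
    class = classes,
    base_class = ifelse(classes %in% c("lytic_or_nonlysogenic_phage",
                                       "lysogenic_phage"),
                        "virus", classes),
    integrase = classes == "lysogenic_phage",
    crass_like = FALSE, infant_gut = FALSE
  )
  viral <- mge$class %in% c("lytic_or_nonlysogenic_phage", "lysogenic_phage")
  mge$crass_like <- viral & stats::runif(n) < config$crass_frac
  mge$infant_gut <- viral & stats::runif(n) < config$infant_frac
  L <- config$spacer_len
  protos <- list()
  for (i in seq_len(n)) {
    # non-overlapping windows on a regular lattice, jittered
    slots <- floor(config$mge_len / (L + 10L))
    take <- sort(sample.int(slots, min(config$n_proto_per_mge, slots)))
    for (s in take) {
      start <- (s - 1L) * (L + 10L) + sample.int(10L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      window <- substr(mge$seq[i], start + 1L, start + L)
      protos[[length(protos) + 1L]] <- data.table::data.table(
        mge_id = mge$mge_id[i], start = start, end = start + L,
        strand = strand,
        spacer_seq = if (strand == "+") window else revcomp(window)
      )
    }
  }
  protospacers <- data.table::rbindlist(protos)
  protospacers[, proto_id := sprintf("P%04d", seq_len(.N))]
  data.table::setcolorder(protospacers, "proto_id")
  list(mge = mge, protospacers = protospacers)
}

#' Evolve one CRISPR lineage across a timeline
#'
#' Starting from an initial array (leader first), each subsequent sample
#' loses each spacer independently with `loss_rate` (survivors keep their
#' relative order: true arrays never rearrange) and gains
#' Poisson(`gain_rate`) new spacers at the leader end, each copied from a
#' protospacer window of the MGE pool on a random strand. Every gain is
#' logged as a candidate acquisition event.
#'
#' @param initial_spacers character vector of spacer sequences, leader
#'   first; must be non-empty.
#' @param n_samples number of timepoints (the initial array is sample 1).
#' @param gain_rate expected leader-end gains per sample.
#' @param loss_rate per-spacer loss probability per sample.
#' @param protospacers protospacer table from [generate_mge_pool()].
#' @return list with `arrays` (list of per-sample character vectors) and
#'   `acquisitions` (`data.table`: sample, spacer_seq, mge_id, proto_id).
#' @export
evolve_lineage <- function(initial_spacers, n_samples, gain_rate, loss_rate,
                           protospacers) {
  stopifnot(length(initial_spacers) >= 1L, n_samples >= 1L)
  arrays <- vector("list", n_samples)
  arrays[[1L]] <- initial_spacers
  acq <- list()
  cur <- initial_spacers
  for (t in seq_len(n_samples)[-1L]) {
    if (length(cur) && loss_rate > 0) {
      keep <- stats::runif(length(cur)) >= loss_rate
      cur <- cur[keep]
    }
    ngain <- stats::rpois(1L, gain_rate)
    if (ngain > 0L && nrow(protospacers) > 0L) {
      pick <- sample.int(nrow(protospacers), ngain, replace = TRUE)
      for (p in pick) {
        sp <- protospacers$spacer_seq[p]
        # re-acquisition of a protospacer already represented in the
        # array is skipped: existing immunity blocks it, and duplicate
        # spacers would break the no-rearrangement guarantee
        if (canonical_seq(sp) %in% canonical_seq(cur)) next
        # the spacer itself is stored on a random strand in the array
        if (stats::runif(1) < 0.5) sp <- revcomp(sp)
        cur <- c(sp, cur)
        acq[[length(acq) + 1L]] <- data.table::data.table(
          sample = t, spacer_seq = sp,
          mge_id = protospacers$mge_id[p],
          proto_id = protospacers$proto_id[p]
        )
      }
    }
    arrays[[t]] <- cur
  }
  list(arrays = arrays,
       acquisitions = if (length(acq)) data.table::rbindlist(acq) else
         data.table::data.table(sample = integer(0),
                                spacer_seq = character(0),
                                mge_id = character(0),
                                proto_id = character(0)))
}

#' Simulate abundance series with a planted immunity effect
#'
#' Each MGE gets a lognormal(0, 1) baseline per subject (a stable
#' colonization level). At an acquisition sample the target's abundance is
#' multiplied by `acquisition_boost`; in later samples where a cognate
#' spacer is present in the subject it is multiplied by
#' `immunity_multiplier`; multiplicative lognormal noise (sd `noise_sd`)
#' is applied last.
#'
#' @param mge_ids character vector of MGE ids.
#' @param subjects character vector of subject ids.
#' @param n_samples samples per subject.
#' @param spacer_present logical array indexed `[mge, subject, sample]`:
#'   cognate spacer present in that subject at that sample.
#' @param acquisition logical array, same shape: acquisition of a cognate
#'   spacer happened at that sample.
#' @param immunity_multiplier,acquisition_boost,noise_sd effect sizes.
#' @return list with `abundance` (`data.table`: target_id, subject,
#'   sample, abundance) and `baseline` (matrix mge x subject).
#' @export
simulate_abundances <- function(mge_ids, subjects, n_samples,
                                spacer_present, acquisition,
                                immunity_multiplier = 0.3,
                                acquisition_boost = 2.0,
                                noise_sd = 0.3) {
  nm <- length(mge_ids); ns <- length(subjects)
  baseline <- matrix(stats::rlnorm(nm * ns, 0, 1), nm, ns,
                     dimnames = list(mge_ids, subjects))
  rows <- list()
  for (j in seq_len(ns)) for (t in seq_len(n_samples)) {
    ab <- baseline[, j]
    boost <- acquisition[, j, t]
    immune <- spacer_present[, j, t] & !boost
    ab[boost] <- ab[boost] * acquisition_boost
    ab[immune] <- ab[immune] * immunity_multiplier
    if (noise_sd > 0) ab <- ab * stats::rlnorm(nm, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      target_id = mge_ids, subject = subjects[j], sample = t, abundance = ab
    )
  }
  list(abundance = data.table::rbindlist(rows), baseline = baseline)
}

#' Simulate a full community with planted truth
#'
#' Orchestrates the generator: MGE pool, per-subject lineages evolved over
#' the timeline, and abundance series with the configured immunity effect.
#' A fraction `local_frac` of each initial array's spacers are copies of
#' protospacer windows (pre-study local adaptation); all later gains are
#' protospacer copies.
#'
#' @param config a [sim_config()].
#' @return object of class `community_truth`: list with `config`, `pool`,
#'   `lineages` (per-lineage per-sample true arrays), `acquisitions`,
#'   `abundance`, `presence` (target detection by sample),
#'   `detection_floor`.
#' @export
simulate_community <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  pool <- generate_mge_pool(config)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  nT <- config$n_samples_per_subject

  lineages <- list()
  acq_all <- list()
  for (sj in subjects) {
    for (li in seq_len(config$n_lineages_per_subject)) {
      lid <- sprintf("%s_lin%02d", sj, li)
      sz <- sample_array_sizes(1L, config$size_alpha, config$size_cutoff)
      sz <- max(2L, min(sz, 60L))  # cap for desk-scale runtime
      init <- random_dna(sz, config$spacer_len)
      n_local <- min(stats::rbinom(1L, sz, config$local_frac),
                     nrow(pool$protospacers))
      if (n_local > 0L && nrow(pool$protospacers) > 0L) {
        at <- sample.int(sz, n_local)
        # without replacement: one lineage never carries the same
        # protospacer twice (no-rearrangement guarantee)
        pk <- sample.int(nrow(pool$protospacers), n_local)
        sp <- pool$protospacers$spacer_seq[pk]
        flip <- stats::runif(n_local) < 0.5
        sp[flip] <- revcomp(sp[flip])
        init[at] <- sp
      }
      # lineage appears at a random early sample, persists to the end
      first_seen <- sample.int(max(1L, nT %/% 3L), 1L)
      ev <- evolve_lineage(init, nT - first_seen + 1L,
                           config$gain_rate, config$loss_rate,
                           pool$protospacers)
      arrays <- c(vector("list", first_seen - 1L), ev$arrays)
      acq <- ev$acquisitions
      if (nrow(acq)) acq[, sample := sample + first_seen - 1L]
      if (nrow(acq)) {
        acq[, `:=`(subject = sj, lineage_id = lid)]
        acq_all[[length(acq_all) + 1L]] <- acq
      }
      lineages[[lid]] <- list(lineage_id = lid, subject = sj,
                              repeat_seq = random_dna(1L, config$repeat_len),
                              subtype = sample(c("I-C", "I-E", "II-A"), 1L),
                              first_seen = first_seen,
                              arrays = arrays)
    }
  }
  acquisitions <- if (length(acq_all)) data.table::rbindlist(acq_all) else
    data.table::data.table(sample = integer(0), spacer_seq = character(0),
                           mge_id = character(0), proto_id = character(0),
                           subject = character(0), lineage_id = character(0))

  # cognate-spacer presence per (mge, subject, sample), strand-insensitive
  canon_proto <- canonical_seq(pool$protospacers$spacer_seq)
  mge_of_canon <- split(pool$protospacers$mge_id, canon_proto)
  nm <- nrow(pool$mge)
  spacer_present <- array(FALSE, c(nm, length(subjects), nT),
                          dimnames = list(pool$mge$mge_id, subjects, NULL))
  acq_flag <- array(FALSE, c(nm, length(subjects), nT),
                    dimnames = list(pool$mge$mge_id, subjects, NULL))
  for (lin in lineages) {
    j <- match(lin$subject, subjects)
    for (t in seq_len(nT)) {
      arr <- lin$arrays[[t]]
      if (is.null(arr) || !length(arr)) next
      hit <- unique(unlist(mge_of_canon[canonical_seq(arr)]))
      if (length(hit)) spacer_present[hit, j, t] <- TRUE
    }
  }
  if (nrow(acquisitions)) {
    for (r in seq_len(nrow(acquisitions))) {
      j <- match(acquisitions$subject[r], subjects)
      acq_flag[acquisitions$mge_id[r], j, acquisitions$sample[r]] <- TRUE
    }
  }

  ab <- simulate_abundances(pool$mge$mge_id, subjects, nT,
                            spacer_present, acq_flag,
                            config$immunity_multiplier,
                            config$acquisition_boost,
                            config$noise_sd)
  floor_q <- stats::quantile(ab$abundance$abundance,
                             config$detection_quantile, names = FALSE)
  presence <- ab$abundance[, list(target_id, subject, sample,
                                  present = abundance > floor_q)]
  structure(list(config = config, pool = pool, subjects = subjects,
                 lineages = lineages, acquisitions = acquisitions,
                 abundance = ab$abundance, baseline = ab$baseline,
                 presence = presence, detection_floor = floor_q),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf(
    "community_truth: %d subjects x %d samples, %d lineages, %d MGE, %d acquisitions\n",
    length(x$subjects), x$config$n_samples_per_subject,
    length(x$lineages), nrow(x$pool$mge), nrow(x$acquisitions)))
  invisible(x)
}

# build the sequence of a CRISPR locus: R s1 R s2 ... R (for contigs)
.array_locus_seq <- function(repeat_seq, spacer_seqs) {
  paste0(paste0(repeat_seq, spacer_seqs, collapse = ""), repeat_seq)
}

#' Emit an observed dataset from a community truth
#'
#' Applies the observation layer: each true array is detected with
#' `detection_prob`; a detected array loses a geometric-length terminal
#' run (random end) with `truncation_prob`; half of all assemblies come
#' out on the reverse strand (spacer order reversed, spacers
#' reverse-complemented), with the orientation label revealed with
#' probability `orient_known_prob`. MGE-bearing contigs are emitted for
#' each sample where the target's abundance exceeds the detection floor,
#' and one contig per observed array locus (with known array intervals for
#' masking). The observed abundance table zeroes undetected samples.
#'
#' @param truth a `community_truth`.
#' @param dir optional directory; when given, all files (arrays.tsv,
#'   spacers.fasta, repeats.fasta, contigs.fasta, mge.fasta,
#'   mge_annotations.tsv, abundance.tsv, truth/ tables) are written there.
#' @return object of class `crispr_dataset`: `arrays` (an `array_set`),
#'   `contigs`, `array_intervals`, `mge_annotations`, `mge_seqs`,
#'   `abundance`, `samples`, plus `truth_membership` (observed array ->
#'   planted lineage) and the `truth` object itself.
#' @export
emit_observed_dataset <- function(truth, dir = NULL) {
  cfg <- truth$config
  nT <- cfg$n_samples_per_subject
  arr_rows <- list()
  truth_membership <- list()
  spacer_seq_pool <- character(0)
  contigs <- list()
  intervals <- list()
  aid <- 0L
  for (lin in truth$lineages) {
    orient_known <- stats::runif(1) < cfg$orient_known_prob
    for (t in seq_len(nT)) {
      arr <- lin$arrays[[t]]
      if (is.null(arr) || !length(arr)) next
      if (stats::runif(1) >= cfg$detection_prob) next
      obs <- arr
      if (length(obs) > 1L && stats::runif(1) < cfg$truncation_prob) {
        run <- min(stats::rgeom(1L, 0.5) + 1L, length(obs) - 1L)
        if (stats::runif(1) < 0.5) obs <- obs[-seq_len(run)]
        else obs <- obs[seq_len(length(obs) - run)]
      }
      aid <- aid + 1L
      array_id <- sprintf("A%05d", aid)
      reversed <- stats::runif(1) < 0.5
      if (reversed) obs <- rev(revcomp(obs))
      orientation <- if (!orient_known) "unknown"
                     else if (reversed) "reverse" else "forward"
      arr_rows[[aid]] <- data.table::data.table(
        array_id = array_id, subject = lin$subject,
        sample = sprintf("%s_t%02d", lin$subject, t), timepoint = t,
        repeat_seq = lin$repeat_seq, orientation = orientation,
        subtype = lin$subtype, spacer_seqs = list(obs)
      )
      truth_membership[[aid]] <- data.table::data.table(
        array_id = array_id, lineage_id = lin$lineage_id)
      spacer_seq_pool <- c(spacer_seq_pool, obs)
      # contig embedding the observed array locus, with random flanks
      locus <- .array_locus_seq(lin$repeat_seq, obs)
      flank <- random_dna(2L, 50L)
      cid <- paste0("ctg_", array_id)
      contigs[[length(contigs) + 1L]] <- data.table::data.table(
        contig_id = cid, subject = lin$subject,
        sample = sprintf("%s_t%02d", lin$subject, t),
        target_id = NA_character_,
        seq = paste0(flank[1], locus, flank[2]))
      intervals[[length(intervals) + 1L]] <- data.table::data.table(
        subject_id = cid, start = 50L, end = 50L + nchar(locus))
    }
  }
  arrays_dt <- data.table::rbindlist(arr_rows)

  # spacer/repeat ids: one id per distinct sequence (strand-sensitive)
  uniq_sp <- unique(spacer_seq_pool)
  sp_ids <- stats::setNames(sprintf("sp%05d", seq_along(uniq_sp)), uniq_sp)
  spacer_seqs <- stats::setNames(uniq_sp, unname(sp_ids))
  uniq_rp <- unique(arrays_dt$repeat_seq)
  rp_ids <- stats::setNames(sprintf("rep%03d", seq_along(uniq_rp)), uniq_rp)
  repeat_seqs <- stats::setNames(uniq_rp, unname(rp_ids))
  arrays <- data.table::data.table(
    array_id = arrays_dt$array_id, subject = arrays_dt$subject,
    sample = arrays_dt$sample, timepoint = arrays_dt$timepoint,
    repeat_id = unname(rp_ids[arrays_dt$repeat_seq]),
    orientation = arrays_dt$orientation, subtype = arrays_dt$subtype,
    spacers = lapply(arrays_dt$spacer_seqs, function(v) unname(sp_ids[v]))
  )
  aset <- new_array_set(arrays, spacer_seqs, repeat_seqs)

  # MGE contigs: present in a sample when abundance exceeds the floor
  det <- truth$presence[truth$presence$present, ]
  if (nrow(det)) {
    mseq <- stats::setNames(truth$pool$mge$seq, truth$pool$mge$mge_id)
    contigs[[length(contigs) + 1L]] <- data.table::data.table(
      contig_id = sprintf("ctg_%s_%s_t%02d", det$target_id, det$subject,
                          det$sample),
      subject = det$subject,
      sample = sprintf("%s_t%02d", det$subject, det$sample),
      target_id = det$target_id,
      seq = unname(mseq[det$target_id]))
  }
  contigs <- data.table::rbindlist(contigs)
  array_intervals <- data.table::rbindlist(intervals)

  abundance <- data.table::copy(truth$abundance)
  abundance <- merge(abundance,
                     truth$presence[, list(target_id, subject, sample,
                                           present)],
                     by = c("target_id", "subject", "sample"))
  abundance[, abundance := ifelse(present, abundance, 0)]
  abundance[, present := NULL]
  data.table::setorder(abundance, target_id, subject, sample)

  mge_annotations <- truth$pool$mge[, list(mge_id, class = base_class,
                                           integrase, crass_like,
                                           infant_gut)]
  samples <- data.table::CJ(subject = truth$subjects,
                            timepoint = seq_len(nT))
  samples[, sample := sprintf("%s_t%02d", subject, timepoint)]

  ds <- structure(list(
    arrays = aset, contigs = contigs, array_intervals = array_intervals,
    mge_annotations = mge_annotations,
    mge_seqs = stats::setNames(truth$pool$mge$seq, truth$pool$mge$mge_id),
    abundance = abundance, samples = samples,
    truth_membership = data.table::rbindlist(truth_membership),
    truth = truth
  ), class = "crispr_dataset")

  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.crispr_dataset <- function(x, ...) {
  cat(sprintf("crispr_dataset: %d arrays, %d contigs, %d MGE, %d abundance rows\n",
              nrow(x$arrays$arrays), nrow(x$contigs),
              nrow(x$mge_annotations), nrow(x$abundance)))
  invisible(x)
}

#' Build the episode table directly from planted truth
#'
#' Test harness: constructs eligible acquisition episodes from the
#' generator's planted acquisition events, bypassing assembly observation
#' and protospacer matching. Useful for validating the phase statistics
#' at scale; the full observation path is exercised by the pipeline.
#'
#' @param truth a `community_truth`.
#' @param min_spacer_samples minimum samples with the spacer (default 2).
#' @return list with `episodes` (same schema as [select_episodes()]) and
#'   `abundance` (truth abundance with sub-detection-floor samples zeroed,
#'   as an observed table would report them).
#' @export
episodes_from_truth <- function(truth, min_spacer_samples = 2L) {
  nT <- truth$config$n_samples_per_subject
  ab <- merge(truth$abundance, truth$presence,
              by = c("target_id", "subject", "sample"))
  ab[, abundance := ifelse(present, abundance, 0)]
  ab[, present := NULL]
  episodes <- list()
  eid <- 0L
  acq <- truth$acquisitions
  if (nrow(acq) == 0L) {
    return(list(episodes = data.table::data.table(), abundance = ab))
  }
  seen <- character(0)
  for (r in seq_len(nrow(acq))) {
    lid <- acq$lineage_id[r]
    key <- paste(acq$spacer_seq[r], acq$mge_id[r], acq$lineage_id[r])
    if (key %in% seen) next
    seen <- c(seen, key)
    lin <- truth$lineages[[lid]]
    tps <- seq(lin$first_seen, nT)
    sc <- canonical_seq(acq$spacer_seq[r])
    sp_at <- vapply(tps, function(t) {
      arr <- lin$arrays[[t]]
      !is.null(arr) && sc %in% canonical_seq(arr)
    }, logical(1))
    if (!any(sp_at)) next
    acq_tp <- tps[which(sp_at)[1L]]
    if (acq_tp <= lin$first_seen) next
    if (sum(sp_at) < min_spacer_samples) next
    tid <- acq$mge_id[r]; subj <- lin$subject
    tg_at <- vapply(tps, function(t) {
      any(ab$abundance[ab$target_id == tid & ab$subject == subj &
                         ab$sample == t] > 0)
    }, logical(1))
    all_tps <- seq_len(nT)
    eid <- eid + 1L
    episodes[[eid]] <- data.table::data.table(
      episode_id = sprintf("T%04d", eid),
      spacer_id = acq$spacer_seq[r], lineage_id = lid, target_id = tid,
      subject = subj, acquisition_tp = acq_tp,
      timepoints = list(tps), spacer_at = list(sp_at),
      target_at = list(tg_at),
      phase = list(phase_assignment(tps, sp_at)),
      tl_timepoints = list(all_tps),
      tl_lineage = list(all_tps %in% tps),
      tl_spacer = list(all_tps %in% tps[sp_at]),
      tl_target = list(vapply(all_tps, function(t) {
        any(ab$abundance[ab$target_id == tid & ab$subject == subj &
                           ab$sample == t] > 0)
      }, logical(1)))
    )
  }
  list(episodes = if (length(episodes)) data.table::rbindlist(episodes)
                  else data.table::data.table(),
       abundance = ab)
}

#' Write a dataset to a directory of plain-text files
#'
#' @param ds a `crispr_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_array_table(ds$arrays, file.path(dir, "arrays.tsv"),
                    file.path(dir, "sequences.fasta"))
  write_fasta(stats::setNames(ds$contigs$seq, ds$contigs$contig_id),
              file.path(dir, "contigs.fasta"))
  write_fasta(ds$mge_seqs, file.path(dir, "mge.fasta"))
  write_tsv(ds$contigs[, c("contig_id", "subject", "sample", "target_id")],
            file.path(dir, "contig_provenance.tsv"))
  write_tsv(ds$array_intervals, file.path(dir, "array_intervals.tsv"))
  write_tsv(ds$mge_annotations, file.path(dir, "mge_annotations.tsv"))
  write_tsv(ds$abundance, file.path(dir, "abundance.tsv"))
  write_tsv(ds$samples, file.path(dir, "samples.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_tsv(ds$truth$acquisitions, file.path(tdir, "acquisitions.tsv"))
  write_tsv(ds$truth_membership, file.path(tdir, "membership.tsv"))
  write_tsv(ds$truth$pool$protospacers, file.path(tdir, "protospacers.tsv"))
  invisible(dir)
}
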