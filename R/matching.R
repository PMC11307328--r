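# Protospacer search. Spacers are short (~34 nt) queries matched ungapped
# against MGE references and local contigs on both strands. At a 95%
# identity threshold on queries this short, gapped placements cannot reach
# the coverage threshold, so Hamming matching at every offset reproduces a
# short-query nucleotide search exactly. Interior placements must cover the
# full spacer; partial coverage is allowed only where the spacer overhangs
# a subject end (contig edge).

#' Find protospacer matches of one spacer in one subject sequence
#'
#' Reports every placement on either strand whose identity (matching
#' positions divided by spacer length) and coverage (aligned spacer
#' positions divided by spacer length) meet the thresholds. Interior
#' placements have coverage 1; placements overhanging a subject end are
#' reported when coverage >= `min_coverage`. Ambiguity codes count as
#' mismatches. A hit is `identical` when it has zero mismatches and full
#' coverage, otherwise `highly_similar`.
#'
#' @param spacer spacer sequence (character, >= 8 nt).
#' @param subject subject sequence (character).
#' @param min_identity minimum identity fraction (default 0.95).
#' @param min_coverage minimum coverage fraction (default 0.95).
#' @param spacer_id,subject_id ids recorded in the output.
#' @return `data.table` with columns `spacer_id`, `subject_id`, `start`,
#'   `end` (0-based half-open subject coordinates), `strand`, `mismatches`,
#'   `identity`, `coverage`, `accuracy`, sorted by (start, strand).
#' @export
find_matches <- function(spacer, subject, min_identity = 0.95,
                         min_coverage = 0.95,
                         spacer_id = "spacer", subject_id = "subject") {
  L <- nchar(spacer)
  if (L < 8L) stop("query too short: spacer must be >= 8 nt", call. = FALSE)
  n <- nchar(subject)
  if (n == 0L) stop("subject sequence is empty", call. = FALSE)
  min_olap <- as.integer(ceiling(min_coverage * L))
  tol <- 1e-9
  sv <- utf8ToInt(subject)

  # accumulated in plain vectors; one table is built at the end
  starts <- ends <- mms <- integer(0)
  strands <- character(0)
  covs <- numeric(0)
  add <- function(st, en, strand, mm, cov) {
    starts <<- c(starts, st); ends <<- c(ends, en)
    strands <<- c(strands, rep(strand, length(st)))
    mms <<- c(mms, mm); covs <<- c(covs, cov)
  }
  scan_strand <- function(qv, strand) {
    # interior placements: full coverage, Hamming distance per offset
    if (n >= L) {
      n_off <- n - L + 1L
      mm <- integer(n_off)
      for (i in seq_len(L)) {
        mm <- mm + (sv[i:(i + n_off - 1L)] != qv[i])
      }
      keep <- which((L - mm) / L >= min_identity - tol)
      if (length(keep)) {
        add(keep - 1L, keep - 1L + L, strand, mm[keep],
            rep(1, length(keep)))
      }
    }
    # edge placements: spacer overhangs a subject end
    if (min_olap < L) {
      for (olap in seq(min_olap, min(L - 1L, n))) {
        mm <- sum(qv[(L - olap + 1L):L] != sv[seq_len(olap)])
        if ((olap - mm) / L >= min_identity - tol) {
          add(0L, olap, strand, mm, olap / L)
        }
        mm <- sum(qv[seq_len(olap)] != sv[(n - olap + 1L):n])
        if ((olap - mm) / L >= min_identity - tol) {
          add(n - olap, n, strand, mm, olap / L)
        }
      }
    }
  }
  scan_strand(utf8ToInt(spacer), "+")
  scan_strand(utf8ToInt(revcomp(spacer)), "-")
  if (!length(starts)) return(empty_hit_table())

  # dedupe identical placements, keep lowest mismatch count
  ord <- order(starts, strands, mms)
  dup <- duplicated(paste(starts[ord], strands[ord]))
  ord <- ord[!dup]
  matches <- ifelse(covs[ord] < 1, as.integer(round(covs[ord] * L)),
                    L) - mms[ord]
  data.table::data.table(
    spacer_id = spacer_id, subject_id = subject_id,
    start = starts[ord], end = ends[ord], strand = strands[ord],
    mismatches = mms[ord],
    identity = matches / L,
    coverage = covs[ord],
    accuracy = ifelse(mms[ord] == 0L & covs[ord] == 1, "identical",
                      "highly_similar")
  )
}

empty_hit_table <- function() {
  data.table::data.table(
    spacer_id = character(0), subject_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mismatches = integer(0), identity = numeric(0), coverage = numeric(0),
    accuracy = character(0)
  )
}

#' Match many spacers against many subjects
#'
#' Convenience wrapper over [find_matches()]. Duplicate subject sequences
#' are scanned once and the hits broadcast to every carrier. A k-mer
#' candidate prefilter (k = 10) skips spacer/subject pairs that cannot
#' produce a reportable hit: a hit tolerates at most
#' `floor((1 - min_identity) * L)` mismatches plus
#' `L - ceiling(min_coverage * L)` edge-clipped positions, and whenever
#' `(L - d) / (d + 1) >= 10` for that damage budget d, any hit must
#' contain an exact shared 10-mer (pigeonhole). Spacers too short for the
#' guarantee are scanned against every subject.
#'
#' @param spacers named character vector of spacer sequences.
#' @param subjects named character vector of subject sequences.
#' @param min_identity,min_coverage thresholds passed through.
#' @return combined hit `data.table` (possibly empty).
#' @export
match_spacer_set <- function(spacers, subjects, min_identity = 0.95,
                             min_coverage = 0.95) {
  if (!length(spacers) || !length(subjects)) return(empty_hit_table())
  k <- 10L
  useq <- unique(unname(subjects))
  subj_of_seq <- split(names(subjects), match(unname(subjects), useq))

  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1L), k:n))
  }
  idx <- data.table::rbindlist(lapply(seq_along(useq), function(i) {
    km <- kmers_of(useq[i])
    if (length(km)) data.table::data.table(kmer = km, seq_i = i) else NULL
  }))

  sp_names <- names(spacers)
  probes <- data.table::rbindlist(lapply(seq_along(spacers), function(i) {
    s <- spacers[[i]]
    km <- unique(c(kmers_of(s), kmers_of(revcomp(s))))
    if (length(km)) data.table::data.table(kmer = km, sp_i = i) else NULL
  }))

  # spacers for which the pigeonhole guarantee fails are scanned everywhere
  L <- nchar(spacers)
  d <- floor((1 - min_identity) * L) + (L - ceiling(min_coverage * L))
  guaranteed <- (L - d) / (d + 1) >= k & L >= k
  cand <- if (nrow(idx) && nrow(probes)) {
    m <- merge(probes, idx, by = "kmer", allow.cartesian = TRUE)
    unique(m[, c("sp_i", "seq_i")])
  } else data.table::data.table(sp_i = integer(0), seq_i = integer(0))
  if (any(!guaranteed)) {
    full <- data.table::CJ(sp_i = which(!guaranteed),
                           seq_i = seq_along(useq))
    cand <- unique(data.table::rbindlist(list(cand, full)))
  }
  data.table::setorder(cand, sp_i, seq_i)

  res <- vector("list", 0L)
  for (r in seq_len(nrow(cand))) {
    i <- cand$sp_i[r]; j <- cand$seq_i[r]
    h <- find_matches(spacers[[i]], useq[j], min_identity, min_coverage,
                      spacer_id = sp_names[i], subject_id = "x")
    if (nrow(h)) {
      for (su in subj_of_seq[[as.character(j)]]) {
        hh <- data.table::copy(h)
        hh[, subject_id := su]
        res[[length(res) + 1L]] <- hh
      }
    }
  }
  out <- if (length(res)) data.table::rbindlist(res) else empty_hit_table()
  if (nrow(out)) data.table::setorder(out, spacer_id, subject_id, start,
                                      strand)
  out
}

#' Remove hits that fall in known CRISPR regions
#'
#' Discards hits overlapping a known CRISPR array interval on the same
#' subject, and hits within `margin` nt of a known repeat hit. Intervals
#' use the same 0-based half-open coordinates as the hits.
#'
#' @param hits hit table from [find_matches()].
#' @param array_intervals `data.table`/data.frame with columns
#'   `subject_id`, `start`, `end` for known CRISPR arrays (may be empty or
#'   NULL).
#' @param repeat_hits same schema, for repeat matches (may be empty/NULL).
#' @param margin exclusion margin around repeat hits in nt (default 100).
#' @return list with `kept` (filtered hit table) and `removed` (hit table
#'   with an extra `reason` column).
#' @export
mask_crispr_regions <- function(hits, array_intervals = NULL,
                                repeat_hits = NULL, margin = 100L) {
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  if (nrow(hits) == 0L) {
    return(list(kept = hits, removed = cbind(hits, reason = character(0))))
  }
  overlaps_any <- function(h, iv, pad) {
    if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, nrow(h)))
    vapply(seq_len(nrow(h)), function(i) {
      j <- iv$subject_id == h$subject_id[i]
      any(j & (h$start[i] < iv$end + pad) & (h$end[i] > iv$start - pad))
    }, logical(1))
  }
  in_array <- overlaps_any(hits, array_intervals, 0L)
  near_repeat <- overlaps_any(hits, repeat_hits, as.integer(margin))
  reason <- ifelse(in_array, "known_array",
                   ifelse(near_repeat, "repeat_neighborhood", NA_character_))
  drop <- in_array | near_repeat
  removed <- hits[drop, ]
  if (nrow(removed)) removed[, reason := reason[drop]] else
    removed <- cbind(removed, reason = character(0))
  list(kept = hits[!drop, ], removed = removed)
}

#' Flag promiscuous spacers
#'
#' A spacer with an anomalously high hit count (crossing both an absolute
#' cap and a multiple of the next-highest count) is treated as an artifact
#' and removed from downstream analyses. The default rule flags a spacer
#' whose hit count exceeds `max(absolute_cap, ratio * next-highest)`.
#'
#' @param hits hit table.
#' @param absolute_cap minimum count for flagging (default 1000).
#' @param ratio multiple of the next-highest spacer's count (default 10).
#' @return list with `kept` (hit table without flagged spacers) and
#'   `flagged` (character vector of spacer ids).
#' @export
flag_promiscuous_spacers <- function(hits, absolute_cap = 1000L, ratio = 10) {
  if (nrow(hits) == 0L) return(list(kept = hits, flagged = character(0)))
  cnt <- sort(table(hits$spacer_id), decreasing = TRUE)
  flagged <- character(0)
  for (i in seq_along(cnt)) {
    nxt <- if (length(cnt) >= i + 1L) cnt[[i + 1L]] else NA_integer_
    thr <- if (is.na(nxt)) absolute_cap else max(absolute_cap, ratio * nxt)
    if (cnt[[i]] > thr) flagged <- c(flagged, names(cnt)[i]) else break
  }
  list(kept = hits[!hits$spacer_id %in% flagged, ], flagged = flagged)
}

#' Search spacers against their own subject's contigs
#'
#' The local microbiome of a subject is the union of contigs from all of
#' that subject's samples; a spacer is searched only against contigs with
#' its own subject's provenance. CRISPR-region masking and promiscuity
#' filtering are applied to the pooled result.
#'
#' @param spacers named character vector of spacer sequences.
#' @param spacer_subjects either a named character vector mapping spacer
#'   id -> subject id, or a data.frame of (`spacer_id`, `subject`) pairs
#'   (a spacer carried by several subjects is scanned within each).
#' @param contigs `data.table` with columns `contig_id`, `subject`, `seq`
#'   (and optionally `sample`).
#' @param params a [crispr_params()] object.
#' @param array_intervals,repeat_hits masking inputs (see
#'   [mask_crispr_regions()]).
#' @return filtered local hit table with an extra `subject` column.
#' @export
local_protospacer_scan <- function(spacers, spacer_subjects, contigs,
                                   params = crispr_params(),
                                   array_intervals = NULL,
                                   repeat_hits = NULL) {
  if (nrow(contigs) == 0L || length(spacers) == 0L) {
    out <- empty_hit_table()
    out[, subject := character(0)]
    return(out[])
  }
  if (!all(c("contig_id", "subject", "seq") %in% names(contigs))) {
    stop("contigs must carry columns contig_id, subject, seq", call. = FALSE)
  }
  if (any(is.na(contigs$subject) | !nzchar(contigs$subject))) {
    stop("contig without subject provenance", call. = FALSE)
  }
  pairs <- if (is.data.frame(spacer_subjects)) {
    data.table::as.data.table(spacer_subjects)[, c("spacer_id", "subject")]
  } else {
    data.table::data.table(spacer_id = names(spacer_subjects),
                           subject = unname(spacer_subjects))
  }
  miss <- setdiff(names(spacers), pairs$spacer_id)
  if (length(miss)) stop("spacer(s) without subject annotation: ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  res <- vector("list", 0L)
  for (subj in unique(contigs$subject)) {
    sp_ids <- intersect(names(spacers),
                        pairs$spacer_id[pairs$subject == subj])
    if (!length(sp_ids)) next
    csub <- contigs[contigs$subject == subj, ]
    seqs <- stats::setNames(csub$seq, csub$contig_id)
    h <- match_spacer_set(spacers[sp_ids], seqs,
                          params$protospacer_min_identity,
                          params$protospacer_min_coverage)
    if (nrow(h)) {
      h[, subject := subj]
      res[[length(res) + 1L]] <- h
    }
  }
  hits <- if (length(res)) data.table::rbindlist(res) else {
    out <- empty_hit_table(); out[, subject := character(0)]; out
  }
  masked <- mask_crispr_regions(hits, array_intervals, repeat_hits,
                                params$repeat_mask_margin)
  flag_promiscuous_spacers(masked$kept)$kept
}
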