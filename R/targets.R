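# Spacer target classification. Each spacer gets exactly one target class
# -- lytic/non-lysogenic phage, lysogenic phage, plasmid, other MGE,
# ambiguous, or unknown -- plus an accuracy tier (identical /
# highly_similar / none), taxonomic tags, and a local-adaptation flag.
# Class assignment is a strict consensus over MGE-database hits; spacers
# with no database hit but a local protospacer are rescued by a
# neighborhood homology search against the database.

.target_classes <- c("lytic_or_nonlysogenic_phage", "lysogenic_phage",
                     "plasmid", "other_mge", "ambiguous", "unknown")

#' Annotate an MGE table with lifestyle and tags
#'
#' Viral records are labeled lysogenic when they carry an integrase flag,
#' and lytic_or_nonlysogenic otherwise (records absent from the lifestyle
#' table default to lytic_or_nonlysogenic with a warning). Plasmid and
#' other records keep their class regardless of integrase flags.
#' crAss-like and infant-gut tags are attached from the tag tables.
#'
#' @param mge `data.table` with columns `mge_id`, `class` in
#'   {virus, plasmid, other_mge}.
#' @param lifestyle `data.table` with `mge_id`, `integrase` (logical); may
#'   be empty.
#' @param tags optional `data.table` with `mge_id`, `crass_like`,
#'   `infant_gut`.
#' @return annotated `data.table` with a `final_class` column over
#'   {lytic_or_nonlysogenic_phage, lysogenic_phage, plasmid, other_mge}.
#' @export
annotate_lifestyle_and_tags <- function(mge, lifestyle = NULL, tags = NULL) {
  out <- data.table::copy(data.table::as.data.table(mge))
  if (!all(c("mge_id", "class") %in% names(out))) {
    stop("mge table needs columns mge_id, class", call. = FALSE)
  }
  if (!is.null(lifestyle) && nrow(lifestyle)) {
    bad <- setdiff(lifestyle$mge_id, out$mge_id)
    if (length(bad)) stop("lifestyle entry for unknown MGE id: ",
                          paste(utils::head(bad, 5), collapse = ", "),
                          call. = FALSE)
  }
  if (!is.null(tags) && nrow(tags)) {
    bad <- setdiff(tags$mge_id, out$mge_id)
    if (length(bad)) stop("tag entry for unknown MGE id: ",
                          paste(utils::head(bad, 5), collapse = ", "),
                          call. = FALSE)
  }
  integ <- rep(NA, nrow(out))
  if (!is.null(lifestyle) && nrow(lifestyle)) {
    m <- match(out$mge_id, lifestyle$mge_id)
    integ <- lifestyle$integrase[m]
  }
  viral <- out$class == "virus"
  unlabeled <- viral & is.na(integ)
  if (any(unlabeled)) {
    warning(sum(unlabeled),
            " viral record(s) without lifestyle annotation; defaulting to",
            " lytic_or_nonlysogenic")
  }
  out$final_class <- out$class
  out$final_class[viral] <- ifelse(!is.na(integ[viral]) & integ[viral],
                                   "lysogenic_phage",
                                   "lytic_or_nonlysogenic_phage")
  out$crass_like <- FALSE
  out$infant_gut <- FALSE
  if (!is.null(tags) && nrow(tags)) {
    m <- match(out$mge_id, tags$mge_id)
    hit <- !is.na(m)
    if ("crass_like" %in% names(tags)) {
      out$crass_like[hit] <- as.logical(tags$crass_like[m[hit]])
    }
    if ("infant_gut" %in% names(tags)) {
      out$infant_gut[hit] <- as.logical(tags$infant_gut[m[hit]])
    }
  }
  out
}

#' Classify spacers from MGE-database hits
#'
#' Class is the strict consensus of the annotated classes of all hit MGEs
#' (any conflict yields `ambiguous`); accuracy is `identical` when any hit
#' has zero mismatches and full coverage, else `highly_similar`; spacers
#' with no hits are `unknown`/`none` pending neighborhood rescue. Tags are
#' the union over hit MGEs.
#'
#' @param hits hit table from [find_matches()] against the MGE db
#'   (`subject_id` = mge_id), already thresholded.
#' @param mge_annotated annotated MGE table from
#'   [annotate_lifestyle_and_tags()] (needs `mge_id`, `final_class`,
#'   `crass_like`, `infant_gut`).
#' @param all_spacer_ids spacer ids to report (spacers without hits
#'   included as unknown).
#' @return `data.table`: `spacer_id`, `target_class`, `accuracy`,
#'   `crass_like`, `infant_gut`, `n_hits`.
#' @export
assign_from_mgedb <- function(hits, mge_annotated, all_spacer_ids) {
  ann <- data.table::as.data.table(mge_annotated)
  out <- data.table::data.table(
    spacer_id = all_spacer_ids,
    target_class = "unknown", accuracy = "none",
    crass_like = FALSE, infant_gut = FALSE, n_hits = 0L
  )
  if (nrow(hits)) {
    bad <- setdiff(unique(hits$subject_id), ann$mge_id)
    if (length(bad)) stop("hit references unannotated MGE: ",
                          paste(utils::head(bad, 5), collapse = ", "),
                          call. = FALSE)
    h <- merge(data.table::as.data.table(hits), ann,
               by.x = "subject_id", by.y = "mge_id")
    agg <- h[, list(
      target_class = if (length(unique(final_class)) == 1L)
        unique(final_class) else "ambiguous",
      accuracy = if (any(accuracy == "identical")) "identical"
                 else "highly_similar",
      crass_like = any(crass_like),
      infant_gut = any(infant_gut),
      n_hits = .N
    ), by = "spacer_id"]
    m <- match(agg$spacer_id, out$spacer_id)
    ok <- !is.na(m)
    for (col in c("target_class", "accuracy", "crass_like", "infant_gut",
                  "n_hits")) {
      data.table::set(out, i = m[ok], j = col, value = agg[[col]][ok])
    }
  }
  out
}

# longest shared exact block between two sequences, either strand,
# found by k-mer anchoring plus exact extension
.longest_shared_block <- function(query, subject, k = 12L) {
  best <- 0L
  qv <- query
  nq <- nchar(qv)
  if (nq < k || nchar(subject) < k) return(0L)
  sub_kmers <- new.env(hash = TRUE, parent = emptyenv())
  ns <- nchar(subject)
  starts <- seq(1L, ns - k + 1L)
  kms <- substring(subject, starts, starts + k - 1L)
  for (i in seq_along(kms)) {
    key <- kms[i]
    assign(key, c(get0(key, envir = sub_kmers, ifnotfound = integer(0)),
                  starts[i]), envir = sub_kmers)
  }
  for (q in c(qv, revcomp(qv))) {
    nqq <- nchar(q)
    qstarts <- seq(1L, nqq - k + 1L)
    qk <- substring(q, qstarts, qstarts + k - 1L)
    qchr <- strsplit(q, "")[[1]]
    schr <- strsplit(subject, "")[[1]]
    seen <- character(0)
    for (i in seq_along(qk)) {
      if (qk[i] %in% seen) next
      seen <- c(seen, qk[i])
      for (s0 in get0(qk[i], envir = sub_kmers, ifnotfound = integer(0))) {
        # extend left
        lq <- qstarts[i]; ls <- s0
        while (lq > 1L && ls > 1L && qchr[lq - 1L] == schr[ls - 1L]) {
          lq <- lq - 1L; ls <- ls - 1L
        }
        rq <- qstarts[i] + k - 1L; rs <- s0 + k - 1L
        while (rq < nqq && rs < ns && qchr[rq + 1L] == schr[rs + 1L]) {
          rq <- rq + 1L; rs <- rs + 1L
        }
        best <- max(best, rq - lq + 1L)
      }
    }
  }
  best
}

#' Rescue unclassified spacers via protospacer neighborhoods
#'
#' For a spacer with a local protospacer but no MGE-database class, the
#' contig window spanning `flank` nt on each side of the protospacer
#' (clipped at contig ends) is compared against every database record by
#' a k-mer-anchored exact-extension search. The score of a record is twice
#' the longest shared exact block (a bitscore-like additive score); a
#' record is significant when the expected number of random blocks that
#' long, `neighborhood_len * db_len * 4^-block_len`, is below
#' `evalue_analog`. Among significant records, those scoring below
#' `score_ratio` times the best are discarded; a unique class among the
#' kept records is returned, a conflict yields `ambiguous`, and no
#' significant record yields `unknown`.
#'
#' @param contig_seq contig sequence containing the protospacer.
#' @param proto_start,proto_end protospacer coordinates (0-based
#'   half-open) on the contig.
#' @param mge_annotated annotated MGE table with a `seq` column.
#' @param flank neighborhood flank in nt (default 7500).
#' @param score_ratio bitscore ratio threshold (default 0.9).
#' @param evalue_analog significance threshold (default 1e-8).
#' @return character scalar: a class, "ambiguous", or "unknown".
#' @export
assign_from_neighborhood <- function(contig_seq, proto_start, proto_end,
                                     mge_annotated, flank = 7500L,
                                     score_ratio = 0.9,
                                     evalue_analog = 1e-8) {
  n <- nchar(contig_seq)
  if (proto_start < 0L || proto_end > n || proto_start >= proto_end) {
    stop("protospacer coordinates outside contig", call. = FALSE)
  }
  lo <- max(0L, proto_start - flank)
  hi <- min(n, proto_end + flank)
  neigh <- substr(contig_seq, lo + 1L, hi)
  ann <- data.table::as.data.table(mge_annotated)
  db_len <- sum(nchar(ann$seq))
  scores <- vapply(seq_len(nrow(ann)), function(i) {
    2L * .longest_shared_block(neigh, ann$seq[i])
  }, integer(1))
  block_len <- scores / 2
  evalue <- nchar(neigh) * db_len * 4^(-block_len)
  sig <- evalue < evalue_analog & block_len > 0
  if (!any(sig)) return("unknown")
  best <- max(scores[sig])
  keep <- sig & scores >= score_ratio * best
  cls <- unique(ann$final_class[keep])
  if (length(cls) == 1L) cls else "ambiguous"
}

#' Flag locally adapted spacers
#'
#' A spacer is locally adapted when it has at least one surviving hit
#' (masked and promiscuity-filtered) in a contig from its own subject,
#' pooled over all of that subject's samples.
#'
#' @param assignments assignment table from [assign_from_mgedb()].
#' @param local_hits filtered local hit table from
#'   [local_protospacer_scan()].
#' @return the assignment table with a logical `locally_adapted` column.
#' @export
flag_local_adaptation <- function(assignments, local_hits) {
  out <- data.table::copy(data.table::as.data.table(assignments))
  out$locally_adapted <- out$spacer_id %in% unique(local_hits$spacer_id)
  out
}

#' Full target classification for a dataset
#'
#' Runs the two-step flow: MGE-database consensus first, then neighborhood
#' rescue for spacers that are unknown but locally adapted. Neighborhood
#' evidence never overrides a database-derived class.
#'
#' @param ds a `crispr_dataset`.
#' @param params a [crispr_params()] object.
#' @return list with `assignments` (one row per spacer), `db_hits`,
#'   `local_hits`.
#' @export
classify_targets <- function(ds, params = crispr_params()) {
  spacer_seqs <- ds$arrays$spacer_seqs
  ann <- annotate_lifestyle_and_tags(
    ds$mge_annotations[, list(mge_id, class)],
    lifestyle = ds$mge_annotations[, list(mge_id, integrase)],
    tags = ds$mge_annotations[, list(mge_id, crass_like, infant_gut)]
  )
  ann$seq <- unname(ds$mge_seqs[ann$mge_id])

  db_hits <- match_spacer_set(spacer_seqs, ds$mge_seqs,
                              params$protospacer_min_identity,
                              params$protospacer_min_coverage)
  db_hits <- flag_promiscuous_spacers(db_hits)$kept
  assignments <- assign_from_mgedb(db_hits, ann, names(spacer_seqs))

  sp_subject <- spacer_subject_map(ds$arrays)
  local_hits <- local_protospacer_scan(
    spacer_seqs, sp_subject,
    ds$contigs, params,
    array_intervals = ds$array_intervals,
    repeat_hits = NULL
  )
  assignments <- flag_local_adaptation(assignments, local_hits)

  # neighborhood rescue for locally adapted unknowns
  rescue <- which(assignments$target_class == "unknown" &
                    assignments$locally_adapted)
  if (length(rescue)) {
    cseq <- stats::setNames(ds$contigs$seq, ds$contigs$contig_id)
    for (i in rescue) {
      sid <- assignments$spacer_id[i]
      h <- local_hits[local_hits$spacer_id == sid, ][1L, ]
      cls <- assign_from_neighborhood(
        cseq[[h$subject_id]], h$start, h$end, ann,
        flank = params$neighborhood_flank_target,
        score_ratio = params$neighborhood_score_ratio,
        evalue_analog = params$neighborhood_evalue_analog
      )
      data.table::set(assignments, i, "target_class", cls)
    }
  }
  list(assignments = assignments, db_hits = db_hits,
       local_hits = local_hits, mge_annotated = ann)
}

# (spacer_id, subject) occurrence pairs; a spacer carried by several
# subjects is scanned within each of them
spacer_subject_map <- function(aset) {
  a <- aset$arrays
  pairs <- unique(data.table::data.table(
    spacer_id = unlist(a$spacers),
    subject = rep(a$subject, lengths(a$spacers))
  ))
  data.table::setorder(pairs, spacer_id, subject)
  pairs
}
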