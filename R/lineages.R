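# CRISPR array lineages. Arrays from one subject are grouped by a strict
# nesting criterion: an array is nested within another when both share the
# same (or highly similar, >90% identity/coverage) repeat and every spacer
# of the former is carried by the latter, treating a spacer and its
# reverse complement as the same spacer. Representatives are arrays not
# nested within any other; each lineage is a representative plus all
# arrays nested within it. Strict nesting leaves partially overlapping
# arrays unmerged, which avoids heterogeneous clusters at the cost of
# occasionally splitting a true lineage.

#' Dereplicate sequences at 100% identity
#'
#' Exact duplicates map to one canonical id (the lexicographically
#' smallest member id, so the choice is deterministic). Exact reverse
#' complements are kept distinct but cross-referenced as a strand pair.
#'
#' @param seqs named character vector of sequences.
#' @return list with `map` (named character: input id -> canonical id),
#'   `canonical` (named character: canonical id -> sequence) and
#'   `strand_pairs` (data.table of canonical id pairs that are reverse
#'   complements of each other).
#' @export
dereplicate_sequences <- function(seqs) {
  if (length(seqs) == 0L) {
    return(list(map = character(0), canonical = character(0),
                strand_pairs = data.table::data.table(id1 = character(0),
                                                      id2 = character(0))))
  }
  ids <- names(seqs)
  # canonical id per distinct sequence = lexicographically smallest member id
  by_seq <- split(ids, unname(seqs))
  canon_of_seq <- vapply(by_seq, function(v) sort(v)[1L], character(1))
  map <- stats::setNames(canon_of_seq[unname(seqs)], ids)
  canonical <- stats::setNames(as.character(names(by_seq)), canon_of_seq)
  # strand pairs among canonical sequences
  cs <- stats::setNames(unname(canonical), names(canonical))
  rc <- revcomp(unname(cs))
  idx <- match(rc, unname(cs))
  pair <- which(!is.na(idx) & idx > seq_along(cs))
  strand_pairs <- data.table::data.table(
    id1 = names(cs)[pair], id2 = names(cs)[idx[pair]]
  )
  list(map = map, canonical = cs, strand_pairs = strand_pairs)
}

# best ungapped sliding-overlap comparison of two sequences, both strands;
# returns max over offsets of (matches, overlap) meeting no threshold yet
.best_overlap <- function(a, b) {
  av <- utf8ToInt(a); na <- length(av)
  best <- list(matches = 0L, overlap = 0L)
  for (bseq in c(b, revcomp(b))) {
    bv <- utf8ToInt(bseq); nb <- length(bv)
    for (off in (-(nb - 1L)):(na - 1L)) {
      ia <- max(1L, off + 1L); ib <- max(1L, 1L - off)
      len <- min(na - ia, nb - ib) + 1L
      if (len <= 0L) next
      m <- sum(av[ia:(ia + len - 1L)] == bv[ib:(ib + len - 1L)])
      if (m > best$matches) best <- list(matches = m, overlap = len)
    }
  }
  best
}

#' Greedy clustering of CRISPR repeats
#'
#' Seeds are processed longest-first (ties broken lexicographically by
#' sequence); a repeat joins the first seed for which identity and
#' coverage exceed the thresholds on either strand. Identity is computed
#' over the best ungapped sliding overlap (matches / overlap length);
#' coverage is overlap length / member length.
#'
#' @param repeats named character vector of dereplicated repeat sequences.
#' @param min_identity,min_coverage clustering thresholds (default 0.90,
#'   exceeded strictly).
#' @return named character vector: repeat id -> cluster id (the seed's id).
#' @export
cluster_repeats <- function(repeats, min_identity = 0.90,
                            min_coverage = 0.90) {
  if (length(repeats) == 0L) return(character(0))
  ord <- order(-nchar(repeats), unname(repeats), names(repeats))
  ids <- names(repeats)[ord]
  seqs <- unname(repeats)[ord]
  cluster <- stats::setNames(rep(NA_character_, length(ids)), ids)
  seeds <- character(0)
  for (i in seq_along(ids)) {
    assigned <- FALSE
    for (s in seeds) {
      bo <- .best_overlap(repeats[[s]], seqs[i])
      ident <- if (bo$overlap > 0L) bo$matches / bo$overlap else 0
      cov <- bo$overlap / nchar(seqs[i])
      if (ident > min_identity && cov > min_coverage) {
        cluster[ids[i]] <- s
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      seeds <- c(seeds, ids[i])
      cluster[ids[i]] <- ids[i]
    }
  }
  cluster
}

# strand-insensitive canonical spacer-id set of one array
.canon_set <- function(spacer_ids, canon_map) {
  unique(unname(canon_map[spacer_ids]))
}

#' Strict nesting test for two arrays
#'
#' `a` is nested within `b` when both belong to the same repeat cluster
#' and every spacer of `a` (strand-insensitive) is also carried by `b`.
#' Spacer order is not consulted.
#'
#' @param spacers_a,spacers_b canonical spacer-id sets of the two arrays.
#' @param cluster_a,cluster_b repeat-cluster ids of the two arrays.
#' @return logical.
#' @export
is_nested <- function(spacers_a, spacers_b, cluster_a, cluster_b) {
  identical(cluster_a, cluster_b) && all(spacers_a %in% spacers_b)
}

#' Build CRISPR lineages for one subject by strict nesting
#'
#' Representatives are arrays not strictly nested within any other array
#' (arrays with identical spacer sets form a tie resolved by earliest
#' timepoint, then most spacers, then lexicographic array id). Every other
#' array joins the representative it is nested within; when several
#' representatives qualify, the one sharing most spacers wins (ties: the
#' larger representative, then the lexicographically smaller id). The
#' output partitions the arrays.
#'
#' @param arrays `data.table` of arrays from a single subject (columns
#'   `array_id`, `subject`, `sample`, `timepoint`, list-column `spacers`).
#' @param spacer_seqs named character vector resolving spacer ids, used
#'   for strand-insensitive spacer identity.
#' @param repeat_clusters named character: array repeat id -> cluster id.
#'   Arrays carry `repeat_id`.
#' @return `data.table` with columns `lineage_id`, `representative`,
#'   `array_id`, `subject`.
#' @export
build_lineages <- function(arrays, spacer_seqs, repeat_clusters) {
  stopifnot(length(unique(arrays$subject)) <= 1L)
  n <- nrow(arrays)
  if (n == 0L) {
    return(data.table::data.table(lineage_id = character(0),
                                  representative = character(0),
                                  array_id = character(0),
                                  subject = character(0)))
  }
  canon_map <- stats::setNames(canonical_seq(unname(spacer_seqs)),
                               names(spacer_seqs))
  sets <- lapply(arrays$spacers, .canon_set, canon_map = canon_map)
  rcl <- unname(repeat_clusters[arrays$repeat_id])
  sizes <- lengths(sets)
  ids <- arrays$array_id
  tp <- arrays$timepoint

  # tie rule among arrays with identical spacer sets: representative is
  # earliest timepoint, then most spacers, then lexicographic id
  wins_tie <- function(i, j) {
    if (tp[i] != tp[j]) return(tp[i] < tp[j])
    if (sizes[i] != sizes[j]) return(sizes[i] > sizes[j])
    ids[i] < ids[j]
  }
  strictly_nested_in <- function(i, j) {
    if (i == j) return(FALSE)
    if (!is_nested(sets[[i]], sets[[j]], rcl[i], rcl[j])) return(FALSE)
    if (sizes[i] < sizes[j]) return(TRUE)
    # equal sets: the tie loser is "nested in" the winner
    !wins_tie(i, j)
  }

  nested_mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) nested_mat[i, j] <- strictly_nested_in(i, j)
  }
  is_rep <- !apply(nested_mat, 1L, any)
  reps <- which(is_rep)

  assign_to <- integer(n)
  assign_to[reps] <- reps
  for (i in setdiff(seq_len(n), reps)) {
    cand <- reps[nested_mat[i, reps]]
    if (length(cand) == 0L) {
      # can only happen via a nesting chain; follow to a representative
      chain <- which(nested_mat[i, ])
      cand <- reps[vapply(reps, function(r) {
        any(chain == r) || any(nested_mat[chain, r])
      }, logical(1))]
    }
    shared <- vapply(cand, function(r) length(intersect(sets[[i]], sets[[r]])),
                     integer(1))
    ord <- order(-shared, -sizes[cand], ids[cand])
    assign_to[i] <- cand[ord[1L]]
  }
  data.table::data.table(
    lineage_id = paste0("L_", ids[assign_to]),
    representative = ids[assign_to],
    array_id = ids,
    subject = if (n > 0L) arrays$subject else character(0)
  )
}

#' Build lineages across all subjects
#'
#' Applies [build_lineages()] independently per subject (lineages never
#' cross subjects) after clustering repeats dataset-wide.
#'
#' @param aset an `array_set`.
#' @param params a [crispr_params()] object.
#' @return list with `membership` (the combined lineage table),
#'   `repeat_clusters`, and `presence` (lineage x sample presence table).
#' @export
build_all_lineages <- function(aset, params = crispr_params()) {
  rc <- cluster_repeats(aset$repeat_seqs,
                        params$repeat_cluster_identity,
                        params$repeat_cluster_coverage)
  parts <- lapply(split(seq_len(nrow(aset$arrays)), aset$arrays$subject),
                  function(idx) {
                    build_lineages(aset$arrays[idx, ], aset$spacer_seqs, rc)
                  })
  membership <- data.table::rbindlist(parts)
  arr <- aset$arrays[, c("array_id", "sample", "timepoint")]
  presence <- merge(membership, arr, by = "array_id")
  presence <- unique(presence[, c("lineage_id", "subject", "sample",
                                  "timepoint")])
  data.table::setorder(presence, lineage_id, timepoint)
  list(membership = membership, repeat_clusters = rc, presence = presence)
}

# shared-spacer order comparison for one member pair; returns flags
.pair_consistency <- function(sp_a, sp_b, seq_a, seq_b, orient_a, orient_b) {
  canon_a <- canonical_seq(seq_a)
  canon_b <- canonical_seq(seq_b)
  shared <- intersect(canon_a, canon_b)
  out <- list(comparable = FALSE, order_inconsistent = FALSE,
              inversion = FALSE, orientation_inconsistent = FALSE)
  if (length(shared) < 2L) return(out)
  out$comparable <- TRUE
  pos_a <- match(shared, canon_a)
  pos_b <- match(shared, canon_b)
  ord <- order(pos_a)
  seq_in_b <- pos_b[ord]
  forward_ok <- !is.unsorted(seq_in_b, strictly = TRUE)
  reverse_ok <- !is.unsorted(rev(seq_in_b), strictly = TRUE)
  out$order_inconsistent <- !(forward_ok || reverse_ok)
  # strand relation per shared spacer: TRUE when stored on the same strand
  same_strand <- (seq_a[pos_a] == seq_b[pos_b])[ord]
  if (forward_ok) {
    out$inversion <- any(!same_strand)
  } else if (reverse_ok) {
    out$inversion <- any(same_strand)
  } else {
    # no consistent alignment; count a strand conflict against the majority
    out$inversion <- length(unique(same_strand)) > 1L
  }
  if (!out$order_inconsistent && orient_a != "unknown" &&
      orient_b != "unknown") {
    aligned_reversed <- !forward_ok && reverse_ok
    same_orient <- orient_a == orient_b
    out$orientation_inconsistent <-
      (aligned_reversed && same_orient) || (!aligned_reversed && !same_orient)
  }
  out
}

#' Within-lineage consistency metrics
#'
#' For every pair of member arrays sharing at least two spacers, checks
#' whether the shared spacers appear in the same relative order (allowing
#' whole-array reversal, since assembly strand is arbitrary), whether any
#' shared spacer is stored as the reverse complement in one member
#' (spacer inversion), and whether predicted array orientations conflict
#' with the order-consistent alignment of the pair.
#'
#' @param members `data.table` of a lineage's member arrays (list-column
#'   `spacers`, columns `orientation`).
#' @param spacer_seqs named character vector resolving spacer ids.
#' @return one-row `data.table` with counts `order_inconsistent_pairs`,
#'   `inversion_pairs`, `orientation_inconsistent_pairs`, `total_pairs`
#'   (pairs with >= 2 shared spacers).
#' @export
lineage_consistency_metrics <- function(members, spacer_seqs) {
  n <- nrow(members)
  zero <- data.table::data.table(order_inconsistent_pairs = 0L,
                                 inversion_pairs = 0L,
                                 orientation_inconsistent_pairs = 0L,
                                 total_pairs = 0L)
  if (n < 2L) return(zero)
  seqs <- lapply(members$spacers, function(v) unname(spacer_seqs[v]))
  counts <- zero
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pc <- .pair_consistency(members$spacers[[i]], members$spacers[[j]],
                            seqs[[i]], seqs[[j]],
                            members$orientation[i], members$orientation[j])
    if (!pc$comparable) next
    counts$total_pairs <- counts$total_pairs + 1L
    counts$order_inconsistent_pairs <-
      counts$order_inconsistent_pairs + pc$order_inconsistent
    counts$inversion_pairs <- counts$inversion_pairs + pc$inversion
    counts$orientation_inconsistent_pairs <-
      counts$orientation_inconsistent_pairs + pc$orientation_inconsistent
  }
  counts
}
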