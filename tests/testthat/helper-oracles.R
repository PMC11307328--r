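# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops and closed forms only.

# exhaustive character-wise scan for spacer placements on both strands,
# including edge overhangs; identity denominator is the spacer length
oracle_scan_matches <- function(spacer, subject, min_identity = 0.95,
                                min_coverage = 0.95) {
  L <- nchar(spacer)
  n <- nchar(subject)
  rc <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else rc(spacer)
    qc <- strsplit(q, "")[[1]]
    sc <- strsplit(subject, "")[[1]]
    # every placement of the full spacer, allowing overhang at both ends
    for (off in (-(L - 1L)):(n - 1L)) {
      qi <- max(1L, 1L - off)
      si <- max(1L, off + 1L)
      olap <- min(L - qi, n - si) + 1L
      if (olap < 1L) next
      cov <- olap / L
      if (cov < min_coverage) next
      if (cov < 1 && off >= 0L && off + L <= n) next  # interior must be full
      mm <- sum(qc[qi:(qi + olap - 1L)] != sc[si:(si + olap - 1L)])
      ident <- (olap - mm) / L
      if (ident < min_identity - 1e-9) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = si - 1L, end = si - 1L + olap, strand = strand,
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  # dedupe same placement keeping fewest mismatches
  out <- out[order(out$start, out$strand, out$mismatches), ]
  out <- out[!duplicated(out[, c("start", "strand")]), ]
  out[order(out$start, out$strand), ]
}

# brute-force lineage construction with the package's documented tie
# rules, written as a direct transcription of the definition
oracle_lineages <- function(ids, sets, tps, clusters) {
  n <- length(ids)
  sizes <- vapply(sets, length, integer(1))
  nested <- function(i, j) {
    identical(clusters[i], clusters[j]) && all(sets[[i]] %in% sets[[j]])
  }
  wins <- function(i, j) {
    if (tps[i] != tps[j]) return(tps[i] < tps[j])
    if (sizes[i] != sizes[j]) return(sizes[i] > sizes[j])
    ids[i] < ids[j]
  }
  strict <- function(i, j) {
    if (i == j || !nested(i, j)) return(FALSE)
    if (sizes[i] < sizes[j]) return(TRUE)
    !wins(i, j)
  }
  is_rep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) strict(i, j), logical(1)))
  }, logical(1))
  reps <- which(is_rep)
  assign <- integer(n)
  for (i in seq_len(n)) {
    if (is_rep[i]) { assign[i] <- i; next }
    cand <- reps[vapply(reps, function(r) nested(i, r), logical(1))]
    shared <- vapply(cand, function(r) length(intersect(sets[[i]],
                                                        sets[[r]])),
                     integer(1))
    ord <- order(-shared, -sizes[cand], ids[cand])
    assign[i] <- cand[ord[1L]]
  }
  ids[assign]
}

# exhaustive enumeration of all global alignments under affine gap costs
# (gap of length g costs open + (g - 1) * extend); no memoization
oracle_align <- function(s1, s2, match = 1, mismatch = -2, open = -2,
                         extend = -1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(a)) {
      g <- if (last == "A") extend else open
      best <- max(best, g + rec(i + 1L, j, "A"))
    }
    if (j <= length(b)) {
      g <- if (last == "B") extend else open
      best <- max(best, g + rec(i, j + 1L, "B"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Clopper-Pearson by numeric inversion of the binomial CDF
oracle_cp <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (k == 0L) 0 else {
    stats::uniroot(function(p) (1 - stats::pbinom(k - 1L, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  e <- si * sj / n2
  (sij - e) / ((si + sj) / 2 - e)
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
}

# build an array_set from a list of spacer-id vectors
make_array_set <- function(spacer_lists, spacer_seqs,
                           repeat_seqs = NULL,
                           subject = "S01",
                           timepoints = seq_along(spacer_lists),
                           orientation = "forward",
                           subtype = "I-E") {
  n <- length(spacer_lists)
  if (is.null(repeat_seqs)) {
    repeat_seqs <- stats::setNames(paste(rep("ACGTACGTACGTACGTACGTACGTACGTACG",
                                             1), collapse = ""), "rep001")
  }
  arrays <- data.table::data.table(
    array_id = sprintf("A%03d", seq_len(n)),
    subject = rep(subject, n),
    sample = sprintf("%s_t%02d", subject, timepoints),
    timepoint = as.integer(timepoints),
    repeat_id = rep(names(repeat_seqs)[1L], n),
    orientation = rep(orientation, length.out = n),
    subtype = rep(subtype, length.out = n),
    spacers = spacer_lists
  )
  crisprmemory:::new_array_set(arrays, spacer_seqs, repeat_seqs)
}
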