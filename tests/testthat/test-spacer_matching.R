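test_that("planted exact and near matches are found at the 95% threshold", {
  set.seed(101)
  sp <- paste(rep(c("A", "C", "G", "T"), length.out = 34), collapse = "")
  flank <- rand_dna(2, 200)
  subj <- paste0(flank[1], sp, flank[2])
  h <- find_matches(sp, subj, spacer_id = "s1", subject_id = "c1")
  planted <- h[h$start == 200L & h$strand == "+", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$mismatches, 0L)
  expect_equal(planted$accuracy, "identical")
  expect_equal(planted$end, 234L)

  # one mismatch is reported as highly similar; two mismatches are not
  # reported (floor(0.05 * 34) = 1)
  mut1 <- sp; substr(mut1, 10, 10) <- "N"
  h1 <- find_matches(sp, paste0(flank[1], mut1, flank[2]))
  expect_true(any(h1$mismatches == 1L & h1$accuracy == "highly_similar"))
  mut2 <- mut1; substr(mut2, 20, 20) <- "N"
  h2 <- find_matches(sp, paste0(flank[1], mut2, flank[2]))
  expect_false(any(h2$start == 200L))

  expect_error(find_matches("ACGTACG", subj), "too short")
})

test_that("find_matches equals the exhaustive offset-scan oracle", {
  set.seed(102)
  for (rep in 1:40) {
    sp <- rand_dna(1, 34)
    subj <- rand_dna(1, sample(300:1500, 1))
    # plant 0-, 1-, 2-mismatch copies on both strands
    pos <- sort(sample(seq(1, nchar(subj) - 40, by = 40),
                       min(6, nchar(subj) %/% 80)))
    for (k in seq_along(pos)) {
      copy <- sp
      nmm <- (k - 1L) %% 3L
      if (nmm > 0) {
        at <- sample(34, nmm)
        old <- strsplit(copy, "")[[1]]
        for (a in at) old[a] <- setdiff(c("A", "C", "G", "T"), old[a])[1]
        copy <- paste(old, collapse = "")
      }
      if (k %% 2 == 0) copy <- revcomp(copy)
      substr(subj, pos[k], pos[k] + 33L) <- copy
    }
    got <- find_matches(sp, subj)
    want <- oracle_scan_matches(sp, subj)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("matching is strand-symmetric and monotone in identity", {
  set.seed(103)
  sp <- rand_dna(1, 34)
  subj <- rand_dna(1, 800)
  substr(subj, 100, 133) <- sp
  substr(subj, 300, 333) <- revcomp(sp)
  h_fwd <- find_matches(sp, subj)
  h_rc <- find_matches(revcomp(sp), subj)
  expect_equal(nrow(h_fwd), nrow(h_rc))
  expect_setequal(paste(h_fwd$start, chartr("+-", "-+", h_fwd$strand)),
                  paste(h_rc$start, h_rc$strand))

  # lowering min_identity never removes hits
  strict <- find_matches(sp, subj, min_identity = 0.99)
  loose <- find_matches(sp, subj, min_identity = 0.90)
  expect_true(all(paste(strict$start, strict$strand) %in%
                    paste(loose$start, loose$strand)))
})

test_that("edge overhangs are reported only at sufficient coverage", {
  set.seed(105)
  sp <- rand_dna(1, 34)
  # subject starts with the last 33 nt of the spacer: left-edge overhang
  subj <- paste0(substr(sp, 2, 34), rand_dna(1, 200))
  h <- find_matches(sp, subj)
  edge <- h[h$coverage < 1, ]
  expect_true(any(edge$start == 0L & abs(edge$coverage - 33 / 34) < 1e-9))
  # an overhang below 95% coverage is never reported
  subj2 <- paste0(substr(sp, 10, 34), rand_dna(1, 200))
  h2 <- find_matches(sp, subj2)
  expect_false(any(h2$coverage < 0.95 - 1e-9))
})

test_that("CRISPR-region masking removes array and repeat-margin hits", {
  hits <- data.table::data.table(
    spacer_id = paste0("s", 1:4), subject_id = "c1",
    start = c(150L, 300L, 651L, 900L), end = c(184L, 334L, 685L, 934L),
    strand = "+", mismatches = 0L, identity = 1, coverage = 1,
    accuracy = "identical")
  arrays <- data.table::data.table(subject_id = "c1", start = 100L,
                                   end = 200L)
  repeats <- data.table::data.table(subject_id = "c1", start = 550L,
                                    end = 581L)
  res <- mask_crispr_regions(hits, arrays, repeats, margin = 100L)
  # s1 is inside the array; s2 ends before the repeat margin zone
  # [450, 681); s3 starts at 651 inside it; s4 is far away
  expect_setequal(res$removed$spacer_id, c("s1", "s3"))
  expect_setequal(res$kept$spacer_id, c("s2", "s4"))
  expect_equal(res$removed$reason[res$removed$spacer_id == "s1"],
               "known_array")
  expect_equal(res$removed$reason[res$removed$spacer_id == "s3"],
               "repeat_neighborhood")

  # boundary: a hit exactly margin nt away is kept
  h99 <- data.table::data.table(
    spacer_id = c("near", "far"), subject_id = "c1",
    start = c(482L, 682L), end = c(516L, 716L), strand = "+",
    mismatches = 0L, identity = 1, coverage = 1, accuracy = "identical")
  res2 <- mask_crispr_regions(h99, NULL, repeats, margin = 100L)
  expect_equal(res2$removed$spacer_id, "near")
  expect_equal(res2$kept$spacer_id, "far")

  expect_error(mask_crispr_regions(hits, arrays, repeats, margin = -1),
               "non-negative")
  # no intervals: identity
  res3 <- mask_crispr_regions(hits, NULL, NULL)
  expect_equal(nrow(res3$kept), nrow(hits))
})

test_that("promiscuous spacers are flagged by the cap-and-ratio rule", {
  mk <- function(counts) {
    data.table::rbindlist(lapply(names(counts), function(s) {
      data.table::data.table(spacer_id = rep(s, counts[[s]]),
                             subject_id = "x", start = 0L, end = 34L,
                             strand = "+", mismatches = 0L, identity = 1,
                             coverage = 1, accuracy = "identical")
    }))
  }
  res <- flag_promiscuous_spacers(mk(c(s1 = 16327, s2 = 121, s3 = 50)))
  expect_equal(res$flagged, "s1")
  expect_false("s1" %in% res$kept$spacer_id)
  expect_true(all(c("s2", "s3") %in% res$kept$spacer_id))

  res_eq <- flag_promiscuous_spacers(mk(c(a = 30, b = 30, c = 30)))
  expect_length(res_eq$flagged, 0L)

  # single spacer: only the absolute cap applies
  res_single <- flag_promiscuous_spacers(mk(c(solo = 500)))
  expect_length(res_single$flagged, 0L)
  res_cap <- flag_promiscuous_spacers(mk(c(solo = 1500)))
  expect_equal(res_cap$flagged, "solo")
})

test_that("local scans are confined to each spacer's own subject", {
  set.seed(104)
  sp <- stats::setNames(rand_dna(2, 34), c("spA", "spB"))
  contigs <- data.table::data.table(
    contig_id = c("c1", "c2"),
    subject = c("S01", "S02"),
    sample = c("S01_t01", "S02_t05"),
    seq = c(paste0(rand_dna(1, 100), sp[["spA"]], rand_dna(1, 100)),
            paste0(rand_dna(1, 100), sp[["spB"]], rand_dna(1, 100))))
  pairs <- data.frame(spacer_id = c("spA", "spB"),
                      subject = c("S02", "S02"))
  hits <- local_protospacer_scan(sp, pairs, contigs)
  # spA's protospacer is in S01, but spA belongs to S02: no local hit;
  # spB found in S02 even though only present at one late timepoint
  expect_false("spA" %in% hits$spacer_id)
  expect_true("spB" %in% hits$spacer_id)

  bad <- data.table::copy(contigs)
  bad$subject[1] <- ""
  expect_error(local_protospacer_scan(sp, pairs, bad), "provenance")
})
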