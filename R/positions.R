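# Positional analysis of spacers along oriented arrays: sliding-window
# densities of a focal flag (e.g. local adaptation) over normalized array
# positions, leading/middle/distal region enrichment with exact binomial
# confidence intervals, and eligibility filtering.

#' Normalized spacer positions along an oriented array
#'
#' Spacer i (0-based from the leader) maps to midpoint (i + 0.5) / n; a
#' reverse-oriented array is flipped first so 0 is always the leading end.
#'
#' @param n_spacers spacer count (>= 1).
#' @param orientation "forward" or "reverse" ("unknown" is an error:
#'   unoriented arrays are ineligible for positional analyses).
#' @return numeric vector of positions in (0, 1), in stored spacer order.
#' @export
normalized_positions <- function(n_spacers, orientation = "forward") {
  if (orientation == "unknown") {
    stop("array with unknown orientation is ineligible", call. = FALSE)
  }
  stopifnot(n_spacers >= 1L)
  p <- (seq_len(n_spacers) - 0.5) / n_spacers
  if (orientation == "reverse") 1 - p else p
}

#' Sliding-window density of a flag along normalized positions
#'
#' Windows [c - w/2, c + w/2) are laid over a symmetric grid of centers
#' spanning w/2 to 1 - w/2 (clipped at the array ends); the step is
#' snapped to the nearest value that tiles the span exactly, so the grid
#' mirrors onto itself when arrays are flipped. The density in a window
#' is the flagged fraction among spacers whose midpoint falls in it,
#' pooled over arrays. Empty windows are reported with `NA` density.
#'
#' @param positions numeric vector of normalized midpoints in [0, 1].
#' @param flags logical vector, same length.
#' @param width_frac window width as a fraction of array length (default
#'   0.12).
#' @param step_frac grid step (default 0.015).
#' @return `data.table` with `center`, `density`, `n` (spacers in
#'   window).
#' @export
sliding_window_density <- function(positions, flags, width_frac = 0.12,
                                   step_frac = 0.015) {
  if (width_frac <= 0) stop("width_frac must be positive", call. = FALSE)
  if (step_frac <= 0 || step_frac > width_frac) {
    stop("need 0 < step_frac <= width_frac", call. = FALSE)
  }
  stopifnot(length(positions) == length(flags))
  w <- width_frac / 2
  n_win <- max(1L, as.integer(round((1 - 2 * w) / step_frac)) + 1L)
  centers <- if (n_win == 1L) 0.5 else seq(w, 1 - w, length.out = n_win)
  out <- data.table::data.table(center = centers, density = NA_real_,
                                n = 0L)
  for (i in seq_along(centers)) {
    lo <- max(0, centers[i] - w)
    hi <- min(1 + 1e-12, centers[i] + w)
    inw <- positions >= lo & positions < hi
    n <- sum(inw)
    data.table::set(out, i, "n", n)
    if (n > 0L) data.table::set(out, i, "density", sum(flags[inw]) / n)
  }
  out
}

#' Assign spacers to leading / middle / distal thirds
#'
#' @param positions normalized midpoints in [0, 1].
#' @return character vector over {"leading", "middle", "distal"}:
#'   [0, 1/3) leading, [1/3, 2/3) middle, [2/3, 1] distal.
#' @export
region_assignment <- function(positions) {
  ifelse(positions < 1 / 3, "leading",
         ifelse(positions < 2 / 3, "middle", "distal"))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric c(lower, upper); lower is exactly 0 when k = 0
#'   and upper exactly 1 when k = n.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1L || k < 0L || k > n) stop("need 0 <= k <= n, n >= 1",
                                      call. = FALSE)
  a <- (1 - level) / 2
  lower <- if (k == 0L) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Region enrichment of a focal predicate with exact CIs
#'
#' Per region: k = focal spacers, n = denominator spacers, fraction k/n
#' with a Clopper-Pearson interval. Regions with n = 0 are reported with
#' missing fraction.
#'
#' @param regions character vector of region labels per spacer.
#' @param focal logical vector: spacer satisfies the focal predicate.
#' @param denominator logical vector: spacer counts toward the
#'   denominator (default all).
#' @param level confidence level.
#' @return `data.table`: `region`, `k`, `n`, `fraction`, `ci_lo`,
#'   `ci_hi`, ordered leading, middle, distal.
#' @export
region_enrichment <- function(regions, focal,
                              denominator = rep(TRUE, length(regions)),
                              level = 0.95) {
  stopifnot(length(regions) == length(focal),
            length(regions) == length(denominator))
  out <- data.table::data.table(region = c("leading", "middle", "distal"),
                                k = 0L, n = 0L, fraction = NA_real_,
                                ci_lo = NA_real_, ci_hi = NA_real_)
  for (i in seq_len(nrow(out))) {
    sel <- regions == out$region[i] & denominator
    n <- sum(sel); k <- sum(focal & sel)
    data.table::set(out, i, "k", k)
    data.table::set(out, i, "n", n)
    if (n > 0L) {
      ci <- clopper_pearson(k, n, level)
      data.table::set(out, i, "fraction", k / n)
      data.table::set(out, i, "ci_lo", ci[["lower"]])
      data.table::set(out, i, "ci_hi", ci[["upper"]])
    }
  }
  out
}

#' Eligibility filter for positional analyses
#'
#' Keeps oriented arrays with more than `min_spacers - 1` spacers (the
#' default keeps arrays with > 5 spacers) belonging to subtypes that
#' retain at least `min_arrays_per_subtype` such arrays.
#'
#' @param arrays array `data.table` (columns `orientation`, `subtype`,
#'   list-column `spacers`).
#' @param min_spacers minimum spacer count (default 6, i.e. "> 5").
#' @param min_arrays_per_subtype minimum eligible arrays per subtype
#'   (default 25).
#' @return the eligible subset of `arrays`.
#' @export
eligibility_filter <- function(arrays, min_spacers = 6L,
                               min_arrays_per_subtype = 25L) {
  if (nrow(arrays) == 0L) return(arrays)
  ok <- arrays$orientation %in% c("forward", "reverse") &
    lengths(arrays$spacers) >= min_spacers
  sub <- arrays[ok, ]
  if (nrow(sub) == 0L) return(sub)
  cnt <- table(sub$subtype)
  keep_sub <- names(cnt)[cnt >= min_arrays_per_subtype]
  sub[sub$subtype %in% keep_sub, ]
}

#' Positional profile of a spacer flag over a set of arrays
#'
#' Pools normalized spacer midpoints over all eligible arrays and runs
#' [sliding_window_density()] plus thirds-based [region_enrichment()].
#'
#' @param arrays eligible oriented arrays (see [eligibility_filter()]).
#' @param flag_of_spacer named logical vector: spacer id -> focal flag.
#' @param params a [crispr_params()] object.
#' @param denominator_of_spacer optional named logical: spacer id ->
#'   counts toward the region-enrichment denominator (default all).
#' @return list with `profile`, `regions`, `n_arrays`.
#' @export
positional_profile <- function(arrays, flag_of_spacer,
                               params = crispr_params(),
                               denominator_of_spacer = NULL) {
  pos <- numeric(0); flg <- logical(0); den <- logical(0)
  for (i in seq_len(nrow(arrays))) {
    sp <- arrays$spacers[[i]]
    p <- normalized_positions(length(sp), arrays$orientation[i])
    pos <- c(pos, p)
    f <- flag_of_spacer[sp]
    f[is.na(f)] <- FALSE
    flg <- c(flg, unname(f))
    if (is.null(denominator_of_spacer)) {
      den <- c(den, rep(TRUE, length(sp)))
    } else {
      d <- denominator_of_spacer[sp]
      d[is.na(d)] <- FALSE
      den <- c(den, unname(d))
    }
  }
  profile <- sliding_window_density(pos, flg, params$window_width_frac,
                                    params$window_step_frac)
  regions <- region_enrichment(region_assignment(pos), flg, den,
                               params$ci_level)
  list(profile = profile, regions = regions, n_arrays = nrow(arrays))
}
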