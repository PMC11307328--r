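# Trajectory clustering. Each episode's per-sample presence/absence of
# (lineage, spacer, target) is encoded as a letter over a 6-state
# alphabet; strings are trimmed of empty ends and internal empty runs are
# collapsed; all pairs are globally aligned with affine gap scores; the
# normalized-score similarity network is clustered by two-level community
# detection; clusters are summarized as state-transition networks.
#
# Letter map (any fixed bijection yields identical alignments; this one
# is declared in the output schema for reproducibility):
#   A = empty (no lineage, no spacer, no target)
#   B = target only
#   C = lineage only
#   D = lineage + target
#   E = lineage + spacer
#   F = lineage + spacer + target
# Spacer presence without the lineage is impossible by construction, so
# exactly 6 of the 8 combinations are reachable.

.state_letter <- function(lineage, spacer, target) {
  if (any(spacer & !lineage)) {
    stop("invalid state: spacer present without its lineage", call. = FALSE)
  }
  ifelse(!lineage & !spacer & !target, "A",
  ifelse(!lineage & !spacer & target, "B",
  ifelse(lineage & !spacer & !target, "C",
  ifelse(lineage & !spacer & target, "D",
  ifelse(lineage & spacer & !target, "E", "F")))))
}

#' Encode an episode as a trimmed, collapsed state string
#'
#' @param lineage,spacer,target logical vectors (one element per sample,
#'   full subject timeline or retained samples).
#' @param timepoints optional integer sample indices (defaults to
#'   1..length); retained indices are returned alongside the letters.
#' @return list of class `state_string` with `letters` (single character
#'   string), `timepoints` (indices retained after trimming/collapsing).
#' @export
encode_trajectory <- function(lineage, spacer, target,
                              timepoints = seq_along(lineage)) {
  stopifnot(length(lineage) == length(spacer),
            length(lineage) == length(target))
  letters <- .state_letter(lineage, spacer, target)
  nonempty <- letters != "A"
  if (!any(nonempty)) stop("all-empty episode cannot be encoded",
                           call. = FALSE)
  lo <- which(nonempty)[1L]
  hi <- which(nonempty)[sum(nonempty)]
  letters <- letters[lo:hi]
  tps <- timepoints[lo:hi]
  keep <- rep(TRUE, length(letters))
  for (i in seq_along(letters)[-1L]) {
    if (letters[i] == "A" && letters[i - 1L] == "A" && keep[i - 1L]) {
      keep[i] <- FALSE
    } else if (letters[i] == "A" && !keep[i - 1L]) {
      keep[i] <- FALSE
    }
  }
  structure(list(letters = paste(letters[keep], collapse = ""),
                 timepoints = tps[keep]),
            class = "state_string")
}

#' Global alignment score of two state strings with affine gaps
#'
#' Needleman-Wunsch/Gotoh dynamic programming with end gaps penalized; a
#' gap of length g costs gap_open + (g - 1) * gap_extend.
#'
#' @param s1,s2 character strings (either may be empty: the score is
#'   then the pure gap cost of the other).
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (defaults 1, -2, -2, -1).
#' @return numeric scalar: the maximal global alignment score.
#' @export
align_state_strings <- function(s1, s2, match = 1, mismatch = -2,
                                gap_open = -2, gap_extend = -1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  gap_cost <- function(g) if (g == 0L) 0 else gap_open + (g - 1) * gap_extend
  if (n == 0L) return(gap_cost(m))
  if (m == 0L) return(gap_cost(n))
  NEG <- -Inf
  # M: ends in match/mismatch; X: gap in s2 (consume a); Y: gap in s1
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_cost(i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_cost(j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                               X[i, j + 1L] + gap_extend,
                               Y[i, j + 1L] + gap_open)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                               Y[i + 1L, j] + gap_extend,
                               X[i + 1L, j] + gap_open)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

#' Build the normalized similarity network of state strings
#'
#' Aligns every pair, normalizes the score by the length of the longer
#' member, and keeps edges with strictly positive weight (zero and
#' negative scores are discarded by default).
#'
#' @param strings named character vector of state strings.
#' @param params a [crispr_params()] object (alignment scores).
#' @param keep_zero keep exact-zero weights as edges (default FALSE).
#' @return `data.table` with columns `i`, `j`, `weight`.
#' @export
build_similarity_network <- function(strings, params = crispr_params(),
                                     keep_zero = FALSE) {
  ids <- names(strings)
  stopifnot(!is.null(ids), length(strings) >= 2L)
  edges <- list()
  ns <- length(strings)
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      sc <- align_state_strings(strings[[i]], strings[[j]],
                                params$align_match, params$align_mismatch,
                                params$align_gap_open,
                                params$align_gap_extend)
      w <- sc / max(nchar(strings[[i]]), nchar(strings[[j]]))
      if (w > 0 || (keep_zero && w == 0)) {
        edges[[length(edges) + 1L]] <- data.table::data.table(
          i = ids[i], j = ids[j], weight = w)
      }
    }
  }
  if (length(edges)) data.table::rbindlist(edges) else
    data.table::data.table(i = character(0), j = character(0),
                           weight = numeric(0))
}

#' Cluster the similarity network into trajectory communities
#'
#' Two-level community detection on the weighted undirected network. The
#' default objective is the map equation (Infomap); modularity-based
#' Louvain is available as an alternative. The best partition over
#' `trials` seeded restarts is returned; nodes without edges form
#' singleton clusters.
#'
#' @param edges edge table from [build_similarity_network()].
#' @param node_ids all node ids (isolated nodes included).
#' @param trials number of restarts (default 200).
#' @param method "infomap" or "louvain".
#' @return named integer vector: node id -> cluster id (1-based, ordered
#'   by decreasing cluster size).
#' @export
cluster_network <- function(edges, node_ids, trials = 200L,
                            method = c("infomap", "louvain")) {
  method <- match.arg(method)
  if (length(node_ids) == 0L) return(stats::setNames(integer(0),
                                                     character(0)))
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j", "weight")], directed = FALSE,
    vertices = data.frame(name = node_ids))
  if (igraph::ecount(g) == 0L) {
    return(stats::setNames(seq_along(node_ids), node_ids))
  }
  comm <- if (method == "infomap") {
    igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                            nb.trials = trials)
  } else {
    best <- NULL; best_mod <- -Inf
    for (b in seq_len(max(1L, trials %/% 10L))) {
      cand <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      mod <- igraph::modularity(cand)
      if (mod > best_mod) { best <- cand; best_mod <- mod }
    }
    best
  }
  mem <- igraph::membership(comm)
  # relabel by decreasing size, deterministic tiebreak on smallest member
  sizes <- table(mem)
  first_member <- vapply(names(sizes), function(cl) {
    min(names(mem)[mem == as.integer(cl)])
  }, character(1))
  ord <- order(-as.integer(sizes), first_member)
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- relab[as.character(mem)]
  stats::setNames(as.integer(out), names(mem))
}

#' Summarize one trajectory cluster
#'
#' Counts state occupancies over member strings and state transitions
#' between consecutive non-empty states, split into direct transitions
#' (adjacent retained samples) and indirect ones (spanning a collapsed
#' empty letter or a gap in retained samples); reports row-normalized
#' transition probabilities and the cluster's MGE-class composition
#' against the global composition.
#'
#' @param member_ids episode ids in the cluster.
#' @param state_strings named list of `state_string` objects.
#' @param episode_classes optional named character: episode id -> MGE
#'   class of its target.
#' @return list with `occupancy`, `transitions` (`data.table`: from, to,
#'   direct, indirect, total, probability), `class_composition`,
#'   `relative_association`, `n_members`.
#' @export
summarize_cluster <- function(member_ids, state_strings,
                              episode_classes = NULL) {
  stopifnot(length(member_ids) >= 1L)
  occ <- integer(0)
  trans <- list()
  for (id in member_ids) {
    ss <- state_strings[[id]]
    letters <- strsplit(ss$letters, "")[[1]]
    tps <- ss$timepoints
    for (l in letters) occ[l] <- (if (is.na(occ[l])) 0L else occ[l]) + 1L
    ne <- which(letters != "A")
    if (length(ne) >= 2L) {
      for (k in seq_len(length(ne) - 1L)) {
        i1 <- ne[k]; i2 <- ne[k + 1L]
        direct <- (i2 == i1 + 1L) && (tps[i2] == tps[i1] + 1L)
        trans[[length(trans) + 1L]] <- data.table::data.table(
          from = letters[i1], to = letters[i2], direct = direct)
      }
    }
  }
  transitions <- if (length(trans)) {
    tr <- data.table::rbindlist(trans)
    agg <- tr[, list(direct = sum(direct), indirect = sum(!direct),
                     total = .N), by = c("from", "to")]
    tot_from <- tr[, list(n_from = .N), by = "from"]
    agg <- merge(agg, tot_from, by = "from")
    agg$probability <- agg$total / agg$n_from
    agg$n_from <- NULL
    data.table::setorder(agg, from, to)
    agg
  } else NULL
  comp <- rel <- NULL
  if (!is.null(episode_classes)) {
    cls <- episode_classes[member_ids]
    comp <- table(cls)
    glob <- table(episode_classes)
    shared <- intersect(names(comp), names(glob))
    rel <- (comp[shared] / sum(comp)) /
      (glob[shared] / sum(glob))
  }
  list(occupancy = occ[order(names(occ))], transitions = transitions,
       class_composition = comp, relative_association = rel,
       n_members = length(member_ids))
}

#' Encode, align and cluster all episodes of a dataset
#'
#' @param episodes episode table from [select_episodes()].
#' @param params a [crispr_params()] object.
#' @param episode_classes optional named character of MGE classes.
#' @return list with `strings`, `edges`, `clusters`, `summaries`.
#' @export
cluster_trajectories <- function(episodes, params = crispr_params(),
                                 episode_classes = NULL) {
  if (nrow(episodes) == 0L) {
    return(list(strings = list(),
                edges = data.table::data.table(i = character(0),
                                               j = character(0),
                                               weight = numeric(0)),
                clusters = stats::setNames(integer(0), character(0)),
                summaries = list()))
  }
  strings <- list()
  for (i in seq_len(nrow(episodes))) {
    strings[[episodes$episode_id[i]]] <- encode_trajectory(
      lineage = episodes$tl_lineage[[i]],
      spacer = episodes$tl_spacer[[i]],
      target = episodes$tl_target[[i]],
      timepoints = episodes$tl_timepoints[[i]])
  }
  letter_vec <- vapply(strings, function(s) s$letters, character(1))
  if (length(letter_vec) < 2L) {
    clusters <- stats::setNames(rep(1L, length(letter_vec)),
                                names(letter_vec))
    edges <- data.table::data.table(i = character(0), j = character(0),
                                    weight = numeric(0))
  } else {
    edges <- build_similarity_network(letter_vec, params)
    clusters <- cluster_network(edges, names(letter_vec),
                                trials = params$community_trials)
  }
  summaries <- lapply(sort(unique(clusters)), function(cl) {
    summarize_cluster(names(clusters)[clusters == cl], strings,
                      episode_classes)
  })
  list(strings = strings, edges = edges, clusters = clusters,
       summaries = summaries)
}
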