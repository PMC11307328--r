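# Stage orchestration. Stages run in dependency order
# (simulate -> lineages -> targets -> positions/dynamics -> trajectories),
# each consuming the previous stage's in-memory outputs and writing TSV
# tables plus a JSON manifest. A CLI wrapper lives in
# inst/cli/crispr-memory.R.

.pipeline_stages <- c("simulate", "lineages", "targets", "positions",
                      "dynamics", "trajectories")
.stage_deps <- list(
  simulate = character(0),
  lineages = "dataset",
  targets = "dataset",
  positions = c("dataset", "targets"),
  dynamics = c("dataset", "lineages", "targets"),
  trajectories = c("dataset", "dynamics")
)

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `crispr_dataset` (without the embedded truth object unless
#'   the truth/ tables are present).
#' @export
read_dataset <- function(dir) {
  aset <- read_array_table(file.path(dir, "arrays.tsv"),
                           file.path(dir, "sequences.fasta"))
  cseq <- read_fasta(file.path(dir, "contigs.fasta"))
  prov <- read_tsv(file.path(dir, "contig_provenance.tsv"))
  contigs <- data.table::data.table(
    contig_id = prov$contig_id, subject = prov$subject,
    sample = prov$sample,
    target_id = if ("target_id" %in% names(prov)) prov$target_id
                else NA_character_,
    seq = unname(cseq[prov$contig_id]))
  structure(list(
    arrays = aset,
    contigs = contigs,
    array_intervals = read_tsv(file.path(dir, "array_intervals.tsv")),
    mge_annotations = read_tsv(file.path(dir, "mge_annotations.tsv")),
    mge_seqs = read_fasta(file.path(dir, "mge.fasta")),
    abundance = read_tsv(file.path(dir, "abundance.tsv")),
    samples = read_tsv(file.path(dir, "samples.tsv"))
  ), class = "crispr_dataset")
}

#' Run pipeline stages on a dataset
#'
#' Requested stages are completed in dependency order; requesting a stage
#' whose upstream outputs are unavailable raises a dependency error
#' naming the missing stage. Outputs are written as TSV under `outdir`
#' with a manifest; the full state is returned for programmatic use.
#' Reruns with the same seed and inputs produce byte-identical tables.
#'
#' @param stages subset of `c("simulate", "lineages", "targets",
#'   "positions", "dynamics", "trajectories")` or `"all"`.
#' @param dataset a `crispr_dataset`; required unless `"simulate"` is
#'   among the stages.
#' @param params a [crispr_params()] object.
#' @param sim_cfg a [sim_config()] used by the simulate stage.
#' @param outdir output directory (NULL for no file output).
#' @param verbose log per-stage counts via [message()].
#' @return list of stage outputs plus the written manifest.
#' @export
run_pipeline <- function(stages = "all", dataset = NULL,
                         params = crispr_params(),
                         sim_cfg = sim_config(rng_seed = params$rng_seed),
                         outdir = NULL, verbose = FALSE) {
  if (identical(stages, "all")) stages <- .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  state <- list(dataset = dataset)
  tables <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  need <- function(what, stage) {
    if (is.null(state[[what]])) {
      stop("stage '", stage, "' requires missing upstream output '", what,
           "' (run its producing stage first)", call. = FALSE)
    }
  }

  for (stage in stages) {
    for (dep in setdiff(.stage_deps[[stage]], "dataset")) need(dep, stage)
    if ("dataset" %in% .stage_deps[[stage]]) need("dataset", stage)
    if (stage == "simulate") {
      truth <- simulate_community(sim_cfg)
      state$dataset <- emit_observed_dataset(truth)
      tables$sim_arrays <- data.table::data.table(
        array_id = state$dataset$arrays$arrays$array_id,
        subject = state$dataset$arrays$arrays$subject,
        timepoint = state$dataset$arrays$arrays$timepoint,
        n_spacers = lengths(state$dataset$arrays$arrays$spacers))
      say("simulate: %d observed arrays, %d acquisitions",
          nrow(state$dataset$arrays$arrays), nrow(truth$acquisitions))
    } else if (stage == "lineages") {
      set.seed(derive_seed(params$rng_seed, "lineages"))
      state$lineages <- build_all_lineages(state$dataset$arrays, params)
      tables$lineages <- state$lineages$membership
      tables$lineage_presence <- state$lineages$presence
      cons <- lapply(split(seq_len(nrow(state$lineages$membership)),
                           state$lineages$membership$lineage_id),
                     function(idx) {
        ids <- state$lineages$membership$array_id[idx]
        members <- state$dataset$arrays$arrays[
          state$dataset$arrays$arrays$array_id %in% ids, ]
        cbind(lineage_id = state$lineages$membership$lineage_id[idx[1L]],
              lineage_consistency_metrics(members,
                                          state$dataset$arrays$spacer_seqs))
      })
      tables$consistency <- data.table::rbindlist(cons)
      say("lineages: %d lineages over %d arrays",
          length(unique(state$lineages$membership$lineage_id)),
          nrow(state$lineages$membership))
    } else if (stage == "targets") {
      set.seed(derive_seed(params$rng_seed, "targets"))
      state$targets <- classify_targets(state$dataset, params)
      tables$assignments <- state$targets$assignments
      tables$db_hits <- state$targets$db_hits
      tables$local_hits <- state$targets$local_hits
      say("targets: %d spacers classified, %d local hits",
          nrow(state$targets$assignments), nrow(state$targets$local_hits))
    } else if (stage == "positions") {
      eligible <- eligibility_filter(state$dataset$arrays$arrays,
                                     params$min_spacers_oriented,
                                     params$min_arrays_per_subtype)
      asg <- state$targets$assignments
      flag <- stats::setNames(asg$locally_adapted, asg$spacer_id)
      pp <- if (nrow(eligible)) positional_profile(eligible, flag, params)
            else NULL
      state$positions <- list(eligible = eligible, profile = pp)
      if (!is.null(pp)) {
        tables$positional_profile <- pp$profile
        tables$region_enrichment <- pp$regions
      }
      say("positions: %d eligible arrays", nrow(eligible))
    } else if (stage == "dynamics") {
      set.seed(derive_seed(params$rng_seed, "dynamics"))
      eps <- select_episodes(state$dataset, state$lineages,
                             state$targets$local_hits, params)
      ps <- if (nrow(eps)) phase_statistics(eps, state$dataset$abundance,
                                            params) else NULL
      dv <- diversity_analysis(state$dataset, state$lineages,
                               state$targets$local_hits, params)
      state$dynamics <- list(episodes = eps, phase_stats = ps,
                             diversity = dv)
      tables$episodes <- if (nrow(eps)) eps[, c("episode_id", "spacer_id",
                                                "lineage_id", "target_id",
                                                "subject",
                                                "acquisition_tp")] else
        data.table::data.table()
      if (!is.null(ps)) {
        tables$phase_stats <- ps$summary
        if (!is.null(ps$tests)) tables$tests <- ps$tests
      }
      tables$diversity <- dv$diversity
      say("dynamics: %d episodes", nrow(eps))
    } else if (stage == "trajectories") {
      set.seed(derive_seed(params$rng_seed, "trajectories"))
      eps <- state$dynamics$episodes
      asg <- state$targets$assignments
      cls <- stats::setNames(asg$target_class, asg$spacer_id)
      ep_cls <- if (nrow(eps)) stats::setNames(unname(cls[eps$spacer_id]),
                                               eps$episode_id) else NULL
      tc <- cluster_trajectories(eps, params, ep_cls)
      state$trajectories <- tc
      if (length(tc$strings)) {
        tables$trajectories <- data.table::data.table(
          episode_id = names(tc$strings),
          state_string = vapply(tc$strings, function(s) s$letters,
                                character(1)))
        tables$network <- tc$edges
        tables$clusters <- data.table::data.table(
          episode_id = names(tc$clusters),
          cluster = unname(tc$clusters))
      }
      say("trajectories: %d strings, %d clusters", length(tc$strings),
          length(unique(tc$clusters)))
    }
  }
  manifest <- NULL
  if (!is.null(outdir)) {
    manifest <- write_results(tables, outdir, params)
    manifest$stages <- stages
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  c(state, list(tables = tables, manifest = manifest, stages = stages))
}
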