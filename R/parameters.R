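# Parameter registry: all numeric thresholds used across the pipeline live
# here, with validation and config-file loading.

.param_defaults <- list(
  protospacer_min_identity = 0.95,
  protospacer_min_coverage = 0.95,
  repeat_cluster_identity  = 0.90,
  repeat_cluster_coverage  = 0.90,
  spacer_derep_identity    = 1.00,
  repeat_mask_margin       = 100L,
  neighborhood_flank_target    = 7500L,
  neighborhood_flank_abundance = 2000L,
  neighborhood_score_ratio = 0.9,
  neighborhood_evalue_analog = 1e-8,
  window_width_frac = 0.12,
  window_step_frac  = 0.015,
  min_spacers_oriented   = 6L,
  min_arrays_per_subtype = 25L,
  min_spacer_samples     = 2L,
  n_bootstraps = 2000L,
  ci_level     = 0.95,
  align_match     = 1L,
  align_mismatch  = -2L,
  align_gap_open  = -2L,
  align_gap_extend = -1L,
  community_trials = 200L,
  rng_seed = 1L
)

.param_fraction_keys <- c(
  "protospacer_min_identity", "protospacer_min_coverage",
  "repeat_cluster_identity", "repeat_cluster_coverage",
  "spacer_derep_identity", "neighborhood_score_ratio",
  "window_width_frac", "window_step_frac", "ci_level"
)

#' Pipeline parameters
#'
#' Builds a validated set of analysis parameters. Defaults reflect the
#' thresholds used throughout the pipeline: 95% identity and coverage for
#' protospacer matches, 90% identity/coverage repeat clustering, a 100 bp
#' repeat-masking margin, 15 kb (7.5 kb per flank) target-rescue
#' neighborhoods, 4 kb (2 kb per flank) abundance neighborhoods, a 0.9
#' bitscore ratio for rescue hits, a sliding window of 12% of array length
#' stepped by 1.5%, oriented arrays with more than 5 spacers and subtypes
#' with at least 25 such arrays for positional analyses, spacers present in
#' at least 2 samples for episode selection, 2000 bootstrap replicates with
#' 95% confidence, state-string alignment scores (1, -2, -2, -1), and 200
#' community-detection trials.
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return object of class `crispr_params` (a named list).
#' @export
crispr_params <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(.param_defaults))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- .param_defaults
  for (k in names(over)) p[[k]] <- over[[k]]
  validate_params(p)
  # preserve integer-ness of integer-typed defaults
  int_keys <- names(.param_defaults)[vapply(.param_defaults, is.integer, logical(1))]
  for (k in int_keys) p[[k]] <- as.integer(p[[k]])
  structure(p, class = "crispr_params")
}

validate_params <- function(p) {
  for (k in .param_fraction_keys) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("parameter '", k, "' must be a fraction in [0, 1], got: ",
           format(v), call. = FALSE)
    }
  }
  for (k in c("repeat_mask_margin", "neighborhood_flank_target",
              "neighborhood_flank_abundance")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("parameter '", k, "' must be a positive size in nt", call. = FALSE)
    }
  }
  for (k in c("min_spacers_oriented", "min_arrays_per_subtype",
              "min_spacer_samples", "n_bootstraps", "community_trials")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop("parameter '", k, "' must be a positive integer", call. = FALSE)
    }
  }
  if (p$align_match <= 0) {
    stop("parameter 'align_match' must be positive", call. = FALSE)
  }
  for (k in c("align_mismatch", "align_gap_open", "align_gap_extend")) {
    if (p[[k]] > 0) {
      stop("parameter '", k, "' must be <= 0", call. = FALSE)
    }
  }
  if (p$window_step_frac > p$window_width_frac) {
    stop("window_step_frac must not exceed window_width_frac", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.crispr_params <- function(x, ...) {
  cat("CRISPR pipeline parameters:\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load parameters from a JSON config file
#'
#' The file holds a flat JSON object whose keys are parameter names; absent
#' keys take their defaults, unknown keys are rejected, out-of-range values
#' raise a validation error. An empty file (or empty object) yields the
#' defaults.
#'
#' @param path path to a JSON config file.
#' @return a [crispr_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(crispr_params())
  cfg <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE),
    error = function(e) stop("malformed config file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(cfg)) stop("config must be a JSON object of parameter keys",
                          call. = FALSE)
  do.call(crispr_params, cfg)
}
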