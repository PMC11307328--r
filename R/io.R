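# Readers and writers for the package's plain-text interchange formats:
# TSV array tables with companion FASTA sequence files, TSV result tables,
# and a JSON run manifest. TSV is the single tabular dialect (tab, UTF-8,
# header row, "." for missing values).

.tsv_na <- "."

#' Read a TSV table
#'
#' @param path file path.
#' @return a `data.table`.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = .tsv_na,
                    colClasses = NULL, data.table = TRUE)
}

#' Write a TSV table
#'
#' Missing values are serialized as ".". Column order is preserved, so a
#' table writes byte-identically across reruns.
#'
#' @param x data.frame or data.table.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = .tsv_na, quote = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector (names = record ids up to first space).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Array collection: TSV + FASTA reader
#'
#' Reads a CRISPR array table (columns `array_id`, `subject`, `sample`,
#' `timepoint`, `repeat_id`, `spacer_ids` as a comma-separated ordered
#' list, optional `orientation` and `subtype`) together with a FASTA file
#' holding both repeat and spacer sequences. Spacer order in the table is
#' the order in the array (leader to trailer when the array is oriented
#' forward).
#'
#' @param tsv path to the array table.
#' @param fasta path to the FASTA with repeat and spacer sequences.
#' @return an object of class `array_set`: a list with `arrays` (a
#'   `data.table` with a list-column `spacers` of ordered spacer ids),
#'   `spacer_seqs` and `repeat_seqs` (named character vectors).
#' @export
read_array_table <- function(tsv, fasta) {
  tab <- read_tsv(tsv)
  need <- c("array_id", "subject", "sample", "timepoint", "repeat_id",
            "spacer_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("array table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$array_id)) {
    dup <- unique(tab$array_id[duplicated(tab$array_id)])
    stop("duplicate array_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- read_fasta(fasta)
  spacers <- strsplit(as.character(tab$spacer_ids), ",", fixed = TRUE)
  all_ids <- unique(c(unlist(spacers), as.character(tab$repeat_id)))
  absent <- setdiff(all_ids, names(seqs))
  if (length(absent)) {
    stop("sequence id(s) with no FASTA entry: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  arrays <- data.table::data.table(
    array_id = as.character(tab$array_id),
    subject = as.character(tab$subject),
    sample = as.character(tab$sample),
    timepoint = as.integer(tab$timepoint),
    repeat_id = as.character(tab$repeat_id),
    orientation = if ("orientation" %in% names(tab)) {
      ifelse(is.na(tab$orientation), "unknown", as.character(tab$orientation))
    } else "unknown",
    subtype = if ("subtype" %in% names(tab)) as.character(tab$subtype)
              else NA_character_,
    spacers = spacers
  )
  spacer_ids <- unique(unlist(spacers))
  new_array_set(arrays,
                spacer_seqs = seqs[spacer_ids],
                repeat_seqs = seqs[unique(arrays$repeat_id)])
}

new_array_set <- function(arrays, spacer_seqs, repeat_seqs) {
  structure(list(arrays = arrays, spacer_seqs = spacer_seqs,
                 repeat_seqs = repeat_seqs),
            class = "array_set")
}

#' @export
print.array_set <- function(x, ...) {
  cat(sprintf("array_set: %d arrays, %d subjects, %d spacers, %d repeats\n",
              nrow(x$arrays), length(unique(x$arrays$subject)),
              length(x$spacer_seqs), length(x$repeat_seqs)))
  invisible(x)
}

#' Write an array collection back to TSV + FASTA
#'
#' Inverse of [read_array_table()]: a written set read back reproduces the
#' original field-for-field.
#'
#' @param aset an `array_set`.
#' @param tsv output TSV path.
#' @param fasta output FASTA path.
#' @export
write_array_table <- function(aset, tsv, fasta) {
  a <- aset$arrays
  out <- data.table::data.table(
    array_id = a$array_id, subject = a$subject, sample = a$sample,
    timepoint = a$timepoint, repeat_id = a$repeat_id,
    spacer_ids = vapply(a$spacers, paste, character(1), collapse = ","),
    orientation = a$orientation, subtype = a$subtype
  )
  write_tsv(out, tsv)
  seqs <- c(aset$repeat_seqs, aset$spacer_seqs)
  write_fasta(seqs[!duplicated(names(seqs))], fasta)
  invisible(tsv)
}

#' Write named result tables with a run manifest
#'
#' Each table is written as `<name>.tsv` under `outdir`; a `manifest.json`
#' records the parameters, the RNG seed, and an md5 checksum per file.
#' Reruns with identical inputs and seed produce byte-identical files (no
#' timestamps are written).
#'
#' @param tables named list of data.frames.
#' @param outdir output directory (created if absent).
#' @param params a [crispr_params()] object recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables, outdir, params = crispr_params()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2L) != 0L) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], f)
    files[nm] <- f
  }
  manifest <- list(
    package = "crisprmemory",
    rng_seed = params$rng_seed,
    parameters = unclass(params),
    tables = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
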