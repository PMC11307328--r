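# Small shared helpers: sequence manipulation, canonical spacer ids, RNG
# bookkeeping.

#' Reverse complement of a DNA string
#'
#' Ambiguity codes are complemented where defined; characters outside the
#' IUPAC alphabet are left untouched after reversal.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Strand-insensitive canonical form of a sequence
#'
#' Returns the lexicographically smaller of a sequence and its reverse
#' complement, so a spacer and its reverse complement share one identity.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of canonical sequences.
#' @export
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Deterministic child seed from a master seed and a stream label.
# Keeps derived seeds in [1, 2^31 - 2].
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chars <- utf8ToInt(as.character(stream))
  h <- sum(chars * seq_along(chars))
  as.integer((abs(seed) * 69069 + h * 1013 + 1) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
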