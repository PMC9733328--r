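#' The genetic code used by the package
#'
#' Returns the codon translation table as a named character vector mapping all
#' 64 DNA codons to single-letter amino acids, with `"*"` marking stop codons.
#' The default is the standard nuclear code (sourced from
#' [Biostrings::GENETIC_CODE]), which has exactly three stops: TAA, TAG, TGA.
#' An alternative 64-entry table may be supplied by callers of the
#' combinatorics functions, but all documented behaviour assumes the standard
#' code.
#'
#' @return named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["CAG"]]  # "Q"
genetic_code <- function() {
  code <- .pkg_env$code
  if (is.null(code)) {
    gc <- Biostrings::GENETIC_CODE
    code <- stats::setNames(as.character(gc), names(gc))
    .validate_code(code)
    .pkg_env$code <- code
  }
  code
}

.pkg_env <- new.env(parent = emptyenv())

.validate_code <- function(code) {
  if (length(code) != 64L || is.null(names(code)))
    stop("genetic code table must have exactly 64 named entries", call. = FALSE)
  if (!setequal(names(code)[code == "*"], STOP_CODONS))
    stop("standard code must have stops {TAA, TAG, TGA}", call. = FALSE)
  invisible(code)
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation. Codons containing N are rendered as `"X"`
#' (undetermined) rather than guessed; stop codons are rendered as `"*"`.
#' A trailing partial codon is dropped with a warning.
#'
#' @param cds DNA string; length need not be a multiple of 3.
#' @param code 64-entry codon table, defaults to [genetic_code()].
#' @return amino-acid string (possibly empty).
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cds <- .validate_dna(cds, allow_n = TRUE, what = "cds")
  if (nchar(cds) %% 3L != 0L)
    warning("cds length not a multiple of 3; trailing partial codon dropped")
  cod <- codons(cds)
  if (length(cod) == 0L) return("")
  aa <- unname(code[cod])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}
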