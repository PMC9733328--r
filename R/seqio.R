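# Readers/writers for the plain-text formats the pipeline touches. FASTA
# parsing is line-oriented so that malformed input can be reported with the
# offending line number.

#' Read a FASTA file of DNA sequences
#'
#' Residues are uppercased on ingestion and RNA `U` is mapped to `T`. Any
#' character outside `{A,C,G,T,N}` (after those liftings) is a parse error
#' that names the offending line.
#'
#' @param path path to a plain-text FASTA file.
#' @return named character vector of sequences, in file order. An empty file
#'   yields an empty vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  .parse_fasta_lines(lines, path, alphabet = "ACGTN")
}

.parse_fasta_lines <- function(lines, path, alphabet) {
  keep <- !grepl("^\\s*$", lines)
  ids <- character(0)
  seqs <- character(0)
  buf <- character(0)
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    line <- lines[i]
    if (startsWith(line, ">")) {
      id <- trimws(sub("^>", "", line))
      if (nchar(id) == 0L)
        stop(sprintf("%s: malformed header at line %d (empty id)", path, i),
             call. = FALSE)
      flush()
      cur <- id
      buf <- character(0)
    } else {
      if (is.null(cur))
        stop(sprintf("%s: sequence data before any header at line %d", path, i),
             call. = FALSE)
      up <- chartr("u", "T", chartr("U", "T", toupper(line)))
      bad <- regmatches(up, regexpr(sprintf("[^%s]", alphabet), up))
      if (length(bad) > 0L)
        stop(sprintf("%s: illegal character '%s' at line %d", path, bad, i),
             call. = FALSE)
      buf <- c(buf, up)
    }
  }
  flush()
  stats::setNames(seqs, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector (ids as names).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    body <- if (n == 0L) character(0) else {
      starts <- seq.int(1L, n, by = width)
      substring(s, starts, pmin(starts + width - 1L, n))
    }
    out <- c(out, paste0(">", names(seqs)[i]), body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gapped multi-FASTA alignment of an element family
#'
#' All rows must be the same length (gaps `-` included). The first record is
#' taken as the family consensus unless `consensus_id` names another record.
#'
#' @param path aligned multi-FASTA.
#' @param consensus_id optional id of the record to use as consensus.
#' @return a [family_alignment] object.
#' @export
read_alignment <- function(path, consensus_id = NULL) {
  lines <- readLines(path)
  rows <- .parse_fasta_lines(lines, path, alphabet = "ACGTN-")
  family_alignment(rows, consensus_id = consensus_id)
}

#' Write a family alignment back to gapped multi-FASTA
#'
#' The consensus is emitted first so that [read_alignment()] round-trips.
#'
#' @param aln a [family_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "family_alignment"))
  rows <- c(stats::setNames(aln$consensus, aln$consensus_id), aln$copies)
  write_fasta(rows, path, width = 80L)
}

#' Read exon models from a BED file
#'
#' Expects BED with at least 3 columns (chrom, start, end); column 4 (name)
#' groups exons into transcripts and column 6 gives the strand. Intervals are
#' kept 0-based half-open, the BED convention.
#'
#' @param path BED path.
#' @return a list of [exon_model] objects, one per transcript name (or per
#'   chromosome when no name column is present).
#' @export
read_exon_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop(path, ": BED needs at least 3 columns", call. = FALSE)
  key <- if (ncol(tab) >= 4L) paste(tab[[1]], tab[[4]]) else tab[[1]]
  out <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    strand <- if (ncol(sub) >= 6L) sub[[6]][1] else "+"
    exon_model(seq_id = sub[[1]][1],
               exons = cbind(start = sub[[2]], end = sub[[3]]),
               strand = strand)
  })
  unname(out)
}

#' Construct an exon model
#'
#' @param seq_id label of the parent sequence.
#' @param exons two-column matrix of (start, end), 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `exon_model`.
#' @export
exon_model <- function(seq_id, exons, strand = "+") {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon end must exceed start", call. = FALSE)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons overlap", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(seq_id = seq_id, exons = exons, strand = strand),
            class = "exon_model")
}

#' Write records to TSV or JSON with a deterministic layout
#'
#' Column order is preserved as given and floating-point values are written
#' with 6 significant digits, so identical inputs yield byte-identical files.
#'
#' @param records a data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    out <- records
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- formatC(signif(out[[j]], 6), format = "g")
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = 6, dataframe = "rows")
  }
  invisible(path)
}
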