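#' Parse a BED file (3--6 columns)
#'
#' Strict parser for the interchange format used throughout the pipeline:
#' whitespace-delimited, 0-based half-open coordinates, optional name, score
#' and strand columns. Lines starting with `track`, `browser` or `#` are
#' skipped. Malformed lines are rejected (never coerced) with the offending
#' line number in the error.
#'
#' @param path Path to a BED file.
#' @return A data.frame with `seqname`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
parse_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("%s: line %d has fewer than 3 columns",
                 path, lineno[which(nf < 3L)[1]]))
  }
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s: line %d has non-numeric coordinates", path,
                 lineno[bad[1]]))
  }
  bad <- which(start < 0L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has a negative coordinate", path, lineno[bad[1]]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("%s: line %d has start >= end", path, lineno[bad[1]]))
  }
  out <- data.frame(seqname = get(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- get(4)
  if (all(nf >= 5L)) {
    score <- suppressWarnings(as.numeric(get(5)))
    bad <- which(is.na(score))
    if (length(bad)) {
      stop(sprintf("%s: line %d has a non-numeric score", path, lineno[bad[1]]))
    }
    out$score <- score
  }
  if (all(nf >= 6L)) {
    strand <- get(6)
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad)) {
      stop(sprintf("%s: line %d has an invalid strand", path, lineno[bad[1]]))
    }
    out$strand <- strand
  }
  out
}

#' Write intervals as BED
#'
#' @param x Data.frame with `seqname`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (0-based half-open), or a `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "GRanges")) x <- granges_to_df0(x)
  cols <- c("seqname", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(x)) cols <- c(cols, extra) else break
  }
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as named character
#' vectors so downstream code can stay string-based.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @param width Line-wrap width for writing.
#' @return `read_fasta`: named character vector.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read a table as TSV
#'
#' TSV with header, `.` decimal separator, no quoting or row names -- the
#' tabular interchange used for tract samples, Cq values and summaries.
#'
#' @param df Data.frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a two-channel fiber field as TIFF
#'
#' The backbone and damage channels are stored as two pages of one 16-bit
#' grayscale TIFF. Intensities are stored as counts in [0, 65535].
#'
#' @param field A fiber field list with `backbone` and `damage` matrices.
#' @param path File path.
#' @return `read_fiber_tiff`: list with `backbone` and `damage` matrices on
#'   the original count scale.
#' @export
write_fiber_tiff <- function(field, path) {
  clip <- function(m) pmin(pmax(m, 0), 65535) / 65535
  tiff::writeTIFF(list(clip(field$backbone), clip(field$damage)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_fiber_tiff
#' @export
read_fiber_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L) stop("expected a two-page TIFF, got ",
                                length(pages), " page(s)")
  list(backbone = pages[[1]] * 65535, damage = pages[[2]] * 65535)
}
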