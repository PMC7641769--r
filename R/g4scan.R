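#' Scanner parameters for G4 motif prediction
#'
#' The default parameters encode the canonical three-tetrad motif grammar
#' (G>=3 N1-25)3 G>=3: four tracts of at least three consecutive guanines
#' separated by loops of 1--25 nucleotides. Setting `min_tract = 2` gives the
#' two-tetrad mode used to describe the less stable quadruplexes found on the
#' non-transcribed strand of 5S rDNA genes.
#'
#' @param min_tract Minimum G-tract length in bp (number of tetrad layers).
#' @param n_tracts Number of G-tracts required (4 for an intramolecular G4).
#' @param loop_min,loop_max Allowed loop lengths in bp.
#' @param strands Which strands to scan: `"both"`, `"+"` or `"-"`.
#' @param mask Optional `GRanges` (or data.frame with `start`/`end`, 0-based
#'   half-open) of regions to exclude; motifs intersecting a masked interval
#'   are dropped. Used, e.g., to exclude repetitive telomeric/rDNA sequence.
#' @return A `scan_params` list.
#' @export
scan_params <- function(min_tract = 3L, n_tracts = 4L, loop_min = 1L,
                        loop_max = 25L, strands = c("both", "+", "-"),
                        mask = NULL) {
  strands <- match.arg(strands)
  min_tract <- as.integer(min_tract)
  n_tracts <- as.integer(n_tracts)
  loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  if (min_tract < 2L) stop("min_tract must be >= 2")
  if (n_tracts < 2L) stop("n_tracts must be >= 2")
  if (loop_min < 1L || loop_min > loop_max) {
    stop("need 0 < loop_min <= loop_max")
  }
  structure(list(min_tract = min_tract, n_tracts = n_tracts,
                 loop_min = loop_min, loop_max = loop_max,
                 strands = strands, mask = mask),
            class = "scan_params")
}

# Maximal G-runs in an uppercase sequence string; 1-based start/end.
g_runs <- function(seq) {
  m <- gregexpr("G+", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L, len = len)
}

# Depth-first chain search over the run table: from run `i`, extend with the
# nearest eligible run first (minimal loops), backtracking when a short loop
# dead-ends where a longer one would complete the chain. Returns indices of
# the chained runs or NULL.
chain_from <- function(runs, elig, i, depth, params) {
  if (depth == params$n_tracts) return(i)
  gap <- runs$start[elig] - runs$end[i] - 1L
  nxt <- elig[gap >= params$loop_min & gap <= params$loop_max &
                runs$start[elig] > runs$end[i]]
  for (j in nxt) {  # elig is start-ordered, so this tries minimal loops first
    res <- chain_from(runs, elig, j, depth + 1L, params)
    if (!is.null(res)) return(c(i, res))
  }
  NULL
}

# Scan one strand of an uppercase sequence. Returns a list of matches, each
# with 1-based tract start/end vectors (coordinates on the scanned strand).
scan_strand <- function(seq, params) {
  runs <- g_runs(seq)
  keep <- runs$len >= params$min_tract
  cand <- which(keep)
  out <- list()
  last_end <- 0L
  for (i in cand) {
    if (runs$start[i] <= last_end) next  # leftmost non-overlapping, resume
    chain <- chain_from(runs, cand, i, 1L, params)
    if (is.null(chain)) next
    out[[length(out) + 1L]] <- list(tstart = runs$start[chain],
                                    tend = runs$end[chain])
    last_end <- runs$end[chain[length(chain)]]
  }
  out
}

check_alphabet <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq, perl = TRUE)
  if (bad != -1L) {
    stop(sprintf("illegal character '%s' at position %d (allowed: A,C,G,T,N)",
                 substr(seq, bad, bad), as.integer(bad)))
  }
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

empty_motif_table <- function() {
  tibble::tibble(seqname = character(), start = integer(), end = integer(),
                 strand = character(), n_tetrads = integer(),
                 tract_starts = list(), tract_ends = list(),
                 loop_lengths = list(), stall_site = integer(),
                 stall_at_boundary = logical(), seq_length = integer(),
                 motif_seq = character())
}

# Assert an emitted motif against its own grammar (self-check on construction).
validate_motif <- function(seq, ts, te, params) {
  stopifnot(length(ts) == params$n_tracts,
            all(te - ts + 1L >= params$min_tract))
  for (k in seq_along(ts)) {
    tract <- substr(seq, ts[k], te[k])
    if (gsub("G", "", tract) != "") stop("internal: tract contains non-G")
    # maximality of the run
    if (ts[k] > 1L && substr(seq, ts[k] - 1L, ts[k] - 1L) == "G") {
      stop("internal: tract not maximal")
    }
    if (te[k] < nchar(seq) && substr(seq, te[k] + 1L, te[k] + 1L) == "G") {
      stop("internal: tract not maximal")
    }
  }
  loops <- ts[-1L] - te[-length(te)] - 1L
  if (any(loops < params$loop_min | loops > params$loop_max)) {
    stop("internal: loop length outside bounds")
  }
  invisible(TRUE)
}

#' Scan a nucleotide sequence for G4 motifs
#'
#' Finds leftmost non-overlapping matches of the quadruplex pattern on the
#' requested strands, scanning 5'->3' on each strand. G-tracts are maximal
#' runs of G; loops are matched minimally, with backtracking so a match is
#' reported whenever the pattern can be satisfied. Minus-strand motifs are
#' found on the reverse complement and mapped back to forward-reference
#' 0-based half-open coordinates. Opposite-strand motifs are reported
#' independently and never merged.
#'
#' @param seq A nucleotide string over A, C, G, T, N (case-insensitive).
#' @param params A [scan_params()] object.
#' @param seqname Sequence name attached to the output records.
#' @return A tibble with one row per motif: 0-based half-open `start`/`end`,
#'   `strand`, `n_tetrads` (= `min_tract` used), list-columns `tract_starts`/
#'   `tract_ends` (0-based half-open, forward reference, ascending),
#'   `loop_lengths` (in motif-strand 5'->3' order), the annotated
#'   `stall_site` (see [annotate_stall()]), and the matched `motif_seq`
#'   (motif-strand orientation). Sorted by (`start`, `strand`).
#' @examples
#' scan_sequence("GGGAGGGAGGGAGGG")
#' @export
scan_sequence <- function(seq, params = scan_params(), seqname = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(empty_motif_table())
  check_alphabet(seq)
  L <- nchar(seq)
  rows <- list()

  add_matches <- function(matches, strand, strand_seq) {
    for (m in matches) {
      validate_motif(strand_seq, m$tstart, m$tend, params)
      s1 <- m$tstart[1L]
      e1 <- m$tend[length(m$tend)]
      loops <- m$tstart[-1L] - m$tend[-length(m$tend)] - 1L
      if (strand == "+") {
        start0 <- s1 - 1L; end0 <- e1
        ts0 <- m$tstart - 1L; te0 <- m$tend
      } else {
        # motif occupies [s1-1, e1) on the reverse complement; mirror back
        start0 <- L - e1; end0 <- L - (s1 - 1L)
        ts0 <- rev(L - m$tend); te0 <- rev(L - (m$tstart - 1L))
      }
      rows[[length(rows) + 1L]] <<- list(
        start = start0, end = end0, strand = strand,
        tract_starts = ts0, tract_ends = te0, loop_lengths = loops,
        motif_seq = substr(strand_seq, s1, e1))
    }
  }

  if (params$strands %in% c("both", "+")) {
    add_matches(scan_strand(seq, params), "+", seq)
  }
  if (params$strands %in% c("both", "-")) {
    add_matches(scan_strand(revcomp_chr(seq), params), "-", revcomp_chr(seq))
  }
  if (length(rows) == 0L) return(empty_motif_table())

  tab <- tibble::tibble(
    seqname = seqname,
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    n_tetrads = params$min_tract,
    tract_starts = lapply(rows, `[[`, "tract_starts"),
    tract_ends = lapply(rows, `[[`, "tract_ends"),
    loop_lengths = lapply(rows, `[[`, "loop_lengths"),
    seq_length = L,
    motif_seq = vapply(rows, `[[`, character(1), "motif_seq"))
  tab <- tab[order(tab$start, tab$strand), ]

  if (!is.null(params$mask)) {
    ms <- if (inherits(params$mask, "GRanges")) {
      data.frame(start = GenomicRanges::start(params$mask) - 1L,
                 end = GenomicRanges::end(params$mask))
    } else as.data.frame(params$mask)
    hit <- vapply(seq_len(nrow(tab)), function(i) {
      any(tab$start[i] < ms$end & tab$end[i] > ms$start)
    }, logical(1))
    tab <- tab[!hit, ]
  }

  st <- annotate_stall(tab)
  tab$stall_site <- st$stall_site
  tab$stall_at_boundary <- st$at_boundary
  tab[, c("seqname", "start", "end", "strand", "n_tetrads", "tract_starts",
          "tract_ends", "loop_lengths", "stall_site", "stall_at_boundary",
          "seq_length", "motif_seq")]
}

#' Annotate the polymerase stall site of G4 motifs
#'
#' Primer-extension experiments show DNA synthesis halting one nucleotide
#' before the first G-tract of a folded quadruplex. The stall site is the
#' base immediately 5' of the first tract in the motif strand's orientation:
#' forward-reference coordinate `start - 1` for a plus-strand motif and
#' `end` for a minus-strand motif (0-based). When the motif abuts the
#' sequence boundary the site does not exist and is flagged.
#'
#' @param motifs A motif table from [scan_sequence()] (needs `start`, `end`,
#'   `strand`, `seq_length`).
#' @return A tibble with `stall_site` (NA at a boundary) and
#'   `at_boundary`.
#' @export
annotate_stall <- function(motifs) {
  n <- nrow(motifs)
  site <- integer(n)
  boundary <- logical(n)
  for (i in seq_len(n)) {
    if (motifs$strand[i] == "+") {
      site[i] <- motifs$start[i] - 1L
      boundary[i] <- motifs$start[i] == 0L
    } else {
      site[i] <- motifs$end[i]
      boundary[i] <- motifs$end[i] >= motifs$seq_length[i]
    }
  }
  site[boundary] <- NA_integer_
  tibble::tibble(stall_site = site, at_boundary = boundary)
}

#' Scan a FASTA file (or DNAStringSet) for G4 motifs
#'
#' Applies [scan_sequence()] to every record and concatenates the results in
#' file order. This is the genome-wide entry point; with the default
#' parameters on the fission-yeast reference assembly it reproduces the
#' canonical intramolecular three-tetrad motif census (use `mask` to exclude
#' repetitive telomeric/rDNA regions as such censuses do).
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param params A [scan_params()] object.
#' @return Motif tibble as in [scan_sequence()], rows ordered by sequence
#'   (file order) then coordinate.
#' @export
scan_fasta <- function(fasta, params = scan_params()) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else {
    Biostrings::readDNAStringSet(fasta)
  }
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  res <- lapply(seq_along(seqs), function(i) {
    scan_sequence(as.character(seqs[[i]]), params, seqname = nms[i])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_motif_table() else out
}

#' Convert a motif table to BED6 records
#'
#' @param motifs Motif tibble from [scan_sequence()]/[scan_fasta()].
#' @return A data.frame with BED6 columns (`seqname`, `start`, `end`,
#'   `name` = `G4_<n>`, `score` = 0, `strand`), 0-based half-open.
#' @export
motifs_to_bed <- function(motifs) {
  data.frame(seqname = motifs$seqname, start = motifs$start, end = motifs$end,
             name = paste0("G4_", seq_len(nrow(motifs))), score = 0L,
             strand = motifs$strand, stringsAsFactors = FALSE)
}
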