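# Independent oracles, written before the implementations they check and
# kept deliberately naive: character-level recursion instead of run tables,
# per-base boolean marking instead of interval algebra, all-pairs loops
# instead of overlap indices.

# Character-level brute-force quadruplex matcher for one strand.
# Semantics: leftmost non-overlapping matches; a tract is a maximal run of
# >= min_tract G's; loops tried shortest-first with full backtracking.
oracle_scan_strand <- function(seq, min_tract = 3L, n_tracts = 4L,
                               loop_min = 1L, loop_max = 25L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  is_g <- ch == "G"
  run_end <- function(p) {
    q <- p
    while (q < n && is_g[q + 1L]) q <- q + 1L
    q
  }
  # try to complete a chain whose previous tract ended at e
  extend <- function(e, tracts_left) {
    if (tracts_left == 0L) return(e)
    for (l in loop_min:loop_max) {
      q <- e + l + 1L
      if (q + min_tract - 1L > n) return(NULL)
      if (!is_g[q] || is_g[q - 1L]) next        # must start a maximal run
      re <- run_end(q)
      if (re - q + 1L < min_tract) next
      done <- extend(re, tracts_left - 1L)
      if (!is.null(done)) return(done)
    }
    NULL
  }
  out <- NULL
  p <- 1L
  while (p + n_tracts * min_tract + (n_tracts - 1L) * loop_min - 1L <= n) {
    if (is_g[p] && (p == 1L || !is_g[p - 1L])) {
      re <- run_end(p)
      if (re - p + 1L >= min_tract) {
        e <- extend(re, n_tracts - 1L)
        if (!is.null(e)) {
          out <- rbind(out, c(start = p - 1L, end = e))  # 0-based half-open
          p <- e  # resume after the match
        }
      }
    }
    p <- p + 1L
  }
  if (is.null(out)) {
    data.frame(start = integer(), end = integer())
  } else {
    as.data.frame(out)
  }
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(seq)), "")[[1]]),
        collapse = "")
}

# Both strands, mapped to forward coordinates, sorted by (start, strand).
oracle_scan <- function(seq, min_tract = 3L, loop_max = 25L) {
  n <- nchar(seq)
  plus <- oracle_scan_strand(seq, min_tract = min_tract, loop_max = loop_max)
  plus$strand <- rep("+", nrow(plus))
  minus <- oracle_scan_strand(oracle_revcomp(seq), min_tract = min_tract,
                              loop_max = loop_max)
  minus <- data.frame(start = n - minus$end, end = n - minus$start,
                      strand = rep("-", nrow(minus)))
  out <- rbind(plus, minus)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Union of 0-based half-open intervals by marking a boolean array.
oracle_union_bp <- function(df) {
  if (nrow(df) == 0) return(0L)
  total <- 0L
  for (sn in unique(df$seqname)) {
    sub <- df[df$seqname == sn, ]
    hit <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) hit[(sub$start[i] + 1):sub$end[i]] <- TRUE
    total <- total + sum(hit)
  }
  total
}

# All-pairs overlap counting.
oracle_overlap_counts <- function(peaks, feats) {
  pw <- 0L
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(feats))) {
      if (peaks$seqname[i] == feats$seqname[j] &&
          peaks$start[i] < feats$end[j] && peaks$end[i] > feats$start[j]) {
        pw <- pw + 1L
        break
      }
    }
  }
  fw <- 0L
  for (j in seq_len(nrow(feats))) {
    for (i in seq_len(nrow(peaks))) {
      if (peaks$seqname[i] == feats$seqname[j] &&
          peaks$start[i] < feats$end[j] && peaks$end[i] > feats$start[j]) {
        fw <- fw + 1L
        break
      }
    }
  }
  c(pw, fw)
}

random_intervals <- function(n, space = 10000L, max_len = 300L,
                             seqnames = "chr1") {
  start <- sample.int(space - max_len, n, replace = TRUE)
  data.frame(seqname = sample(seqnames, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

# Small fiber-field configuration shared by the imaging tests.
small_fiber_config <- function(seed, n_molecules = 20L, image_size = 512L,
                               molecule_length_mean = 12,
                               molecule_length_sd = 3, ...) {
  sim_config(seed = seed, n_molecules = n_molecules, image_size = image_size,
             molecule_length_mean = molecule_length_mean,
             molecule_length_sd = molecule_length_sd, ...)
}
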