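#' Generate a genome with planted G4 motifs and ground truth
#'
#' Draws a background sequence at the configured GC fraction that is free of
#' quadruplex matches on either strand (rejection sampling: the sequence is
#' rescanned and matched spans are re-drawn until clean), then plants
#' `n_planted_motifs` canonical motifs at recorded non-overlapping positions,
#' half on each strand. Planted motifs use A/T loops and A/T guard flanks
#' one base longer than the maximum loop, so they cannot chain with
#' background guanine runs into earlier hybrid matches; the finished genome
#' is verified to scan to exactly the planted set,
#' so scanning it with the same parameters gives recall = precision = 1.
#'
#' @param config A [sim_config()].
#' @param params Scanner parameters the genome is guaranteed against
#'   (defaults to [scan_params()] defaults).
#' @return List with `sequence` (character) and `truth`, a tibble of planted
#'   motifs (0-based half-open `start`/`end`, `strand`, `motif_seq`).
#' @export
gen_genome_with_motifs <- function(config = sim_config(),
                                   params = scan_params()) {
  with_config_seed(config, 1L, {
    L <- config$genome_length
    motifs <- replicate(config$n_planted_motifs,
                        draw_motif_seq(config, params), simplify = FALSE)
    widths <- vapply(motifs, nchar, integer(1)) + 2L * (params$loop_max + 2L)
    if (sum(widths) + config$n_planted_motifs > L) {
      stop("genome_length too small to host n_planted_motifs without overlap")
    }

    seq <- draw_clean_background(L, config$gc_fraction, params)

    truth <- NULL
    for (attempt in 1:25) {
      placed <- place_motifs(seq, motifs, config, params)
      if (is.null(placed)) next
      # Guarantee: the planted genome scans to exactly the truth set.
      got <- scan_sequence(placed$sequence, params)
      ok <- nrow(got) == nrow(placed$truth) &&
        all(got$start == placed$truth$start) &&
        all(got$end == placed$truth$end) &&
        all(got$strand == placed$truth$strand)
      if (ok) {
        truth <- placed
        break
      }
    }
    if (is.null(truth)) {
      stop("could not place motifs so that the scan recovers exactly the ",
           "planted set; increase genome_length or reduce n_planted_motifs")
    }
    list(sequence = truth$sequence, truth = truth$truth)
  })
}

# One canonical planted motif: n_tracts G-runs of lengths drawn from the
# configured tract range, joined by A/T loops from the configured loop range.
draw_motif_seq <- function(config, params) {
  tl <- pmax(config$tract_length_range, params$min_tract)
  tract_len <- sample(seq(tl[1], tl[2]), params$n_tracts, replace = TRUE)
  ll <- config$loop_length_range
  ll[2] <- min(ll[2], params$loop_max)
  loop_len <- sample(seq(max(ll[1], params$loop_min), ll[2]),
                     params$n_tracts - 1L, replace = TRUE)
  parts <- character(2L * params$n_tracts - 1L)
  parts[seq(1, length(parts), by = 2)] <- vapply(
    tract_len, function(k) strrep("G", k), character(1))
  parts[seq(2, length(parts), by = 2)] <- vapply(
    loop_len, function(k) paste(sample(c("A", "T"), k, replace = TRUE),
                                collapse = ""), character(1))
  paste(parts, collapse = "")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Background free of scanner matches on both strands: draw, scan, re-draw
# the matched spans (with padding) until no match remains.
draw_clean_background <- function(L, gc, params) {
  p <- base_probs(gc)
  chars <- sample(names(p), L, replace = TRUE, prob = p)
  for (iter in 1:100) {
    seq <- paste(chars, collapse = "")
    hits <- scan_sequence(seq, scan_params(
      min_tract = params$min_tract, n_tracts = params$n_tracts,
      loop_min = params$loop_min, loop_max = params$loop_max))
    if (nrow(hits) == 0L) return(seq)
    for (i in seq_len(nrow(hits))) {
      s <- max(1L, hits$start[i] - 1L)
      e <- min(L, hits$end[i] + 2L)
      chars[s:e] <- sample(names(p), e - s + 1L, replace = TRUE, prob = p)
    }
  }
  stop("failed to draw a motif-free background; lower gc_fraction")
}

# Insert motifs (alternating strands) at non-overlapping positions. Each
# motif is flanked on both sides by an A/T guard one base longer than the
# maximum loop, so a background G- or C-run can never chain with the
# planted tracts into an earlier hybrid match (the gap across a guard
# always exceeds loop_max). Returns NULL if placement collides.
place_motifs <- function(seq, motifs, config, params) {
  L <- nchar(seq)
  n <- length(motifs)
  if (n == 0L) {
    return(list(sequence = seq,
                truth = tibble::tibble(start = integer(), end = integer(),
                                       strand = character(),
                                       motif_seq = character())))
  }
  guard <- params$loop_max + 2L
  strand <- rep(c("+", "-"), length.out = n)
  widths <- vapply(motifs, nchar, integer(1))
  occupied <- matrix(numeric(0), ncol = 2)
  starts <- integer(n)  # 1-based start of the guarded block
  for (i in seq_len(n)) {
    w <- widths[i] + 2L * guard
    ok <- FALSE
    for (try in 1:200) {
      s <- sample.int(L - w, 1L)
      if (nrow(occupied) == 0 ||
          all(s + w - 1L < occupied[, 1] - 2 | s > occupied[, 2] + 2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
    occupied <- rbind(occupied, c(s, s + w - 1L))
    starts[i] <- s
  }
  chars <- strsplit(seq, "")[[1]]
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    body <- motifs[[i]]
    if (strand[i] == "-") body <- revcomp_chr(body)
    s <- starts[i]
    block <- c(sample(c("A", "T"), guard, replace = TRUE),
               strsplit(body, "")[[1]],
               sample(c("A", "T"), guard, replace = TRUE))
    chars[s:(s + length(block) - 1L)] <- block
    truth_rows[[i]] <- tibble::tibble(
      start = s + guard - 1L,  # 0-based motif start
      end = s + guard - 1L + widths[i],
      strand = strand[i],
      motif_seq = motifs[[i]])
  }
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$start, truth$strand), ]
  list(sequence = paste(chars, collapse = ""), truth = truth)
}
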