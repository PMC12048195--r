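iupac_ok <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Per-window mismatch counts of `primer` against reference windows starting
# at `starts` (1-based), IUPAC-aware on the primer side.
window_mismatches <- function(primer_chars, ref_chars, starts) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(map[primer_chars], "")
  k <- length(primer_chars)
  vapply(starts, function(s) {
    w <- ref_chars[s:(s + k - 1L)]
    sum(!mapply(function(set, b) b %in% set, sets, w))
  }, integer(1))
}

#' Locate primer binding sites on a reference
#'
#' Finds every window of the reference, on both strands, that a primer can
#' anneal to under a mismatch-count model of specificity: at most
#' `max_mismatch` mismatches are allowed outside the primer's 3'-terminal
#' `anchor_len` bases, which must match exactly (mispriming at the 3' end
#' blocks extension). IUPAC ambiguity codes in the primer match their base
#' sets. Minus-strand sites are windows whose reverse complement the primer
#' matches; positions always refer to the plus strand.
#'
#' @param primer Primer sequence, 5' to 3' as synthesized (uppercase IUPAC
#'   DNA).
#' @param reference Reference sequence (character scalar of A/C/G/T) or a
#'   `pah_reference`.
#' @param max_mismatch Maximum mismatches tolerated outside the anchor
#'   (default 2, a permissive virtual-PCR setting).
#' @param anchor_len Number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @return Tibble with columns `position` (0-based window start on the plus
#'   strand), `strand` (`"+"`/`"-"`) and `mismatches`, ordered by position.
#'   A primer longer than the reference yields zero rows.
#' @export
find_primer_sites <- function(primer, reference, max_mismatch = 2L,
                              anchor_len = 3L) {
  if (inherits(reference, "pah_reference")) reference <- reference$seq
  stopifnot(max_mismatch >= 0, anchor_len >= 0)
  primer <- toupper(primer)
  reference <- toupper(reference)
  if (!iupac_ok(primer)) abort("primer contains non-IUPAC characters")
  if (!grepl("^[ACGTN]*$", reference)) abort("reference contains non-DNA characters")
  k <- nchar(primer)
  if (k > nchar(reference)) {
    return(tibble(position = integer(), strand = character(),
                  mismatches = integer()))
  }
  anchor_len <- min(anchor_len, k)
  subject <- Biostrings::DNAString(reference)

  scan_strand <- function(pat, strand) {
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), subject,
      max.mismatch = max_mismatch, fixed = c(pattern = FALSE, subject = TRUE)
    )
    starts <- Biostrings::start(hits)
    if (!length(starts)) {
      return(tibble(position = integer(), strand = character(),
                    mismatches = integer()))
    }
    ref_chars <- strsplit(reference, "")[[1]]
    pat_chars <- strsplit(pat, "")[[1]]
    mm <- window_mismatches(pat_chars, ref_chars, starts)
    # 3' anchor of the primer: last bases on "+", first window bases on "-"
    anchor_idx <- if (strand == "+") (k - anchor_len + 1L):k else seq_len(anchor_len)
    ok <- vapply(seq_along(starts), function(i) {
      if (anchor_len == 0L) return(TRUE)
      w <- ref_chars[(starts[i] + anchor_idx - 1L)]
      all(mapply(function(set, b) b %in% set,
                 strsplit(Biostrings::IUPAC_CODE_MAP[pat_chars[anchor_idx]], ""), w))
    }, logical(1))
    tibble(position = starts[ok] - 1L, strand = strand, mismatches = mm[ok])
  }

  out <- dplyr::bind_rows(
    scan_strand(primer, "+"),
    scan_strand(revcomp(primer), "-")
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Enumerate predicted PCR products for a primer panel
#'
#' Virtual PCR: for each primer pair, every combination of a plus-strand
#' forward-primer site and a minus-strand reverse-primer site downstream of
#' it yields a candidate product; products within `[min_len, max_len]` are
#' emitted. Products that do not overlap any target interval are flagged
#' off-target rather than dropped. Pairs yielding no in-range product are
#' recorded as design failures in the `"design_failures"` attribute, not
#' raised as errors.
#'
#' @param pairs Tibble of primer pairs with columns `name`, `fwd_seq`,
#'   `rev_seq` (both 5' to 3' as synthesized).
#' @param reference Character reference sequence or a `pah_reference`.
#' @param min_len,max_len Product size filter in bp (defaults 1500 and
#'   5000, the panel's design range).
#' @param targets Optional target tibble (see [toy_targets()]) used to flag
#'   off-target products.
#' @param max_mismatch,anchor_len Site-search parameters, see
#'   [find_primer_sites()].
#' @return Tibble of amplicons: `pair`, `contig`, `start`, `end` (0-based
#'   half-open, primers included), `length`, `fwd_mismatches`,
#'   `rev_mismatches`, `on_target` (`NA` when no targets given).
#' @export
enumerate_amplicons <- function(pairs, reference, min_len = 1500L,
                                max_len = 5000L, targets = NULL,
                                max_mismatch = 2L, anchor_len = 3L) {
  contig <- if (inherits(reference, "pah_reference")) reference$contig else "ref"
  if (min_len > max_len) {
    warn("min_len exceeds max_len: no amplicon can satisfy the size filter")
    return(structure(empty_amplicons(), design_failures = pairs$name))
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    fwd <- find_primer_sites(pairs$fwd_seq[i], reference, max_mismatch, anchor_len)
    rev <- find_primer_sites(pairs$rev_seq[i], reference, max_mismatch, anchor_len)
    fwd <- fwd[fwd$strand == "+", ]
    rev <- rev[rev$strand == "-", ]
    if (!nrow(fwd) || !nrow(rev)) return(empty_amplicons())
    grid <- tidyr::expand_grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    start <- fwd$position[grid$f]
    end <- rev$position[grid$r] + nchar(pairs$rev_seq[i])
    len <- end - start
    keep <- len >= min_len & len <= max_len
    tibble(
      pair = pairs$name[i], contig = contig,
      start = start[keep], end = end[keep], length = len[keep],
      fwd_mismatches = fwd$mismatches[grid$f][keep],
      rev_mismatches = rev$mismatches[grid$r][keep]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$on_target <- if (is.null(targets)) NA else {
    purrr::map_lgl(seq_len(nrow(out)), function(i) {
      any(targets$start < out$end[i] & out$start[i] < targets$end)
    })
  }
  failures <- pairs$name[!pairs$name %in% out$pair]
  structure(dplyr::arrange(out, .data$start, .data$end),
            design_failures = failures)
}

empty_amplicons <- function() {
  tibble(pair = character(), contig = character(), start = integer(),
         end = integer(), length = integer(), fwd_mismatches = integer(),
         rev_mismatches = integer())
}

#' Per-target coverage of an amplicon set
#'
#' Interval arithmetic on 0-based half-open intervals: for each target, the
#' number of amplicons overlapping it and the fraction of its bases covered
#' by the union of all amplicons.
#'
#' @param amplicons Amplicon tibble from [enumerate_amplicons()].
#' @param targets Target tibble with `contig`, `start`, `end` (and
#'   optionally `kind`).
#' @return The targets tibble with `n_amplicons` and `covered_fraction`
#'   columns added; the attribute `"complete"` is `TRUE` iff every target's
#'   fraction equals 1. An empty amplicon set yields all-zero coverage.
#' @export
coverage_report <- function(amplicons, targets) {
  out <- targets
  if (nrow(amplicons) == 0) {
    out$n_amplicons <- 0L
    out$covered_fraction <- 0
    return(structure(out, complete = FALSE))
  }
  n_amp <- integer(nrow(targets))
  frac <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    same <- amplicons[amplicons$contig == targets$contig[i], ]
    ov <- same$start < targets$end[i] & targets$start[i] < same$end
    n_amp[i] <- sum(ov)
    if (!any(ov)) next
    amp_r <- IRanges::reduce(IRanges::IRanges(same$start[ov] + 1L, same$end[ov]))
    tgt_r <- IRanges::IRanges(targets$start[i] + 1L, targets$end[i])
    frac[i] <- sum(IRanges::width(IRanges::intersect(amp_r, tgt_r))) /
      IRanges::width(tgt_r)
  }
  out$n_amplicons <- n_amp
  out$covered_fraction <- frac
  structure(out, complete = all(frac == 1))
}

#' Assign amplicons to non-overlapping PCR pools
#'
#' Greedy interval colouring: amplicons are sorted by start then length and
#' each is placed in the lowest-numbered pool containing no amplicon that
#' overlaps it on the reference, so that products within one tube cannot
#' interfere by overlap. For intervals this first-fit scan uses the minimum
#' possible number of pools; if more than `n_pools` would be needed the
#' mutually overlapping set is reported as an error.
#'
#' @param amplicons Amplicon tibble.
#' @param n_pools Number of tubes available (default 2).
#' @return The amplicon tibble, sorted by `start` then `length`, with an
#'   integer `pool` column.
#' @export
assign_pools <- function(amplicons, n_pools = 2L) {
  stopifnot(n_pools >= 1)
  x <- dplyr::arrange(amplicons, .data$start, .data$length)
  pool <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    taken <- integer(0)
    if (i > 1) {
      prev <- seq_len(i - 1L)
      ov <- x$start[prev] < x$end[i] & x$start[i] < x$end[prev] &
        x$contig[prev] == x$contig[i]
      taken <- unique(pool[prev][ov])
    }
    free <- setdiff(seq_len(n_pools), taken)
    if (!length(free)) {
      clique <- c(x$pair[prev][ov], x$pair[i])
      abort(paste0("cannot assign ", n_pools, " pool(s): mutually overlapping ",
                   "amplicons ", paste(clique, collapse = ", ")))
    }
    pool[i] <- min(free)
  }
  x$pool <- pool
  x
}

#' The shipped 9-pair toy panel
#'
#' Derives nine primer pairs (22-mers read off the toy reference) that tile
#' the whole gene body in nine overlapping ~3.3 kb products, mirroring the
#' design constraints of the assay: nine pairs, products between 1.5 and
#' 5 kb, complete coverage of exons, UTRs, junction flanks and reported
#' deep-intronic sites, and two internally non-overlapping pools (adjacent
#' tiles overlap, so they alternate tubes).
#'
#' @param ref A `pah_reference` from [build_toy_reference()].
#' @param primer_len Primer length in nt (default 22).
#' @return Tibble of primer pairs: `name`, `fwd_seq`, `rev_seq`.
#' @export
toy_panel <- function(ref, primer_len = 22L) {
  tile_len <- 3345L
  overlap <- 120L
  starts <- 960L + (0:8) * (tile_len - overlap)
  ends <- starts + tile_len
  stopifnot(max(ends) <= ref$length)
  tibble(
    name = sprintf("PAH_amp%02d", 1:9),
    fwd_seq = substring(ref$seq, starts + 1L, starts + primer_len),
    rev_seq = vapply(substring(ref$seq, ends - primer_len + 1L, ends),
                     revcomp, character(1), USE.NAMES = FALSE)
  )
}
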