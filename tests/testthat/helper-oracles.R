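# Independent oracles used across tests: deliberately naive implementations
# that share no code with the package internals.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Exhaustive position-by-position primer-site scan (exact bases only; no
# IUPAC), returning the same (position, strand, mismatches) layout as
# find_primer_sites(), 0-based positions.
brute_force_sites <- function(primer, reference, max_mismatch, anchor_len) {
  k <- nchar(primer)
  L <- nchar(reference)
  if (k > L) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  ref <- strsplit(reference, "")[[1]]
  scan <- function(pat, strand) {
    p <- strsplit(pat, "")[[1]]
    anchor_idx <- if (strand == "+") (k - anchor_len + 1L):k else seq_len(anchor_len)
    rows <- list()
    for (s in 0:(L - k)) {
      w <- ref[(s + 1):(s + k)]
      mm <- sum(w != p)
      if (mm <= max_mismatch && (anchor_len == 0 || all(w[anchor_idx] == p[anchor_idx]))) {
        rows[[length(rows) + 1]] <- data.frame(position = s, strand = strand,
                                               mismatches = mm)
      }
    }
    do.call(rbind, c(rows, list(data.frame(position = integer(),
                                           strand = character(),
                                           mismatches = integer()))))
  }
  out <- rbind(scan(primer, "+"), scan(revcomp_chr(primer), "-"))
  out[order(out$position, out$strand), , drop = FALSE]
}

# Interval-union coverage of [t_start, t_end) by a set of half-open
# intervals, via sorted sweep - no IRanges.
union_covered_fraction <- function(starts, ends, t_start, t_end) {
  s <- pmax(starts, t_start)
  e <- pmin(ends, t_end)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  covered <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  covered <- covered + (cur_e - cur_s)
  covered / (t_end - t_start)
}

fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pku_cohort()
    cache
  }
})

toy_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_reference(1)
    cache
  }
})
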