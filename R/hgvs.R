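#' Parse the HGVS c.-notation subset used in clinical PAH reports
#'
#' Parses coding-DNA (`c.`) variant descriptions of the kinds that occur in
#' PAH diagnostic reports: single-nucleotide substitutions (including
#' intronic positions written with a signed offset, e.g. `c.1066-11G>A`),
#' deletions (`c.592_613del`, `c.165del`) and deletion-insertions
#' (`c.100_102delinsTG`). An optional `NC_...(NM_...):` or `NM_...:` prefix
#' is recognised and whitespace around tokens is tolerated. Anything outside
#' this subset (duplications, insertions, inversions, protein or genomic
#' notation) raises an explicit error rather than being silently skipped.
#'
#' @param x Character vector of HGVS strings.
#'
#' @return A tibble with one row per input string and columns
#'   `raw` (input as given), `refseq_id` (chromosome accession or `NA`),
#'   `transcript_id` (transcript accession or `NA`), `kind`
#'   (`"substitution"`, `"deletion"` or `"delins"`), `start_pos`,
#'   `start_offset`, `end_pos`, `end_offset` (1-based CDS coordinates with
#'   signed intronic offsets, 0 when exonic), `ref_allele`, `alt_allele`
#'   (empty string when not stated), and `hgvs` (the canonical re-formatted
#'   string, see [format_hgvs()]).
#'
#' @examples
#' parse_hgvs_c("NC_000012.12(NM_000277.3):c.1066-11G > A")
#' parse_hgvs_c(c("c.592_613del", "c.168+5G>C"))
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x))
  purrr::map_dfr(x, parse_hgvs_one)
}

parse_hgvs_one <- function(s) {
  raw <- s
  if (is.na(s) || !nzchar(trimws(s))) {
    abort("cannot parse empty HGVS string")
  }
  z <- gsub("[[:space:]]+", "", s)

  refseq_id <- NA_character_
  transcript_id <- NA_character_
  m <- regmatches(z, regexec("^([A-Z]{2}_[0-9]+\\.[0-9]+)\\(([A-Z]{2}_[0-9]+\\.[0-9]+)\\):", z))[[1]]
  if (length(m)) {
    refseq_id <- m[2]
    transcript_id <- m[3]
    z <- substring(z, nchar(m[1]) + 1L)
  } else {
    m <- regmatches(z, regexec("^([A-Z]{2}_[0-9]+\\.[0-9]+):", z))[[1]]
    if (length(m)) {
      transcript_id <- m[2]
      z <- substring(z, nchar(m[1]) + 1L)
    }
  }

  if (!startsWith(z, "c.")) {
    abort(paste0("not a coding (c.) HGVS description: '", raw, "'"))
  }
  body <- substring(z, 3L)

  pos_re <- "([0-9]+)([+-][0-9]+)?"
  m <- regmatches(body, regexec(paste0("^", pos_re, "(?:_", pos_re, ")?(.*)$"), body))[[1]]
  if (!length(m)) {
    abort(paste0("cannot parse HGVS position in '", raw, "'"))
  }
  start_pos <- as.integer(m[2])
  start_offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  has_range <- nzchar(m[4])
  end_pos <- if (has_range) as.integer(m[4]) else start_pos
  end_offset <- if (has_range && nzchar(m[5])) as.integer(m[5]) else if (has_range) 0L else start_offset
  event <- m[6]

  if (start_pos < 1L) abort(paste0("CDS position must be >= 1 in '", raw, "'"))
  if (end_pos < start_pos || (end_pos == start_pos && end_offset < start_offset)) {
    abort(paste0("range end precedes start in '", raw, "'"))
  }

  if (grepl("^(dup|ins|inv)", event)) {
    abort(paste0("unsupported HGVS kind '", sub("^(dup|ins|inv).*$", "\\1", event),
                 "' in '", raw, "'"))
  }

  kind <- ref_allele <- alt_allele <- NULL
  if (grepl("^[ACGT]>[ACGT]$", event)) {
    if (has_range) abort(paste0("substitution cannot span a range in '", raw, "'"))
    ref_allele <- substring(event, 1L, 1L)
    alt_allele <- substring(event, 3L, 3L)
    if (ref_allele == alt_allele) {
      abort(paste0("degenerate substitution (ref equals alt) in '", raw, "'"))
    }
    kind <- "substitution"
  } else if (grepl("^delins[ACGT]+$", event)) {
    kind <- "delins"
    ref_allele <- ""
    alt_allele <- substring(event, 7L)
  } else if (grepl("^del[ACGT]*$", event)) {
    kind <- "deletion"
    ref_allele <- substring(event, 4L)
    alt_allele <- ""
    if (nzchar(ref_allele) && start_offset == 0L && end_offset == 0L &&
        nchar(ref_allele) != end_pos - start_pos + 1L) {
      abort(paste0("deleted sequence length disagrees with the span in '", raw, "'"))
    }
  } else {
    abort(paste0("cannot parse HGVS event token '", event, "' in '", raw, "'"))
  }

  out <- tibble(
    raw = raw, refseq_id = refseq_id, transcript_id = transcript_id,
    kind = kind, start_pos = start_pos, start_offset = start_offset,
    end_pos = end_pos, end_offset = end_offset,
    ref_allele = ref_allele, alt_allele = alt_allele
  )
  out$hgvs <- format_hgvs(out)
  out
}

#' Format parsed variants back to canonical HGVS strings
#'
#' The canonical form strips whitespace and keeps the accession prefix when
#' present, so `format_hgvs(parse_hgvs_c(s))` reproduces `s` up to
#' typographic spacing.
#'
#' @param v A tibble as returned by [parse_hgvs_c()].
#' @return Character vector of HGVS strings.
#' @export
format_hgvs <- function(v) {
  off <- function(o) ifelse(o == 0L, "", sprintf("%+d", o))
  pos <- paste0(v$start_pos, off(v$start_offset))
  rng <- v$end_pos != v$start_pos | v$end_offset != v$start_offset
  pos[rng] <- paste0(pos[rng], "_", v$end_pos[rng], off(v$end_offset[rng]))
  event <- dplyr::case_when(
    v$kind == "substitution" ~ paste0(v$ref_allele, ">", v$alt_allele),
    v$kind == "deletion" ~ paste0("del", v$ref_allele),
    v$kind == "delins" ~ paste0("delins", v$alt_allele)
  )
  core <- paste0("c.", pos, event)
  prefix <- dplyr::case_when(
    !is.na(v$refseq_id) ~ paste0(v$refseq_id, "(", v$transcript_id, "):"),
    !is.na(v$transcript_id) ~ paste0(v$transcript_id, ":"),
    TRUE ~ ""
  )
  paste0(prefix, core)
}

#' Canonical short key for a variant
#'
#' Reduces an HGVS string to its accession-free `c.` core (e.g.
#' `"c.1066-11G>A"`), the key under which variants are counted and looked up
#' across the package.
#'
#' @param x Character vector of HGVS strings (with or without accession
#'   prefix), or a parsed tibble from [parse_hgvs_c()].
#' @return Character vector of `c.` keys.
#' @examples
#' variant_key("NC_000012.12(NM_000277.3):c.782G > A")
#' @export
variant_key <- function(x) {
  v <- if (is.data.frame(x)) x else parse_hgvs_c(x)
  sub("^.*:", "", format_hgvs(v))
}
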