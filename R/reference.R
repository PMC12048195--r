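# Gene model of the toy PAH-like reference. The CDS exon boundaries follow
# the 13-exon structure of the PAH transcript (1359 bp CDS), so that the
# intron-anchored variant positions seen in clinical reports (c.168+5,
# c.169-13, c.353-1, c.1066-11) fall at real exon edges. Introns, UTRs and
# flanks are toy-sized so the whole locus fits in ~31 kb.
toy_cds_ends <- c(60L, 168L, 352L, 441L, 509L, 706L, 842L, 912L, 969L,
                  1065L, 1199L, 1315L, 1359L)
toy_intron_lens <- c(1800L, 2500L, 2200L, 1900L, 3000L, 2600L, 2100L,
                     2400L, 2000L, 2700L, 2300L, 1700L)
toy_utr5_len <- 100L
toy_utr3_len <- 400L
toy_flank_len <- 1000L

#' Build the toy PAH-like annotated reference
#'
#' Generates a deterministic ~31 kb single-contig reference carrying a
#' 13-exon gene with the exon sizes of the PAH coding sequence (1359 bp
#' CDS), 5'/3' UTRs and toy-sized introns, on the plus strand. The
#' reference bases at the mapped positions of all variants in the packaged
#' cohort are set to those variants' reference alleles, so every cohort
#' variant lifts onto this genome consistently.
#'
#' @param seed Integer seed; the same seed always yields the byte-identical
#'   sequence.
#' @return An object of class `pah_reference`: a list with `contig`, `seq`
#'   (character scalar), `exons` (per-exon CDS and genomic coordinates,
#'   0-based half-open), `utr5`, `utr3`, and `length`.
#' @seealso [cds_to_genomic()], [genomic_to_cds()], [toy_targets()],
#'   [toy_panel()].
#' @export
build_toy_reference <- function(seed = 1L) {
  cds_start <- c(1L, head(toy_cds_ends, -1L) + 1L)
  cds_len <- toy_cds_ends - cds_start + 1L
  n <- length(cds_len)

  g_len <- cds_len
  g_len[1] <- g_len[1] + toy_utr5_len
  g_len[n] <- g_len[n] + toy_utr3_len
  g_start <- integer(n)
  g_start[1] <- toy_flank_len
  for (i in seq_len(n - 1L)) {
    g_start[i + 1L] <- g_start[i] + g_len[i] + toy_intron_lens[i]
  }
  g_end <- g_start + g_len

  total <- g_end[n] + toy_flank_len
  bases <- with_preserved_seed(seed, {
    sample(c("A", "C", "G", "T"), total, replace = TRUE)
  })

  exons <- tibble(
    exon = seq_len(n),
    cds_start = cds_start,
    cds_end = toy_cds_ends,
    g_start = g_start,
    g_end = g_end,
    # genomic position (0-based) of the first CDS base of the exon
    g_cds_start = g_start + ifelse(seq_len(n) == 1L, toy_utr5_len, 0L)
  )

  ref <- structure(
    list(
      contig = "toyPAH",
      seq = "",
      exons = exons,
      utr5 = c(start = g_start[1], end = g_start[1] + toy_utr5_len),
      utr3 = c(start = g_end[n] - toy_utr3_len, end = g_end[n]),
      length = total
    ),
    class = "pah_reference"
  )

  # Plant the reference alleles of the packaged cohort's variants.
  vars <- parse_hgvs_c(unique(pku_cohort()$variant))
  for (i in seq_len(nrow(vars))) {
    if (vars$kind[i] == "substitution") {
      pos <- cds_to_genomic(ref, vars$start_pos[i], vars$start_offset[i])
      bases[pos + 1L] <- vars$ref_allele[i]
    }
  }
  ref$seq <- paste(bases, collapse = "")
  ref
}

#' @export
print.pah_reference <- function(x, ...) {
  cat("<pah_reference> contig", x$contig, "-", x$length, "bp,",
      nrow(x$exons), "exons, CDS", max(x$exons$cds_end), "bp\n")
  invisible(x)
}

#' Map CDS coordinates (with intronic offsets) to genomic positions
#'
#' Converts 1-based coding positions, optionally carrying a signed intronic
#' offset (`c.168+5` is offset `+5` from CDS position 168; `c.1066-11` is
#' offset `-11` from position 1066), to 0-based genomic positions on the
#' toy reference. Positions outside the annotated CDS, or offsets that run
#' past the adjacent intron, are lift errors.
#'
#' @param ref A `pah_reference`.
#' @param pos Integer vector of CDS positions (1-based).
#' @param offset Integer vector of intronic offsets (0 when exonic).
#' @return Integer vector of 0-based genomic positions.
#' @export
cds_to_genomic <- function(ref, pos, offset = 0L) {
  n <- max(length(pos), length(offset))
  pos <- rep_len(as.integer(pos), n)
  offset <- rep_len(as.integer(offset), n)
  ex <- ref$exons
  out <- integer(n)
  for (i in seq_len(n)) {
    j <- which(ex$cds_start <= pos[i] & pos[i] <= ex$cds_end)
    if (!length(j)) {
      abort(paste0("CDS position ", pos[i], " is outside the annotated transcript"))
    }
    g <- ex$g_cds_start[j] + (pos[i] - ex$cds_start[j]) + offset[i]
    if (offset[i] > 0L) {
      nxt <- if (j < nrow(ex)) ex$g_start[j + 1L] else ref$length
      if (g >= nxt) abort(paste0("offset +", offset[i], " from c.", pos[i],
                                 " runs past the downstream exon"))
    } else if (offset[i] < 0L) {
      prv <- if (j > 1L) ex$g_end[j - 1L] else 0L
      if (g < prv) abort(paste0("offset ", offset[i], " from c.", pos[i],
                                " runs past the upstream exon"))
    }
    out[i] <- g
  }
  out
}

#' Map genomic positions back to CDS coordinates
#'
#' Inverse of [cds_to_genomic()]: exonic positions map to `(pos, 0)`;
#' intronic positions are expressed relative to the nearest exon edge (the
#' usual HGVS convention), giving a positive offset from the upstream
#' exon's last CDS base or a negative offset from the downstream exon's
#' first CDS base.
#'
#' @param ref A `pah_reference`.
#' @param g Integer vector of 0-based genomic positions.
#' @return Tibble with columns `pos` and `offset`.
#' @export
genomic_to_cds <- function(ref, g) {
  ex <- ref$exons
  n <- length(g)
  pos <- integer(n); offset <- integer(n)
  for (i in seq_len(n)) {
    j <- which(ex$g_cds_start <= g[i] &
                 g[i] < ex$g_cds_start + (ex$cds_end - ex$cds_start + 1L))
    if (length(j)) {
      pos[i] <- ex$cds_start[j] + (g[i] - ex$g_cds_start[j])
      offset[i] <- 0L
      next
    }
    k <- which(head(ex$g_end, -1L) <= g[i] & g[i] < ex$g_start[-1])
    if (!length(k)) {
      abort(paste0("genomic position ", g[i], " is not within the transcript's ",
                   "CDS exons or introns"))
    }
    d_don <- g[i] - (ex$g_end[k] - 1L)            # distance past exon k's last base
    d_acc <- ex$g_start[k + 1L] - g[i]            # distance before exon k+1's first base
    if (d_don <= d_acc) {
      pos[i] <- ex$cds_end[k]
      offset[i] <- d_don
    } else {
      pos[i] <- ex$cds_start[k + 1L]
      offset[i] <- -d_acc
    }
  }
  tibble(pos = pos, offset = offset)
}

#' Target regions of the toy panel
#'
#' Enumerates the intervals the amplicon panel must cover: the 13 exon
#' bodies, both UTRs, a +/- `flank` bp window across every exon-intron
#' junction, and one-base targets at each intronic variant position of the
#' packaged cohort (deep-intronic reported sites). Coordinates are 0-based
#' half-open.
#'
#' @param ref A `pah_reference`.
#' @param flank Junction flank width in bp on each side (default 25).
#' @return Tibble with columns `contig`, `start`, `end`, `kind`.
#' @export
toy_targets <- function(ref, flank = 25L) {
  ex <- ref$exons
  n <- nrow(ex)
  exons <- tibble(contig = ref$contig, start = ex$g_start, end = ex$g_end,
                  kind = "exon")
  utrs <- tibble(
    contig = ref$contig,
    start = c(ref$utr5[["start"]], ref$utr3[["start"]]),
    end = c(ref$utr5[["end"]], ref$utr3[["end"]]),
    kind = c("utr5", "utr3")
  )
  donors <- tibble(contig = ref$contig, start = ex$g_end[-n] - flank,
                   end = ex$g_end[-n] + flank, kind = "junction_flank")
  acceptors <- tibble(contig = ref$contig, start = ex$g_start[-1] - flank,
                      end = ex$g_start[-1] + flank, kind = "junction_flank")

  vars <- parse_hgvs_c(unique(pku_cohort()$variant))
  intronic <- vars[vars$start_offset != 0L, ]
  deep <- tibble(
    contig = ref$contig,
    start = cds_to_genomic(ref, intronic$start_pos, intronic$start_offset),
    kind = "deep_intronic_site"
  )
  deep$end <- deep$start + 1L

  dplyr::bind_rows(exons, utrs, donors, acceptors,
                   deep[c("contig", "start", "end", "kind")]) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Write the reference as FASTA
#'
#' @param ref A `pah_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(setNames(ref$seq, ref$contig))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read/write BED interval files
#'
#' Minimal BED3/BED4 support (0-based half-open, tab-separated, no track
#' lines), the interchange convention used for target and amplicon
#' intervals.
#'
#' @param x Tibble with columns `contig`, `start`, `end` and optionally a
#'   fourth name column (`kind`, `name` or `pair`).
#' @param path File path.
#' @return `read_bed()` returns a tibble with columns `contig`, `start`,
#'   `end` (+ `name` when present); `write_bed()` returns `path` invisibly.
#' @export
write_bed <- function(x, path) {
  name_col <- intersect(c("name", "kind", "pair"), names(x))[1]
  out <- x[c("contig", "start", "end")]
  if (!is.na(name_col)) out$name <- x[[name_col]]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE)
  if (ncol(x) < 3) abort("BED file must have at least 3 columns")
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$start >= x$end)) abort("BED intervals must satisfy start < end")
  as_tibble(x[, 1:min(4, ncol(x))])
}
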