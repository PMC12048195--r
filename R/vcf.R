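#' Lift coding-coordinate variants onto the toy reference
#'
#' Maps parsed `c.` variants to genomic coordinates on a `pah_reference`
#' and derives VCF-style `POS`/`REF`/`ALT` fields: substitutions are
#' reported at their own base; deletions are left-anchored on the preceding
#' base so that `REF` spans the anchor plus the deleted bases and `ALT` is
#' the anchor (the VCF convention for length-changing events). Variants
#' outside the annotated transcript raise a lift error.
#'
#' @param variants Character vector of HGVS strings or a tibble from
#'   [parse_hgvs_c()].
#' @param reference A `pah_reference`.
#' @return Tibble with `hgvs`, `key`, `contig`, `pos` (1-based VCF
#'   position), `ref`, `alt`.
#' @export
lift_variants <- function(variants, reference) {
  v <- if (is.data.frame(variants)) variants else parse_hgvs_c(variants)
  ref_chars <- strsplit(reference$seq, "")[[1]]
  n <- nrow(v)
  pos <- integer(n); REF <- character(n); ALT <- character(n)
  for (i in seq_len(n)) {
    g_start <- cds_to_genomic(reference, v$start_pos[i], v$start_offset[i])
    if (v$kind[i] == "substitution") {
      pos[i] <- g_start + 1L
      REF[i] <- ref_chars[g_start + 1L]
      ALT[i] <- v$alt_allele[i]
      if (nzchar(v$ref_allele[i]) && v$ref_allele[i] != REF[i]) {
        abort(paste0("reference allele mismatch for ", v$hgvs[i], ": reference has ",
                     REF[i], " at lifted position ", pos[i]))
      }
    } else {
      g_end <- cds_to_genomic(reference, v$end_pos[i], v$end_offset[i])
      anchor <- g_start            # 1-based position of the base before the event
      pos[i] <- anchor
      REF[i] <- paste(ref_chars[anchor:(g_end + 1L)], collapse = "")
      ALT[i] <- if (v$kind[i] == "delins") {
        paste0(ref_chars[anchor], v$alt_allele[i])
      } else {
        ref_chars[anchor]
      }
    }
  }
  tibble(hgvs = v$hgvs, key = variant_key(v), contig = reference$contig,
         pos = pos, ref = REF, alt = ALT)
}

#' Write variant calls as minimal VCF 4.2
#'
#' Produces a header (fileformat, contig, INFO definitions for read depth
#' `DP` and allele fraction `AF`) and one data line per call, ordered by
#' position. An empty call set yields a header-only VCF.
#'
#' @param calls Tibble with a `variant` column of HGVS strings and
#'   optionally `depth` and `allele_fraction`.
#' @param reference A `pah_reference`.
#' @param path Optional output path; when given the lines are written
#'   there.
#' @return Character vector of VCF lines, invisibly when `path` is given.
#' @export
write_vcf <- function(calls, reference, path = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", reference$contig, ",length=", reference$length, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Observed allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (is.null(calls) || nrow(calls) == 0) {
    lines <- header
  } else {
    lifted <- lift_variants(calls$variant, reference)
    info <- rep(".", nrow(lifted))
    has_dp <- "depth" %in% names(calls)
    has_af <- "allele_fraction" %in% names(calls)
    if (has_dp || has_af) {
      parts <- cbind(
        if (has_dp) paste0("DP=", calls$depth) else NULL,
        if (has_af) paste0("AF=", format(calls$allele_fraction, trim = TRUE)) else NULL
      )
      info <- apply(parts, 1, paste, collapse = ";")
    }
    body <- tibble(
      chrom = lifted$contig, pos = lifted$pos, id = lifted$key,
      ref = lifted$ref, alt = lifted$alt, qual = ".", filter = ".", info = info
    )
    body <- dplyr::arrange(body, .data$pos, .data$ref, .data$alt)
    lines <- c(header, do.call(paste, c(as.list(body), sep = "\t")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
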