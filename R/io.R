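#' Write tRNA references as FASTA
#'
#' Writes one `mature` record per locus (header
#' `>id mature anticodon_start=N`) and, when a trailer is present, one
#' `precursor` record holding mature-without-CCA plus the 3' trailer.
#'
#' @param refs tibble from [make_trna_reference()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_trna_fasta <- function(refs, path) {
  seqs <- character(0)
  for (i in seq_len(nrow(refs))) {
    r <- refs[i, ]
    hdr <- paste0(r$id, " mature")
    if (!is.na(r$anticodon_start)) {
      hdr <- paste0(hdr, " anticodon_start=", r$anticodon_start)
    }
    seqs[hdr] <- r$mature_seq
    if (nchar(r$trailer_seq) > 0) {
      pre <- paste0(
        substr(r$mature_seq, 1, nchar(r$mature_seq) - 3), r$trailer_seq
      )
      seqs[paste0(r$id, " precursor")] <- pre
    }
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read tRNA references from FASTA
#'
#' Inverse of [write_trna_fasta()]: pairs `mature` and `precursor` records by
#' id and recovers the trailer as the precursor suffix beyond the CCA-less
#' mature body.
#'
#' @param path FASTA path.
#' @return tibble in the [make_trna_reference()] layout.
#' @export
read_trna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  parts <- strsplit(hdr, "\\s+")
  ids <- vapply(parts, `[`, character(1), 1)
  kind <- vapply(parts, `[`, character(1), 2)
  ac <- vapply(parts, function(p) {
    m <- grep("^anticodon_start=", p, value = TRUE)
    if (length(m)) as.integer(sub("anticodon_start=", "", m)) else NA_integer_
  }, integer(1))
  mature_idx <- which(kind == "mature")
  purrr::map_dfr(mature_idx, function(i) {
    id <- ids[i]
    mature <- as.character(x[[i]])
    pre_i <- which(ids == id & kind == "precursor")
    trailer <- if (length(pre_i)) {
      substr(as.character(x[[pre_i[1]]]), nchar(mature) - 2, .Machine$integer.max)
    } else {
      ""
    }
    iso_ac <- strsplit(id, "-")[[1]]
    tibble::tibble(
      id = id, isotype = iso_ac[1],
      anticodon = if (length(iso_ac) > 1) iso_ac[2] else NA_character_,
      mature_seq = mature, trailer_seq = trailer, anticodon_start = ac[i]
    )
  })
}

#' Write reads as FASTQ (constant quality)
#'
#' @param reads tibble (`read_id`, `seq`).
#' @param path output path.
#' @param quality_char Phred+33 quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
  xq <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(q)
  )
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path reads file; format inferred from extension
#'   (`.fq`/`.fastq` vs anything else).
#' @return tibble (`read_id`, `seq`).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(
    read_id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1),
    seq = as.character(x)
  )
}

#' Write a named sequence tibble as FASTA
#'
#' @param seqs tibble with an id column and a `seq` column.
#' @param path output path.
#' @param id_col name of the id column.
#' @return `path`, invisibly.
#' @export
write_seq_fasta <- function(seqs, path, id_col = 1L) {
  ids <- seqs[[id_col]]
  x <- Biostrings::DNAStringSet(stats::setNames(gsub("U", "T", seqs$seq), ids))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a UTR (or generic) FASTA into a tibble
#'
#' @param path FASTA path.
#' @param id_col name for the id column.
#' @return tibble (`<id_col>`, `seq`). Duplicate ids are an error.
#' @export
read_seq_fasta <- function(path, id_col = "utr_id") {
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate sequence ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(id = ids, seq = as.character(x))
  names(out)[1] <- id_col
  out
}

#' Read an expression matrix TSV
#'
#' Expects the feature id in column 1 and one column per sample; sample
#' group is carried by the `_ctrl`/`_trt` header suffix.
#'
#' @param path TSV path.
#' @return tibble with `feature_id` first.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "feature_id"
  out
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of gene symbol vectors.
#' @param path output path.
#' @param description second-column description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Thin wrapper over [fgsea::gmtPathways()]; the term id doubles as the term
#' name (GMT description column is not retained).
#'
#' @param path GMT path.
#' @return named list of gene symbol vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
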