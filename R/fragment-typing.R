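#' Trim a 3' adapter from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter with at least `min_overlap` bases; at most one trim per read.
#' Reads shorter than `min_overlap` (or empty) are returned unchanged.
#'
#' @param read character vector of read sequences.
#' @param adapter adapter sequence (5'->3', as ligated).
#' @param min_overlap minimum exact overlap (>= 1).
#' @return character vector of trimmed reads.
#' @export
#' @examples
#' trim_adapter("ACGTACGTTGGAA", "TGGAATTCTCGG", min_overlap = 5)
trim_adapter <- function(read, adapter, min_overlap = 5L) {
  stopifnot(min_overlap >= 1)
  na <- nchar(adapter)
  vapply(read, function(r) {
    n <- nchar(r)
    if (n == 0 || n < min_overlap) return(r)
    for (k in seq(min(n, na), min_overlap)) {
      if (substr(r, n - k + 1, n) == substr(adapter, 1, k)) {
        return(substr(r, 1, n - k))
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

fragment_classes <- function() {
  c("tRF-5", "tRF-3", "tRF-1", "i-tRF", "tiRNA-5", "tiRNA-3")
}

#' Align reads to mature and precursor tRNA sequences
#'
#' Ungapped full-read alignment against each reference's mature sequence and
#' 3' trailer. The best hit per read minimises (mismatches, compartment with
#' mature before trailer, start, ref id) lexicographically, making multi-hit
#' resolution deterministic.
#'
#' @param reads tibble (`read_id`, `seq`) or character vector of sequences.
#' @param refs tibble from [make_trna_reference()].
#' @param max_mismatch maximum mismatches allowed (default 0: fragments are
#'   exact subsequences of their source tRNA by definition).
#' @return tibble (`read_id`, `ref_id`, `compartment`, `start`, `end`,
#'   `mismatches`); unmapped reads are absent and listed in the
#'   `"unmapped"` attribute. Coordinates are 0-based half-open on the mature
#'   sequence or on the trailer.
#' @export
align_to_trna <- function(reads, refs, max_mismatch = 0L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = sprintf("read_%05d", seq_along(reads)), seq = reads
    )
  }
  mature <- Biostrings::DNAStringSet(stats::setNames(refs$mature_seq, refs$id))
  has_trailer <- nchar(refs$trailer_seq) > 0
  trailer <- Biostrings::DNAStringSet(
    stats::setNames(refs$trailer_seq[has_trailer], refs$id[has_trailer])
  )
  # exact matching (the default) is plain substring search; the Biostrings
  # path below is only needed when mismatches are allowed
  hit_exact <- function(read_id, seq) {
    if (nchar(seq) < 14 || grepl("[^ACGT]", seq)) return(NULL)
    for (comp in c("mature", "trailer")) {
      subj <- if (comp == "mature") refs$mature_seq else refs$trailer_seq
      pos <- regexpr(seq, subj, fixed = TRUE)
      found <- which(pos > 0)
      if (length(found)) {
        starts <- as.integer(pos[found]) - 1L
        best <- order(starts, refs$id[found])[1]
        return(tibble::tibble(
          read_id = read_id, ref_id = refs$id[found[best]],
          compartment = comp, start = starts[best],
          end = starts[best] + nchar(seq), mismatches = 0L
        ))
      }
    }
    NULL
  }
  hit_one <- function(read_id, seq) {
    if (nchar(seq) < 14 || grepl("[^ACGT]", seq)) return(NULL)
    pat <- Biostrings::DNAString(seq)
    collect <- function(set, compartment) {
      if (length(set) == 0) return(NULL)
      m <- Biostrings::vmatchPattern(pat, set, max.mismatch = max_mismatch)
      idx <- which(S4Vectors::elementNROWS(m) > 0)
      if (length(idx) == 0) return(NULL)
      purrr::map_dfr(idx, function(i) {
        st <- BiocGenerics::start(m[[i]])
        mm <- vapply(st, function(s) {
          Biostrings::neditStartingAt(pat, set[[i]], starting.at = s)
        }, integer(1))
        tibble::tibble(
          ref_id = names(set)[i], compartment = compartment,
          start = st - 1L, mismatches = mm
        )
      })
    }
    hits <- dplyr::bind_rows(
      collect(mature, "mature"), collect(trailer, "trailer")
    )
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    hits <- dplyr::arrange(
      hits, .data$mismatches,
      factor(.data$compartment, levels = c("mature", "trailer")),
      .data$start, .data$ref_id
    )[1, ]
    tibble::tibble(
      read_id = read_id, ref_id = hits$ref_id,
      compartment = hits$compartment, start = hits$start,
      end = hits$start + nchar(seq), mismatches = hits$mismatches
    )
  }
  finder <- if (max_mismatch == 0) hit_exact else hit_one
  out <- purrr::map2(reads$read_id, reads$seq, finder)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      read_id = character(), ref_id = character(), compartment = character(),
      start = integer(), end = integer(), mismatches = integer()
    )
  }
  attr(res, "unmapped") <- setdiff(reads$read_id, res$read_id)
  res
}

#' Classify aligned fragments into the six tRF/tiRNA classes
#'
#' Applies the positional rule table, first match wins:
#' \enumerate{
#'   \item trailer compartment, start 0: tRF-1 (precursor trailer product)
#'   \item mature, start 0, 16-28 nt: tRF-5
#'   \item mature, ends at (or within `cca_slack` of) the mature 3' end,
#'     16-28 nt: tRF-3
#'   \item mature, start 0, 29-50 nt: tiRNA-5
#'   \item mature, 3'-anchored as in rule 3, 29-50 nt: tiRNA-3
#'   \item mature, strictly internal: i-tRF
#'   \item otherwise unclassified
#' }
#' The `cca_slack` (default 1 nt) tolerates 3' trimming variability of the
#' CCA terminus. When `check_anticodon = TRUE` and the reference carries
#' `anticodon_start`, tiRNA calls additionally require the cut site to fall
#' in the anticodon loop (`[anticodon_start - 3, anticodon_start + 6)`);
#' halves failing the check fall through to i-tRF/unclassified.
#'
#' @param hits tibble from [align_to_trna()].
#' @param refs reference tibble.
#' @param cca_slack nt of slack at the mature 3' terminus.
#' @param check_anticodon enforce the anticodon-loop cut for tiRNAs.
#' @return `hits` with added `length`, `fragment_class`, `name` columns.
#' @export
classify_fragment <- function(hits, refs, cca_slack = 1L,
                              check_anticodon = FALSE) {
  ref_len <- stats::setNames(nchar(refs$mature_seq), refs$id)
  trailer_len <- stats::setNames(nchar(refs$trailer_seq), refs$id)
  ac_start <- stats::setNames(refs$anticodon_start, refs$id)
  n <- nrow(hits)
  cls <- character(n)
  for (i in seq_len(n)) {
    h <- hits[i, ]
    L <- h$end - h$start
    comp_len <- if (h$compartment == "mature") {
      ref_len[[h$ref_id]]
    } else {
      trailer_len[[h$ref_id]]
    }
    if (h$start < 0 || h$end > comp_len) {
      stop("hit coordinates outside reference ", h$ref_id, call. = FALSE)
    }
    mlen <- ref_len[[h$ref_id]]
    at_3p <- h$compartment == "mature" && h$end >= mlen - cca_slack
    ac <- ac_start[[h$ref_id]]
    in_loop <- function(pos) {
      !check_anticodon || is.na(ac) || (pos >= ac - 3 && pos < ac + 6)
    }
    cls[i] <- if (h$compartment == "trailer" && h$start == 0) {
      "tRF-1"
    } else if (h$compartment == "mature" && h$start == 0 && L >= 16 && L <= 28) {
      "tRF-5"
    } else if (at_3p && L >= 16 && L <= 28) {
      "tRF-3"
    } else if (h$compartment == "mature" && h$start == 0 && L >= 29 && L <= 50 &&
      in_loop(h$end)) {
      "tiRNA-5"
    } else if (at_3p && L >= 29 && L <= 50 && in_loop(h$start)) {
      "tiRNA-3"
    } else if (h$compartment == "mature" && h$start > 0 && h$end < mlen) {
      "i-tRF"
    } else {
      "unclassified"
    }
  }
  dplyr::mutate(hits,
    length = .data$end - .data$start,
    fragment_class = cls,
    name = name_fragment(cls, .data$ref_id)
  )
}

#' Standard fragment names
#'
#' Maps a fragment class and reference id to the conventional name, e.g.
#' `("tRF-3", "Thr-AGT")` becomes `"tRF3-Thr-AGT"` and
#' `("i-tRF", "Met-CAT")` becomes `"i-tRF-Met-CAT"`.
#'
#' @param fragment_class character vector of classes.
#' @param ref_id character vector of reference ids.
#' @return character vector of names.
#' @export
name_fragment <- function(fragment_class, ref_id) {
  prefix <- c(
    "tRF-5" = "tRF5", "tRF-3" = "tRF3", "tRF-1" = "tRF1",
    "i-tRF" = "i-tRF", "tiRNA-5" = "tiRNA5", "tiRNA-3" = "tiRNA3",
    "unclassified" = "unclassified"
  )
  bad <- setdiff(unique(fragment_class), names(prefix))
  if (length(bad)) stop("unknown fragment class: ", bad[1], call. = FALSE)
  paste0(prefix[fragment_class], "-", ref_id)
}

#' Trim, align and classify reads in one call
#'
#' @param reads tibble (`read_id`, `seq`).
#' @param refs reference tibble.
#' @param adapter optional 3' adapter to trim first.
#' @param min_overlap adapter trimming overlap.
#' @param max_mismatch alignment mismatch budget.
#' @param min_len reads shorter than this after trimming are dropped to the
#'   unmapped log (alignment requires >= 14 nt).
#' @inheritParams classify_fragment
#' @return FragmentCall tibble (`read_id`, `ref_id`, `compartment`, `start`,
#'   `end`, `mismatches`, `length`, `fragment_class`, `name`), with unmapped
#'   read ids in the `"unmapped"` attribute.
#' @export
classify_reads <- function(reads, refs, adapter = NULL, min_overlap = 5L,
                           max_mismatch = 0L, cca_slack = 1L,
                           check_anticodon = FALSE, min_len = 14L) {
  if (!is.null(adapter)) {
    reads <- dplyr::mutate(reads, seq = trim_adapter(.data$seq, adapter, min_overlap))
  }
  keep <- nchar(reads$seq) >= min_len
  hits <- align_to_trna(reads[keep, ], refs, max_mismatch = max_mismatch)
  calls <- classify_fragment(hits, refs,
    cca_slack = cca_slack, check_anticodon = check_anticodon
  )
  attr(calls, "unmapped") <- c(reads$read_id[!keep], attr(hits, "unmapped"))
  calls
}

#' Fragment-class distribution
#'
#' Per-class read counts and fractions, overall or per source tRNA.
#' Unclassified reads are excluded from the denominator and reported in a
#' separate row with `fraction = NA`.
#'
#' @param calls FragmentCall tibble.
#' @param weights optional numeric read counts (per call row); default 1.
#' @param by_ref also split by `ref_id`.
#' @return tibble (`ref_id` if `by_ref`, `fragment_class`, `count`,
#'   `fraction`).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   read_id = c("a", "b"), ref_id = "Thr-AGT",
#'   fragment_class = c("tRF-3", "tRF-5")
#' )
#' type_distribution(calls)
type_distribution <- function(calls, weights = NULL, by_ref = FALSE) {
  if (nrow(calls) == 0) stop("no fragment calls supplied", call. = FALSE)
  w <- weights %||% rep(1, nrow(calls))
  stopifnot(length(w) == nrow(calls))
  calls <- dplyr::mutate(calls, .w = w)
  keys <- if (by_ref) c("ref_id", "fragment_class") else "fragment_class"
  counts <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(count = sum(.data$.w), .groups = "drop_last")
  counts |>
    dplyr::mutate(
      fraction = ifelse(
        .data$fragment_class == "unclassified", NA_real_,
        .data$count / sum(.data$count[.data$fragment_class != "unclassified"])
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}
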