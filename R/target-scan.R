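#' Scoring parameters for the target-site scanner
#'
#' Constants for the seed-weighted local duplex score, following the
#' published miRanda-3.3a defaults: Watson-Crick match +5, G:U wobble +2,
#' mismatch -3, affine gaps (open -9, extend -4), positions 2-8 from the
#' sncRNA 5' end (the seed) scaled by 4, and sites kept only when their
#' score strictly exceeds 140. The seed scale multiplies every score
#' contribution at a seed position - substitutions and gap penalties alike -
#' as in miRanda. These constants are the single source of truth for all
#' scoring in the package.
#'
#' @param match,wobble,mismatch per-position pairing scores.
#' @param gap_open,gap_extend affine gap penalties (negative; scaled by the
#'   seed weight inside the seed).
#' @param seed_from,seed_to 1-based positions (sncRNA 5' end) of the seed.
#' @param seed_weight multiplier applied at seed positions.
#' @param threshold minimum reported site score (strict inequality).
#' @return list of class `scan_params`.
#' @export
scan_params <- function(match = 5, wobble = 2, mismatch = -3,
                        gap_open = -9, gap_extend = -4,
                        seed_from = 2L, seed_to = 8L, seed_weight = 4,
                        threshold = 140) {
  stopifnot(match > 0, gap_open <= 0, gap_extend <= 0, seed_weight >= 1,
    seed_from >= 1, seed_to >= seed_from)
  structure(
    list(
      match = match, wobble = wobble, mismatch = mismatch,
      gap_open = gap_open, gap_extend = gap_extend,
      seed_from = as.integer(seed_from), seed_to = as.integer(seed_to),
      seed_weight = seed_weight, threshold = threshold
    ),
    class = "scan_params"
  )
}

encode_seq <- function(seq, what) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)
  bad <- setdiff(unique(chars), names(code))
  if (length(bad)) {
    stop(
      what, " contains non-ACGTU characters: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  unname(code[chars])
}

#' Scan one 3'UTR for sncRNA binding sites
#'
#' Aligns the reversed sncRNA (3'->5') against the UTR (5'->3') with a local
#' affine-gap alignment scored by complementarity, seed positions weighted
#' per [scan_params()]. All non-overlapping sites scoring strictly above the
#' threshold are returned best-first; overlaps are resolved greedily by
#' score, ties to the leftmost site.
#'
#' @param sncrna sncRNA sequence, 5'->3' (RNA or DNA alphabet, 15-50 nt).
#' @param utr UTR sequence, 5'->3' (DNA or RNA); must be at least as long as
#'   the sncRNA.
#' @param params a [scan_params()].
#' @return tibble (`utr_start`, `utr_end`, `score`, `pairing`); coordinates
#'   0-based half-open on the UTR; `pairing` lists paired positions as
#'   `sncrna_pos:utr_pos` (sncRNA 1-based from its 5' end, UTR 0-based).
#' @export
#' @examples
#' snc <- "AUCCCAGCGGUGCCUCC"
#' site <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(gsub("U", "T", snc))
#' ))
#' utr <- paste0(strrep("A", 20), site, strrep("A", 20))
#' scan_utr(snc, utr)
scan_utr <- function(sncrna, utr, params = scan_params()) {
  q <- encode_seq(sncrna, "sncRNA")
  s <- encode_seq(utr, "UTR")
  L <- length(q)
  if (L < 15 || L > 50) {
    stop("sncRNA length must be in [15, 50], got ", L, call. = FALSE)
  }
  if (length(s) < L) {
    stop("UTR (", length(s), " nt) shorter than sncRNA (", L, " nt)",
      call. = FALSE
    )
  }
  w <- ifelse(
    seq_len(L) >= params$seed_from & seq_len(L) <= params$seed_to,
    params$seed_weight, 1
  )
  # query is reversed: position i of the reversed query is original L - i + 1
  res <- sw_scan_sites(
    rev(q), s, rev(w),
    params$match, params$wobble, params$mismatch,
    params$gap_open, params$gap_extend, params$threshold
  )
  tibble::as_tibble(res)
}

#' Predict sncRNA targets across a UTR collection
#'
#' Scans every differentially expressed sncRNA against every UTR and keeps
#' one row per (sncRNA, mRNA) pair with at least one site above threshold,
#' retaining the best site score.
#'
#' @param de_sncrna [de_test()] tibble for the sncRNA class (only `up`/`down`
#'   features are scanned).
#' @param sncrna_seqs tibble (`feature_id`, `seq`).
#' @param utrs tibble (`utr_id`, `seq`); duplicate ids are an error.
#' @param params a [scan_params()].
#' @return tibble (`sncrna_id`, `utr_id`, `best_score`, `n_sites`).
#' @export
predict_targets <- function(de_sncrna, sncrna_seqs, utrs,
                            params = scan_params()) {
  if (anyDuplicated(utrs$utr_id)) {
    stop(
      "duplicate UTR ids: ",
      paste(unique(utrs$utr_id[duplicated(utrs$utr_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  de <- dplyr::filter(de_sncrna, .data$direction %in% c("up", "down"))
  scanned <- dplyr::inner_join(
    dplyr::select(de, "feature_id"), sncrna_seqs,
    by = "feature_id"
  )
  missing_seq <- setdiff(de$feature_id, scanned$feature_id)
  if (length(missing_seq)) {
    warning(
      length(missing_seq), " DE sncRNA(s) lack a sequence and were skipped",
      call. = FALSE
    )
  }
  if (nrow(scanned) == 0 || nrow(utrs) == 0) {
    return(tibble::tibble(
      sncrna_id = character(), utr_id = character(),
      best_score = numeric(), n_sites = integer()
    ))
  }
  rows <- purrr::map(seq_len(nrow(scanned)), function(i) {
    snc_id <- scanned$feature_id[i]
    snc <- scanned$seq[i]
    hits <- purrr::map(seq_len(nrow(utrs)), function(j) {
      sites <- scan_utr(snc, utrs$seq[j], params)
      if (nrow(sites) == 0) return(NULL)
      tibble::tibble(
        sncrna_id = snc_id, utr_id = utrs$utr_id[j],
        best_score = max(sites$score), n_sites = nrow(sites)
      )
    })
    dplyr::bind_rows(hits)
  })
  dplyr::bind_rows(rows)
}
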