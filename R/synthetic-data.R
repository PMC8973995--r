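#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: a two-group comparison of stimulated vs
#' untreated acinar cells with three replicates per group, small-RNA reads
#' drawn from all six tRF/tiRNA classes, and planted differential-expression
#' structure (172 up / 34 down mRNAs, 11/24 miRNAs, 4/16 tRF/tiRNAs).
#'
#' @param seed single integer; one global seed governs all generators, each
#'   operation deriving its own sub-seed deterministically.
#' @param n_trnas number of tRNA reference loci to simulate.
#' @param trailer_len length (nt) of each precursor 3' trailer.
#' @param n_features named integer vector: features per expression class,
#'   names `mRNA`, `miRNA`, `tRF`.
#' @param group_sizes integer pair: replicates in (control, treated).
#' @param planted_up,planted_down named integer vectors (same names as
#'   `n_features`): how many features per class are planted up/down.
#' @param effect_fold treated/control mean ratio for planted-up features
#'   (reciprocal for planted-down); must exceed 1.
#' @param noise_cv within-group coefficient of variation of expression.
#' @param reads_per_class simulated reads per fragment class.
#' @param site_plant_rate fraction of DE-mRNA 3'UTRs that receive a perfectly
#'   complementary target site.
#' @param utr_len simulated 3'UTR length (nt).
#' @param adapter optional 3' adapter sequence appended to simulated reads
#'   (for exercising adapter trimming); `NULL` for none.
#'
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, n_trnas = 5, reads_per_class = 10)
#' cfg$group_sizes
simulation_config <- function(seed = 1L,
                              n_trnas = 20L,
                              trailer_len = 30L,
                              n_features = c(mRNA = 2000L, miRNA = 300L, tRF = 150L),
                              group_sizes = c(3L, 3L),
                              planted_up = c(mRNA = 172L, miRNA = 11L, tRF = 4L),
                              planted_down = c(mRNA = 34L, miRNA = 24L, tRF = 16L),
                              effect_fold = 4,
                              noise_cv = 0.05,
                              reads_per_class = 100L,
                              site_plant_rate = 0.5,
                              utr_len = 200L,
                              adapter = NULL) {
  classes <- c("mRNA", "miRNA", "tRF")
  stopifnot(
    length(seed) == 1, is.finite(seed),
    all(classes %in% names(n_features)),
    all(classes %in% names(planted_up)),
    all(classes %in% names(planted_down))
  )
  n_features <- n_features[classes]
  planted_up <- planted_up[classes]
  planted_down <- planted_down[classes]
  if (any(group_sizes < 2)) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (any(planted_up + planted_down > n_features)) {
    stop("planted_up + planted_down exceeds n_features for some class",
      call. = FALSE
    )
  }
  if (effect_fold <= 1) stop("effect_fold must exceed 1", call. = FALSE)
  if (n_trnas < 0 || trailer_len < 0 || reads_per_class < 0 ||
    any(n_features < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (site_plant_rate < 0 || site_plant_rate > 1) {
    stop("site_plant_rate must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_trnas = as.integer(n_trnas),
      trailer_len = as.integer(trailer_len),
      n_features = as.integer(n_features) |> stats::setNames(classes),
      group_sizes = as.integer(group_sizes),
      planted_up = as.integer(planted_up) |> stats::setNames(classes),
      planted_down = as.integer(planted_down) |> stats::setNames(classes),
      effect_fold = effect_fold, noise_cv = noise_cv,
      reads_per_class = as.integer(reads_per_class),
      site_plant_rate = site_plant_rate, utr_len = as.integer(utr_len),
      adapter = adapter
    ),
    class = "simulation_config"
  )
}

# canonical isotype-anticodon pool (DNA sense anticodons, GtRNAdb-style ids)
trna_isotype_pool <- function() {
  tibble::tribble(
    ~isotype, ~anticodon,
    "Ala", "AGC", "Arg", "ACG", "Asn", "GTT", "Asp", "GTC", "Cys", "GCA",
    "Gln", "CTG", "Glu", "CTC", "Gly", "GCC", "His", "GTG", "Ile", "AAT",
    "Leu", "CAA", "Lys", "CTT", "Met", "CAT", "Phe", "GAA", "Pro", "AGG",
    "Ser", "AGA", "Thr", "AGT", "Trp", "CCA", "Tyr", "GTA", "Val", "AAC"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a set of tRNA reference loci
#'
#' Each locus carries a mature sequence (70-90 nt, ending in the
#' post-transcriptionally added CCA) with its anticodon at the canonical
#' position, and a precursor 3' trailer containing a poly-U run (encoded as
#' T in the DNA sense) within its first 25 nt, as expected for RNase-Z
#' products that give rise to tRF-1 fragments.
#'
#' @param config a [simulation_config()].
#' @return A tibble with columns `id`, `isotype`, `anticodon`, `mature_seq`,
#'   `trailer_seq`, `anticodon_start` (0-based offset of the anticodon on the
#'   mature sequence).
#' @export
#' @examples
#' refs <- make_trna_reference(simulation_config(seed = 1, n_trnas = 3))
#' refs$id
make_trna_reference <- function(config) {
  n <- config$n_trnas
  if (n == 0) {
    return(tibble::tibble(
      id = character(), isotype = character(), anticodon = character(),
      mature_seq = character(), trailer_seq = character(),
      anticodon_start = integer()
    ))
  }
  pool <- trna_isotype_pool()
  with_seed(derive_seed(config$seed, "trna_reference"), {
    idx <- rep_len(seq_len(nrow(pool)), n)
    rows <- purrr::map(seq_len(n), function(i) {
      iso <- pool$isotype[idx[i]]
      ac <- pool$anticodon[idx[i]]
      # cap at 88 nt so a 3' half cut in the anticodon loop stays <= 50 nt
      len <- sample(70:88, 1)
      ac_start <- 33L # 0-based: canonical positions 34-36
      seq <- random_dna(len)
      substr(seq, ac_start + 1, ac_start + 3) <- ac
      substr(seq, len - 2, len) <- "CCA"
      trailer <- random_dna(config$trailer_len)
      if (config$trailer_len >= 4) {
        upos <- sample(seq_len(max(1, min(25, config$trailer_len) - 3)), 1)
        substr(trailer, upos, upos + 3) <- "TTTT"
      }
      tibble::tibble(
        isotype = iso, anticodon = ac, mature_seq = seq,
        trailer_seq = trailer, anticodon_start = ac_start
      )
    })
    refs <- dplyr::bind_rows(rows)
    base_id <- paste0(refs$isotype, "-", refs$anticodon)
    # disambiguate repeated isotype-anticodon combinations GtRNAdb-style
    refs$id <- ifelse(duplicated(base_id) | duplicated(base_id, fromLast = TRUE),
      paste0(base_id, "-", stats::ave(base_id, base_id, FUN = seq_along)),
      base_id
    )
    dplyr::select(
      refs, "id", "isotype", "anticodon", "mature_seq", "trailer_seq",
      "anticodon_start"
    )
  })
}

#' A deterministic Thr-AGT tRNA whose 3' end carries the canonical tRF-3
#'
#' Builds a 76-nt mature threonine (anticodon AGT) tRNA whose final 18 nt are
#' `ATCCCAGCGGTGCCTCCA`: the last 17 nt before the terminal A spell the
#' fragment `ATCCCAGCGGTGCCTCC` (RNA `AUCCCAGCGGUGCCUCC`), so a 17-nt read of
#' that sequence ends one base short of the mature 3' terminus and is called
#' tRF-3 under the default 1-nt CCA slack.
#'
#' @param trailer_len precursor trailer length (nt).
#' @return One-row tibble in the [make_trna_reference()] layout.
#' @export
#' @examples
#' ref <- trna_thr_agt()
#' substr(ref$mature_seq, 60, 76)
trna_thr_agt <- function(trailer_len = 30L) {
  tail18 <- "ATCCCAGCGGTGCCTCCA"
  with_seed(derive_seed(760L, "thr_agt"), {
    prefix <- random_dna(76 - nchar(tail18))
    substr(prefix, 34, 36) <- "AGT"
    trailer <- random_dna(trailer_len)
    if (trailer_len >= 4) substr(trailer, 3, 6) <- "TTTT"
    tibble::tibble(
      id = "Thr-AGT", isotype = "Thr", anticodon = "AGT",
      mature_seq = paste0(prefix, tail18), trailer_seq = trailer,
      anticodon_start = 33L
    )
  })
}

# per-class sampling windows for fragment simulation; returns NULL when the
# reference cannot host the class
class_window <- function(class, ref, cca_slack = 1L) {
  n <- nchar(ref$mature_seq)
  ac <- ref$anticodon_start
  switch(class,
    "tRF-5" = list(compartment = "mature", start = 0L, len = 16:28),
    "tRF-3" = list(compartment = "mature", end = n, len = 16:28),
    "tRF-1" = {
      if (nchar(ref$trailer_seq) < 16) {
        NULL
      } else {
        list(
          compartment = "trailer", start = 0L,
          len = 16:min(28, nchar(ref$trailer_seq))
        )
      }
    },
    "i-tRF" = list(compartment = "mature", internal = TRUE, len = 16:28),
    "tiRNA-5" = {
      # cut in the anticodon loop: end coordinate in [ac-3, ac+6)
      lens <- intersect(29:50, (ac - 3):(ac + 5))
      if (length(lens) == 0) NULL else {
        list(compartment = "mature", start = 0L, len = lens)
      }
    },
    "tiRNA-3" = {
      starts <- intersect((ac - 3):(ac + 5), (n - 50):(n - 29))
      if (length(starts) == 0) NULL else {
        list(compartment = "mature", end = n, starts = starts)
      }
    },
    stop("unknown fragment class: ", class, call. = FALSE)
  )
}

#' Simulate classified small-RNA reads from tRNA references
#'
#' Draws reads per fragment class obeying that class's positional rule and
#' length window exactly: tRF-5 anchored at the mature 5' end (16-28 nt),
#' tRF-3 at the mature 3' end, tRF-1 at position 0 of the precursor trailer,
#' i-tRF strictly internal, and tiRNA halves (29-50 nt) cut within the
#' anticodon loop. When `config$adapter` is set the adapter is appended to
#' every read, for exercising [trim_adapter()].
#'
#' @param refs tibble from [make_trna_reference()].
#' @param config a [simulation_config()].
#' @param classes fragment classes to simulate.
#' @return A list with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `class`, `ref_id`, `compartment`, `start`, `end`),
#'   coordinates 0-based half-open.
#' @export
simulate_reads <- function(refs, config,
                           classes = c(
                             "tRF-5", "tRF-3", "tRF-1", "i-tRF",
                             "tiRNA-5", "tiRNA-3"
                           )) {
  if (nrow(refs) == 0) stop("refs must be nonempty", call. = FALSE)
  with_seed(derive_seed(config$seed, "reads"), {
    rows <- list()
    counter <- 0L
    for (cls in classes) {
      windows <- purrr::map(seq_len(nrow(refs)), function(i) {
        class_window(cls, refs[i, ])
      })
      ok <- !purrr::map_lgl(windows, is.null)
      if (!any(ok)) {
        stop("no reference can produce a ", cls,
          " fragment (e.g. trailer or anticodon geometry unsuitable)",
          call. = FALSE
        )
      }
      feasible <- which(ok)
      for (r in seq_len(config$reads_per_class)) {
        i <- feasible[sample.int(length(feasible), 1)]
        w <- windows[[i]]
        ref <- refs[i, ]
        n <- nchar(ref$mature_seq)
        if (cls == "tiRNA-3") {
          start <- w$starts[sample.int(length(w$starts), 1)]
          end <- n
        } else if (isTRUE(w$internal)) {
          len <- w$len[sample.int(length(w$len), 1)]
          # keep internal fragments clear of the 3'-slack window (end <= n-2)
          start <- sample(1:(n - len - 2), 1)
          end <- start + len
        } else if (!is.null(w$start)) {
          len <- w$len[sample.int(length(w$len), 1)]
          start <- w$start
          end <- start + len
        } else {
          len <- w$len[sample.int(length(w$len), 1)]
          end <- w$end
          start <- end - len
        }
        src <- if (w$compartment == "mature") ref$mature_seq else ref$trailer_seq
        counter <- counter + 1L
        rows[[counter]] <- tibble::tibble(
          read_id = sprintf("read_%05d", counter),
          class = cls, ref_id = ref$id, compartment = w$compartment,
          start = as.integer(start), end = as.integer(end),
          seq = substr(src, start + 1, end)
        )
      }
    }
    truth <- dplyr::bind_rows(rows)
    seqs <- truth$seq
    if (!is.null(config$adapter)) seqs <- paste0(seqs, config$adapter)
    list(
      reads = tibble::tibble(read_id = truth$read_id, seq = seqs),
      truth = dplyr::select(truth, -"seq")
    )
  })
}

make_feature_ids <- function(class, n, refs = NULL) {
  if (n == 0) return(character())
  switch(class,
    mRNA = sprintf("Gene%04d", seq_len(n)),
    miRNA = sprintf("rno-miR-%d-%s", seq_len(n), rep(c("3p", "5p"), length.out = n)),
    tRF = {
      if (is.null(refs) || nrow(refs) == 0) {
        sprintf("tRF-sim-%03d", seq_len(n))
      } else {
        prefixes <- c("tRF5", "tRF3", "tRF1", "i-tRF", "tiRNA5", "tiRNA3")
        combos <- as.vector(outer(prefixes, refs$id, paste, sep = "-"))
        if (n <= length(combos)) combos[seq_len(n)] else {
          c(combos, sprintf("tRF-sim-%03d", seq_len(n - length(combos))))
        }
      }
    },
    stop("unknown feature class: ", class, call. = FALSE)
  )
}

# extract the fragment a synthetic tRF feature id names, so expression
# features double as scannable sncRNA sequences
fragment_seq_for_id <- function(id, refs) {
  m <- regmatches(id, regexec("^(tRF5|tRF3|tRF1|i-tRF|tiRNA5|tiRNA3)-(.+)$", id))[[1]]
  if (length(m) == 0) return(random_dna(sample(16:28, 1)))
  ref <- refs[refs$id == m[3], ]
  if (nrow(ref) == 0) return(random_dna(sample(16:28, 1)))
  n <- nchar(ref$mature_seq)
  switch(m[2],
    tRF5 = substr(ref$mature_seq, 1, sample(16:28, 1)),
    tRF3 = substr(ref$mature_seq, n - sample(16:28, 1) + 1, n),
    tRF1 = substr(ref$trailer_seq, 1, min(nchar(ref$trailer_seq), sample(16:28, 1))),
    `i-tRF` = {
      len <- sample(16:28, 1)
      st <- sample(2:(n - len - 1), 1)
      substr(ref$mature_seq, st, st + len - 1)
    },
    tiRNA5 = substr(ref$mature_seq, 1, sample(30:38, 1)),
    tiRNA3 = substr(ref$mature_seq, n - sample(32:min(50, n - 30), 1) + 1, n)
  )
}

#' Simulate an expression matrix with planted differential expression
#'
#' Null features share group means; planted-up features have a treated/control
#' mean ratio of `effect_fold`, planted-down the reciprocal. Within-group
#' values are log-normal with the configured coefficient of variation and are
#' mean-preserving, so the planted ratio is the ratio of expectations.
#'
#' @param config a [simulation_config()].
#' @param class one of `"mRNA"`, `"miRNA"`, `"tRF"`.
#' @param refs optional tRNA reference tibble; when supplied, tRF feature ids
#'   are fragment names derived from the references and each feature carries
#'   the corresponding fragment sequence.
#' @return A list: `matrix` (tibble, `feature_id` + one column per sample,
#'   samples suffixed `_ctrl`/`_trt`), `truth` (tibble `feature_id`,
#'   `direction` in up/down/null), and `seqs` (tibble `feature_id`, `seq`;
#'   `NULL` for mRNA).
#' @export
simulate_expression <- function(config, class = c("mRNA", "miRNA", "tRF"),
                                refs = NULL) {
  class <- match.arg(class)
  n <- config$n_features[[class]]
  n_up <- config$planted_up[[class]]
  n_down <- config$planted_down[[class]]
  with_seed(derive_seed(config$seed, paste0("expression_", class)), {
    ids <- make_feature_ids(class, n, refs)
    direction <- rep("null", n)
    planted <- sample.int(n, n_up + n_down)
    direction[planted[seq_len(n_up)]] <- "up"
    if (n_down > 0) direction[planted[n_up + seq_len(n_down)]] <- "down"
    base_mean <- 2^runif(n, log2(50), log2(2000))
    fold <- ifelse(direction == "up", config$effect_fold,
      ifelse(direction == "down", 1 / config$effect_fold, 1)
    )
    sigma <- sqrt(log(1 + config$noise_cv^2))
    n_ctrl <- config$group_sizes[1]
    n_trt <- config$group_sizes[2]
    draw <- function(mean_vec, k) {
      vapply(seq_len(k), function(j) {
        mean_vec * exp(rnorm(n, 0, sigma) - sigma^2 / 2)
      }, numeric(n))
    }
    ctrl <- draw(base_mean, n_ctrl)
    trt <- draw(base_mean * fold, n_trt)
    mat <- cbind(ctrl, trt)
    colnames(mat) <- c(
      sprintf("s%d_ctrl", seq_len(n_ctrl)),
      sprintf("s%d_trt", seq_len(n_trt))
    )
    seqs <- NULL
    if (class != "mRNA") {
      seqs <- tibble::tibble(
        feature_id = ids,
        seq = if (class == "miRNA") {
          vapply(seq_len(n), function(i) random_dna(sample(20:23, 1)), character(1))
        } else {
          vapply(ids, fragment_seq_for_id, character(1), refs = refs %||% tibble::tibble())
        }
      )
    }
    list(
      matrix = dplyr::bind_cols(
        tibble::tibble(feature_id = ids), tibble::as_tibble(mat)
      ),
      truth = tibble::tibble(feature_id = ids, direction = direction),
      seqs = seqs
    )
  })
}

#' Simulate 3'UTR sequences
#'
#' @param utr_ids character vector of mRNA ids.
#' @param utr_len UTR length (nt).
#' @param seed integer seed.
#' @return tibble with `utr_id`, `seq` (i.i.d. uniform nucleotides).
#' @export
simulate_utrs <- function(utr_ids, utr_len = 200L, seed = 1L) {
  with_seed(derive_seed(seed, "utrs"), {
    tibble::tibble(
      utr_id = utr_ids,
      seq = vapply(seq_along(utr_ids), function(i) random_dna(utr_len), character(1))
    )
  })
}

#' Plant perfectly complementary target sites into UTRs
#'
#' A planted site is the exact reverse complement (DNA sense) of its sncRNA,
#' overwritten at a random position of the UTR, so the duplex formed by the
#' sncRNA and the site is fully Watson-Crick paired.
#'
#' @param utrs tibble (`utr_id`, `seq`).
#' @param sncrna_seqs tibble (`feature_id`, `seq`), DNA or RNA alphabet.
#' @param site_plant_rate fraction of UTRs that receive a site.
#' @param seed integer seed.
#' @param hub_sncrna optional feature id designated as the planted hub; it
#'   receives a `hub_rate` share of all planted sites so that downstream hub
#'   ranking has a known answer.
#' @param hub_rate probability that a planted site belongs to `hub_sncrna`.
#' @return list: `utrs` (updated tibble) and `sites` (tibble `utr_id`,
#'   `sncrna_id`, `start`, `end`; 0-based half-open).
#' @export
plant_target_sites <- function(utrs, sncrna_seqs, site_plant_rate = 0.5,
                               seed = 1L, hub_sncrna = NULL, hub_rate = 0.4) {
  if (nrow(sncrna_seqs) == 0 || nrow(utrs) == 0 || site_plant_rate == 0) {
    return(list(utrs = utrs, sites = tibble::tibble(
      utr_id = character(), sncrna_id = character(),
      start = integer(), end = integer()
    )))
  }
  with_seed(derive_seed(seed, "plant_sites"), {
    n_plant <- round(nrow(utrs) * site_plant_rate)
    chosen <- sample.int(nrow(utrs), n_plant)
    sites <- vector("list", n_plant)
    seqs <- utrs$seq
    hub_j <- if (!is.null(hub_sncrna)) {
      match(hub_sncrna, sncrna_seqs$feature_id)
    } else {
      NA_integer_
    }
    for (k in seq_along(chosen)) {
      i <- chosen[k]
      j <- if (!is.na(hub_j) && runif(1) < hub_rate) {
        hub_j
      } else {
        sample.int(nrow(sncrna_seqs), 1)
      }
      site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gsub("U", "T", sncrna_seqs$seq[j]))
      ))
      L <- nchar(site)
      if (L > nchar(seqs[i])) {
        stop("planted site longer than UTR ", utrs$utr_id[i], call. = FALSE)
      }
      start <- sample.int(nchar(seqs[i]) - L + 1, 1) - 1L # 0-based
      substr(seqs[i], start + 1, start + L) <- site
      sites[[k]] <- tibble::tibble(
        utr_id = utrs$utr_id[i], sncrna_id = sncrna_seqs$feature_id[j],
        start = start, end = start + L
      )
    }
    list(
      utrs = tibble::tibble(utr_id = utrs$utr_id, seq = seqs),
      sites = dplyr::bind_rows(sites)
    )
  })
}

#' Simulate a qPCR Ct table with a known ddCt
#'
#' Target Ct values in the treated group are shifted by `ddct_true` cycles
#' relative to control, on top of a shared per-gene baseline and Gaussian
#' noise, so Livak quantification should recover RQ = 2^-ddct_true.
#'
#' @param n_per_group integer pair (control, treated), each >= 2.
#' @param ddct_true true delta-delta-Ct (cycles).
#' @param base_ct_target,base_ct_reference baseline Ct values (cycles).
#' @param noise_sd Gaussian Ct noise, cycles (0 for exact recovery).
#' @param groups group labels (calibrator first).
#' @param seed integer seed.
#' @return tibble (`sample`, `group`, `ct_target`, `ct_reference`).
#' @export
#' @examples
#' simulate_ct_table(ddct_true = 1.5, noise_sd = 0, seed = 2)
simulate_ct_table <- function(n_per_group = c(3L, 3L), ddct_true = 1.446,
                              base_ct_target = 25, base_ct_reference = 20,
                              noise_sd = 0.1,
                              groups = c("control", "treated"), seed = 1L) {
  if (any(n_per_group < 2)) stop("need >= 2 samples per group", call. = FALSE)
  with_seed(derive_seed(seed, "ct_table"), {
    tabs <- purrr::map2(groups, seq_along(groups), function(g, gi) {
      n <- n_per_group[gi]
      shift <- if (gi == 1) 0 else ddct_true
      tibble::tibble(
        sample = sprintf("%s_%d", g, seq_len(n)), group = g,
        ct_target = base_ct_target + shift + rnorm(n, 0, noise_sd),
        ct_reference = base_ct_reference + rnorm(n, 0, noise_sd)
      )
    })
    dplyr::bind_rows(tabs)
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' @param universe character vector of gene symbols (the background).
#' @param n_sets number of random terms.
#' @param set_size integer range of term sizes.
#' @param planted_genes genes forming an extra fully-enriched term
#'   (`"planted_term"`); `NULL` for none.
#' @param seed integer seed.
#' @return named list of gene vectors (GMT-style).
#' @export
simulate_gene_sets <- function(universe, n_sets = 50L, set_size = c(10L, 80L),
                               planted_genes = NULL, seed = 1L) {
  with_seed(derive_seed(seed, "gene_sets"), {
    sets <- purrr::map(seq_len(n_sets), function(i) {
      sample(universe, sample(set_size[1]:set_size[2], 1))
    })
    names(sets) <- sprintf("TERM_%03d", seq_len(n_sets))
    if (!is.null(planted_genes) && length(planted_genes) > 0) {
      sets$planted_term <- unique(planted_genes)
    }
    sets
  })
}
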