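test_that("adapter trimming removes the longest suffix-prefix overlap", {
  adapter <- "TGGAATTCTCGG"
  insert <- "ACGTACGT"
  # read built as insert + adapter prefix comes back as the insert
  expect_identical(
    trim_adapter(paste0(insert, substr(adapter, 1, 5)), adapter, 5),
    insert
  )
  expect_identical(
    trim_adapter(paste0(insert, adapter), adapter, 5),
    insert
  )
  # no adapter suffix, read shorter than min_overlap, empty read: unchanged
  expect_identical(trim_adapter("ACGTACGT", adapter, 5), "ACGTACGT")
  expect_identical(trim_adapter("ACG", adapter, 5), "ACG")
  expect_identical(trim_adapter("", adapter, 5), "")
  # overlap below min_overlap is not trimmed
  expect_identical(
    trim_adapter(paste0(insert, substr(adapter, 1, 3)), adapter, 5),
    paste0(insert, substr(adapter, 1, 3))
  )
  # vectorised
  expect_identical(
    trim_adapter(c(paste0(insert, adapter), insert), adapter),
    c(insert, insert)
  )
})

make_two_refs <- function() {
  tibble::tibble(
    id = c("Ala-AGC", "Thr-AGT"),
    isotype = c("Ala", "Thr"), anticodon = c("AGC", "AGT"),
    mature_seq = c(
      paste0(strrep("ACGG", 18), "TCCA"), # 76 nt
      paste0(strrep("GTCA", 19), "GCCA") # 80 nt
    ),
    trailer_seq = c(paste0("GTTTT", strrep("CA", 10)), ""),
    anticodon_start = c(33L, 33L)
  )
}

test_that("alignment finds exact substrings with deterministic tie-breaks", {
  refs <- make_two_refs()
  read <- substr(refs$mature_seq[1], 1, 20)
  hit <- align_to_trna(read, refs)
  expect_equal(nrow(hit), 1)
  # ACGG repeats: several starts match, the smallest wins
  expect_equal(hit$start, 0)
  expect_equal(hit$end, 20)
  expect_equal(hit$ref_id, "Ala-AGC")
  expect_equal(hit$compartment, "mature")
  # a read present in both compartments prefers mature
  both <- tibble::tibble(
    id = "X-Y", isotype = "X", anticodon = "Y",
    mature_seq = paste0(random_seq(57), "ACGTACGTACGTACGT", "CCA"),
    trailer_seq = paste0("ACGTACGTACGTACGT", random_seq(10)),
    anticodon_start = 33L
  )
  h <- align_to_trna("ACGTACGTACGTACGT", both)
  expect_equal(h$compartment, "mature")
  # unalignable reads land in the unmapped log
  non <- align_to_trna(strrep("N", 14), refs)
  expect_equal(nrow(non), 0)
  expect_length(attr(non, "unmapped"), 1)
})

test_that("tie between references resolves to the smaller start", {
  shared <- "ACGTTGCAAGGTCCAT"
  refs <- withr::with_seed(1, tibble::tibble(
    id = c("Aa-AAA", "Bb-CCC"),
    isotype = c("Aa", "Bb"), anticodon = c("AAA", "CCC"),
    mature_seq = c(
      paste0(random_seq(30), shared, random_seq(24), "CCA"),
      paste0(random_seq(10), shared, random_seq(44), "CCA")
    ),
    trailer_seq = c("", ""), anticodon_start = c(33L, 33L)
  ))
  hit <- align_to_trna(shared, refs)
  # exhaustive scan oracle: all occurrences across both references
  occ <- purrr::map_dfr(1:2, function(i) {
    starts <- gregexpr(shared, refs$mature_seq[i], fixed = TRUE)[[1]]
    tibble::tibble(ref = refs$id[i], start = as.integer(starts) - 1L)
  })
  occ <- occ[occ$start >= 0, ]
  best <- occ[order(occ$start, occ$ref), ][1, ]
  expect_equal(hit$start, best$start)
  expect_equal(hit$ref_id, best$ref)
})

test_that("classification follows the positional rule table", {
  refs <- make_two_refs()
  mlen <- nchar(refs$mature_seq[2]) # 80
  hit <- function(ref_id, compartment, start, end) {
    tibble::tibble(
      read_id = "r", ref_id = ref_id, compartment = compartment,
      start = as.integer(start), end = as.integer(end), mismatches = 0L
    )
  }
  cls <- function(h) classify_fragment(h, refs)$fragment_class
  expect_equal(cls(hit("Thr-AGT", "mature", 0, 20)), "tRF-5")
  expect_equal(cls(hit("Thr-AGT", "mature", mlen - 17, mlen)), "tRF-3")
  # ends one base short of the 3' terminus: still tRF-3 under default slack
  expect_equal(cls(hit("Thr-AGT", "mature", mlen - 18, mlen - 1)), "tRF-3")
  expect_equal(cls(hit("Thr-AGT", "mature", 0, 34)), "tiRNA-5")
  expect_equal(cls(hit("Thr-AGT", "mature", mlen - 40, mlen)), "tiRNA-3")
  expect_equal(cls(hit("Thr-AGT", "mature", 15, 35)), "i-tRF")
  expect_equal(cls(hit("Ala-AGC", "trailer", 0, 18)), "tRF-1")
  # trailer fragment not anchored at the trailer start is unclassified
  expect_equal(cls(hit("Ala-AGC", "trailer", 2, 20)), "unclassified")
  # 14-15 nt and 51+ reads have no class
  expect_equal(cls(hit("Thr-AGT", "mature", 0, 15)), "unclassified")
  expect_equal(cls(hit("Thr-AGT", "mature", 0, 60)), "unclassified")
  expect_error(
    classify_fragment(hit("Thr-AGT", "mature", 70, 90), refs),
    "outside"
  )
})

test_that("anticodon-loop check restricts tiRNA calls when enabled", {
  refs <- make_two_refs()
  h <- tibble::tibble(
    read_id = "r", ref_id = "Thr-AGT", compartment = "mature",
    start = 0L, end = 45L, mismatches = 0L
  )
  # cut at 45 is outside [30, 39): tiRNA-5 only without the check
  expect_equal(classify_fragment(h, refs)$fragment_class, "tiRNA-5")
  expect_equal(
    classify_fragment(h, refs, check_anticodon = TRUE)$fragment_class,
    "unclassified"
  )
  h$end <- 34L
  expect_equal(
    classify_fragment(h, refs, check_anticodon = TRUE)$fragment_class,
    "tiRNA-5"
  )
})

test_that("fragment names use the standard class prefixes", {
  expect_equal(name_fragment("tRF-3", "Thr-AGT"), "tRF3-Thr-AGT")
  expect_equal(name_fragment("i-tRF", "Met-CAT"), "i-tRF-Met-CAT")
  expect_equal(name_fragment("tiRNA-5", "Gly-GCC"), "tiRNA5-Gly-GCC")
  expect_equal(name_fragment("tRF-1", "Ser-AGA"), "tRF1-Ser-AGA")
  expect_equal(
    name_fragment("unclassified", "Ala-AGC"),
    "unclassified-Ala-AGC"
  )
  expect_error(name_fragment("tRF-9", "Ala-AGC"), "unknown fragment class")
})

test_that("classification is order-invariant and classes exclusive", {
  cfg <- simulation_config(seed = 13, n_trnas = 8, reads_per_class = 15)
  refs <- make_trna_reference(cfg)
  sim <- simulate_reads(refs, cfg)
  calls <- classify_reads(sim$reads, refs)
  perm <- withr::with_seed(1, sample(nrow(sim$reads)))
  calls_perm <- classify_reads(sim$reads[perm, ], refs)
  merged <- dplyr::inner_join(
    calls, calls_perm,
    by = "read_id", suffix = c("", "_perm")
  )
  expect_equal(nrow(merged), nrow(calls))
  expect_identical(merged$fragment_class, merged$fragment_class_perm)
  expect_identical(merged$start, merged$start_perm)
  # exactly one class per aligned read
  expect_true(all(table(calls$read_id) == 1))
})

test_that("adapter-carrying reads classify identically after trimming", {
  cfg <- simulation_config(
    seed = 17, n_trnas = 6, reads_per_class = 10,
    adapter = "TGGAATTCTCGGGTGCCAAGG"
  )
  refs <- make_trna_reference(cfg)
  sim <- simulate_reads(refs, cfg)
  calls <- classify_reads(sim$reads, refs, adapter = cfg$adapter)
  joined <- dplyr::inner_join(sim$truth, calls, by = "read_id",
    suffix = c("_true", ""))
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_identical(joined$fragment_class, joined$class)
})

test_that("type distribution excludes unclassified from the denominator", {
  calls <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    ref_id = c("A-AAA", "A-AAA", "B-CCC", "B-CCC"),
    fragment_class = c("tRF-5", "tRF-3", "tRF-3", "unclassified")
  )
  d <- type_distribution(calls)
  expect_equal(d$fraction[d$fragment_class == "tRF-5"], 1 / 3)
  expect_equal(d$fraction[d$fragment_class == "tRF-3"], 2 / 3)
  expect_true(is.na(d$fraction[d$fragment_class == "unclassified"]))
  expect_error(type_distribution(calls[0, ]), "no fragment calls")
  # single-class input gives fraction 1
  one <- type_distribution(calls[1, ])
  expect_equal(one$fraction, 1)
})

test_that("weighted distribution reproduces proportion arithmetic", {
  # constructed check: counts 219 / 507 / 274 give 21.9% / 50.7% / 27.4%
  calls <- tibble::tibble(
    read_id = c("a", "b", "c"), ref_id = "X-AAA",
    fragment_class = c("tRF-5", "tRF-3", "i-tRF")
  )
  d <- type_distribution(calls, weights = c(219, 507, 274))
  expect_equal(d$fraction[d$fragment_class == "tRF-5"], 0.219)
  expect_equal(d$fraction[d$fragment_class == "tRF-3"], 0.507)
})

test_that("overall proportions are the count-weighted mixture of per-ref ones", {
  cfg <- simulation_config(seed = 19, n_trnas = 8, reads_per_class = 25)
  refs <- make_trna_reference(cfg)
  sim <- simulate_reads(refs, cfg)
  calls <- classify_reads(sim$reads, refs)
  overall <- type_distribution(calls)
  by_ref <- type_distribution(calls, by_ref = TRUE)
  mix <- by_ref |>
    dplyr::filter(.data$fragment_class != "unclassified") |>
    dplyr::group_by(.data$fragment_class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count))
  cmp <- dplyr::inner_join(overall, mix, by = "fragment_class")
  expect_equal(cmp$fraction.x, cmp$fraction.y, tolerance = 1e-12)
})
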