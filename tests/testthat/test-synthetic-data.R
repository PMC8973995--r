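test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(group_sizes = c(1L, 3L)), "2 replicates")
  expect_error(
    simulation_config(planted_up = c(mRNA = 1500L, miRNA = 11L, tRF = 4L),
      planted_down = c(mRNA = 600L, miRNA = 24L, tRF = 16L)),
    "exceeds n_features"
  )
  expect_error(simulation_config(effect_fold = 1), "effect_fold")
  expect_error(simulation_config(n_trnas = -1), "non-negative")
})

test_that("simulated tRNA references obey mature/trailer structure", {
  cfg <- simulation_config(seed = 3, n_trnas = 25, trailer_len = 30)
  refs <- make_trna_reference(cfg)
  expect_equal(nrow(refs), 25)
  len <- nchar(refs$mature_seq)
  expect_true(all(len >= 70 & len <= 90))
  expect_true(all(endsWith(refs$mature_seq, "CCA")))
  # anticodon embedded at the annotated offset
  expect_true(all(substr(refs$mature_seq, refs$anticodon_start + 1,
    refs$anticodon_start + 3) == refs$anticodon))
  # poly-U (T in DNA sense) run of >= 4 within the first 25 trailer nt
  expect_true(all(grepl("TTTT", substr(refs$trailer_seq, 1, 25))))
  # repeated isotype-anticodon combinations get unique ids
  expect_false(anyDuplicated(refs$id) > 0)
  expect_equal(nrow(make_trna_reference(simulation_config(n_trnas = 0))), 0)
})

test_that("fixed seed gives byte-identical reference FASTA", {
  cfg <- simulation_config(seed = 5, n_trnas = 5)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_trna_fasta(make_trna_reference(cfg), f1)
  write_trna_fasta(make_trna_reference(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the FASTA round-trips
  back <- read_trna_fasta(f1)
  fwd <- make_trna_reference(cfg)
  expect_equal(back$mature_seq, fwd$mature_seq)
  expect_equal(back$trailer_seq, fwd$trailer_seq)
  expect_equal(back$anticodon_start, fwd$anticodon_start)
})

test_that("simulated reads follow their class's positional rule", {
  cfg <- simulation_config(seed = 7, n_trnas = 10, reads_per_class = 20)
  refs <- make_trna_reference(cfg)
  sim <- simulate_reads(refs, cfg)
  expect_equal(nrow(sim$reads), 120)
  truth <- dplyr::left_join(sim$truth, refs, by = c("ref_id" = "id"))
  L <- truth$end - truth$start
  mlen <- nchar(truth$mature_seq)
  with_class <- function(cl) truth[truth$class == cl, ]
  t5 <- with_class("tRF-5")
  expect_true(all(t5$start == 0 & L[truth$class == "tRF-5"] %in% 16:28))
  t3 <- with_class("tRF-3")
  expect_true(all(t3$end == nchar(t3$mature_seq)))
  t1 <- with_class("tRF-1")
  expect_true(all(t1$compartment == "trailer" & t1$start == 0))
  ti5 <- with_class("tiRNA-5")
  expect_true(all(ti5$start == 0 &
    L[truth$class == "tiRNA-5"] %in% 29:50))
  itr <- with_class("i-tRF")
  expect_true(all(itr$start > 0 & itr$end < nchar(itr$mature_seq)))
  # reads are exact subsequences of their source compartment
  src <- ifelse(truth$compartment == "mature", truth$mature_seq,
    truth$trailer_seq)
  expect_identical(
    sim$reads$seq,
    substr(src, truth$start + 1, truth$end)
  )
})

test_that("unsatisfiable fragment classes fail loudly", {
  cfg <- simulation_config(seed = 1, n_trnas = 2, trailer_len = 10)
  refs <- make_trna_reference(cfg)
  expect_error(simulate_reads(refs, cfg, classes = "tRF-1"), "tRF-1")
  expect_error(
    simulate_reads(refs[0, ], cfg),
    "nonempty"
  )
})

test_that("expression simulation plants the configured fold structure", {
  cfg <- simulation_config(
    seed = 21,
    n_features = c(mRNA = 400L, miRNA = 50L, tRF = 30L),
    planted_up = c(mRNA = 40L, miRNA = 5L, tRF = 2L),
    planted_down = c(mRNA = 10L, miRNA = 5L, tRF = 4L),
    effect_fold = 4, noise_cv = 0.05
  )
  sim <- simulate_expression(cfg, "mRNA")
  expect_equal(nrow(sim$matrix), 400)
  expect_equal(sum(sim$truth$direction == "up"), 40)
  expect_equal(sum(sim$truth$direction == "down"), 10)
  m <- as.matrix(sim$matrix[, -1])
  ratio <- rowMeans(m[, 4:6]) / rowMeans(m[, 1:3])
  expect_equal(
    as.numeric(tapply(ratio, sim$truth$direction, median)[c("down", "null", "up")]),
    c(0.25, 1, 4),
    tolerance = 0.15
  )
  # same seed, same matrices
  sim2 <- simulate_expression(cfg, "mRNA")
  expect_identical(sim$matrix, sim2$matrix)
  # sncRNA classes carry sequences
  expect_true(all(nchar(simulate_expression(cfg, "miRNA")$seqs$seq) >= 20))
})

test_that("planted target sites are exact reverse complements in bounds", {
  utrs <- simulate_utrs(sprintf("G%02d", 1:20), utr_len = 120, seed = 4)
  snc <- tibble::tibble(
    feature_id = c("mir-a", "mir-b"),
    seq = c(random_seq(20), random_seq(22))
  )
  res <- plant_target_sites(utrs, snc, site_plant_rate = 0.5, seed = 4)
  expect_equal(nrow(res$sites), 10)
  for (r in seq_len(nrow(res$sites))) {
    s <- res$sites[r, ]
    utr_seq <- res$utrs$seq[res$utrs$utr_id == s$utr_id]
    planted <- substr(utr_seq, s$start + 1, s$end)
    expected <- revcomp_dna(snc$seq[snc$feature_id == s$sncrna_id])
    expect_identical(planted, expected)
    expect_true(s$start >= 0 && s$end <= nchar(utr_seq))
  }
  # site longer than UTR is an error
  short <- tibble::tibble(utr_id = "u1", seq = random_seq(10))
  long_snc <- tibble::tibble(feature_id = "m", seq = random_seq(30))
  expect_error(
    plant_target_sites(short, long_snc, site_plant_rate = 1, seed = 1),
    "longer than UTR"
  )
})

test_that("hub-biased planting concentrates sites on the designated hub", {
  utrs <- simulate_utrs(sprintf("G%03d", 1:100), utr_len = 120, seed = 8)
  snc <- tibble::tibble(
    feature_id = sprintf("mir-%02d", 1:10),
    seq = vapply(1:10, function(i) random_seq(20), character(1))
  )
  res <- plant_target_sites(utrs, snc,
    site_plant_rate = 1, seed = 8,
    hub_sncrna = "mir-03", hub_rate = 0.5
  )
  counts <- table(res$sites$sncrna_id)
  expect_equal(names(which.max(counts)), "mir-03")
})

test_that("Ct simulation recovers the planted ddCt exactly at zero noise", {
  ct <- simulate_ct_table(ddct_true = 1.5, noise_sd = 0, seed = 6)
  rq <- ddct(ct)
  treated <- rq$samples$rq[rq$samples$group == "treated"]
  expect_equal(treated, rep(2^-1.5, 3))
  ct0 <- simulate_ct_table(ddct_true = 0, noise_sd = 0.05, seed = 6)
  gm <- ddct(ct0)$groups
  expect_equal(gm$geomean_rq[gm$group == "treated"], 1, tolerance = 0.2)
})
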