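#' Pipeline configuration
#'
#' One object drives a full run: a [simulation_config()] block generating
#' every input, the calling thresholds (mRNA fold 2.0, sncRNA fold 1.2,
#' alpha 0.05, target score 140), and enrichment/network knobs.
#'
#' @param simulation a [simulation_config()].
#' @param mrna_fold,sncrna_fold class fold-change thresholds.
#' @param alpha raw p-value cutoff.
#' @param scan a [scan_params()] (its `threshold` is the target score
#'   cutoff).
#' @param n_tfs how many DE mRNAs to mark as transcription factors in the
#'   simulated TF list.
#' @param n_gene_sets random gene-set terms for the enrichment stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            mrna_fold = 2.0, sncrna_fold = 1.2,
                            alpha = 0.05, scan = scan_params(),
                            n_tfs = 10L, n_gene_sets = 50L) {
  stopifnot(
    mrna_fold > 0, sncrna_fold > 0, alpha > 0, alpha < 1,
    inherits(simulation, "simulation_config"),
    inherits(scan, "scan_params")
  )
  structure(
    list(
      simulation = simulation, mrna_fold = mrna_fold,
      sncrna_fold = sncrna_fold, alpha = alpha, scan = scan,
      n_tfs = as.integer(n_tfs), n_gene_sets = as.integer(n_gene_sets)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `simulation` (fields of
#' [simulation_config()]), `thresholds` (`mrna_fold`, `sncrna_fold`,
#' `alpha`, `target_score`), `n_tfs`, `n_gene_sets`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  for (f in c("n_features", "planted_up", "planted_down")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  if (!is.null(sim_args$group_sizes)) {
    sim_args$group_sizes <- unlist(sim_args$group_sizes)
  }
  thr <- y$thresholds %||% list()
  scan <- scan_params()
  if (!is.null(thr$target_score)) scan$threshold <- thr$target_score
  pipeline_config(
    simulation = do.call(simulation_config, sim_args),
    mrna_fold = thr$mrna_fold %||% 2.0,
    sncrna_fold = thr$sncrna_fold %||% 1.2,
    alpha = thr$alpha %||% 0.05,
    scan = scan,
    n_tfs = y$n_tfs %||% 10L,
    n_gene_sets = y$n_gene_sets %||% 50L
  )
}

pipeline_stage_order <- function() {
  c("simulate", "classify", "de", "targets", "network", "enrich", "ddct")
}

pipeline_stage_deps <- function() {
  list(
    simulate = character(), classify = "simulate", de = "simulate",
    targets = "de", network = "targets", enrich = "network",
    ddct = "simulate"
  )
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the stages in dependency order: `simulate` (tRNA references,
#' classified reads, expression matrices, UTRs-to-be, Ct table), `classify`
#' (adapter trim, alignment, fragment typing, type distribution), `de`
#' (CPM normalisation and class-thresholded differential expression),
#' `targets` (UTR simulation with planted sites, seed-weighted scanning),
#' `network` (anti-correlation filter, miRNA and tRF/tiRNA networks, hubs,
#' TF overlap, merged network), `enrich` (hypergeometric enrichment of the
#' network's target genes) and `ddct` (Livak quantification plus group
#' statistics). Every output file is listed in `manifest.json` with its MD5
#' content hash; a run is a pure function of the configuration, so repeated
#' runs produce identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages stages to run; must be closed under the dependency map
#'   (e.g. `c("simulate", "classify")` for a classification-only run).
#' @return tibble manifest (`file`, `stage`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = pipeline_stage_order()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stage_order(), several.ok = TRUE)
  deps <- pipeline_stage_deps()
  for (st in stages) {
    miss <- setdiff(deps[[st]], stages)
    if (length(miss)) {
      stop(
        "stage '", st, "' requires stage(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
  }
  stages <- intersect(pipeline_stage_order(), stages)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simcfg <- config$simulation
  log_path <- file.path(outdir, "run.log")
  cat("trfnet pipeline run\n", file = log_path)
  manifest <- list()
  note <- function(files, stage) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = files, stage = stage
    )
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    cat(sprintf(
      "stage=%s elapsed=%.2fs\n", stage, proc.time()[["elapsed"]] - t0
    ), file = log_path, append = TRUE)
    res
  }
  env <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      env$refs <- make_trna_reference(simcfg)
      write_trna_fasta(env$refs, file.path(outdir, "trna_reference.fa"))
      sim <- simulate_reads(env$refs, simcfg)
      env$reads <- sim$reads
      env$read_truth <- sim$truth
      write_reads_fastq(env$reads, file.path(outdir, "reads.fastq"))
      readr::write_tsv(sim$truth, file.path(outdir, "reads_truth.tsv"))
      env$expr <- purrr::map(
        stats::setNames(c("mRNA", "miRNA", "tRF"), c("mRNA", "miRNA", "tRF")),
        function(cl) simulate_expression(simcfg, cl, refs = env$refs)
      )
      for (cl in names(env$expr)) {
        tag <- tolower(cl)
        readr::write_tsv(
          env$expr[[cl]]$matrix, file.path(outdir, paste0("expr_", tag, ".tsv"))
        )
        readr::write_tsv(
          env$expr[[cl]]$truth,
          file.path(outdir, paste0("expr_", tag, "_truth.tsv"))
        )
      }
      env$ct <- simulate_ct_table(
        n_per_group = simcfg$group_sizes, seed = simcfg$seed
      )
      readr::write_tsv(env$ct, file.path(outdir, "ct_table.tsv"))
      note(c(
        "trna_reference.fa", "reads.fastq", "reads_truth.tsv",
        "expr_mrna.tsv", "expr_mrna_truth.tsv", "expr_mirna.tsv",
        "expr_mirna_truth.tsv", "expr_trf.tsv", "expr_trf_truth.tsv",
        "ct_table.tsv"
      ), "simulate")
    })
  }

  if ("classify" %in% stages) {
    run_stage("classify", function() {
      env$calls <- classify_reads(env$reads, env$refs, adapter = simcfg$adapter)
      readr::write_tsv(env$calls, file.path(outdir, "fragment_calls.tsv"))
      readr::write_tsv(
        type_distribution(env$calls),
        file.path(outdir, "type_distribution.tsv")
      )
      readr::write_tsv(
        type_distribution(env$calls, by_ref = TRUE),
        file.path(outdir, "type_distribution_by_ref.tsv")
      )
      note(c(
        "fragment_calls.tsv", "type_distribution.tsv",
        "type_distribution_by_ref.tsv"
      ), "classify")
    })
  }

  if ("de" %in% stages) {
    run_stage("de", function() {
      thr <- c(
        mRNA = config$mrna_fold, miRNA = config$sncrna_fold,
        tRF = config$sncrna_fold
      )
      env$de <- purrr::imap(env$expr, function(sim, cl) {
        de_test(
          normalize_cpm(sim$matrix),
          feature_class = cl, fc_threshold = thr[[cl]], alpha = config$alpha
        )
      })
      for (cl in names(env$de)) {
        readr::write_tsv(
          env$de[[cl]], file.path(outdir, paste0("de_", tolower(cl), ".tsv"))
        )
      }
      readr::write_tsv(
        summarize_de(env$de), file.path(outdir, "de_summary.tsv")
      )
      note(
        c("de_mrna.tsv", "de_mirna.tsv", "de_trf.tsv", "de_summary.tsv"),
        "de"
      )
    })
  }

  if ("targets" %in% stages) {
    run_stage("targets", function() {
      de_mrna_ids <- env$de$mRNA$feature_id[env$de$mRNA$direction != "ns"]
      utrs <- simulate_utrs(de_mrna_ids, simcfg$utr_len, simcfg$seed)
      de_seqs <- dplyr::bind_rows(
        dplyr::semi_join(
          env$expr$miRNA$seqs,
          dplyr::filter(env$de$miRNA, .data$direction != "ns"),
          by = "feature_id"
        ),
        dplyr::semi_join(
          env$expr$tRF$seqs,
          dplyr::filter(env$de$tRF, .data$direction != "ns"),
          by = "feature_id"
        )
      )
      # designated hub: the first down-regulated miRNA (short queries keep
      # its planted degree well clear of chance hits)
      env$hub <- env$de$miRNA |>
        dplyr::filter(.data$direction == "down") |>
        dplyr::pull("feature_id") |>
        head(1)
      planted <- plant_target_sites(
        utrs, de_seqs,
        site_plant_rate = simcfg$site_plant_rate, seed = simcfg$seed,
        hub_sncrna = if (length(env$hub)) env$hub else NULL
      )
      env$utrs <- planted$utrs
      env$planted_sites <- planted$sites
      write_seq_fasta(env$utrs, file.path(outdir, "utrs.fa"), id_col = "utr_id")
      readr::write_tsv(planted$sites, file.path(outdir, "planted_sites.tsv"))
      writeLines(env$hub %||% character(), file.path(outdir, "planted_hub.txt"))
      env$pairs <- purrr::map(
        stats::setNames(c("miRNA", "tRF"), c("miRNA", "tRF")),
        function(cl) {
          predict_targets(
            env$de[[cl]], env$expr[[cl]]$seqs, env$utrs, config$scan
          )
        }
      )
      readr::write_tsv(env$pairs$miRNA, file.path(outdir, "pairs_mirna.tsv"))
      readr::write_tsv(env$pairs$tRF, file.path(outdir, "pairs_trf.tsv"))
      note(c(
        "utrs.fa", "planted_sites.tsv", "planted_hub.txt",
        "pairs_mirna.tsv", "pairs_trf.tsv"
      ), "targets")
    })
  }

  if ("network" %in% stages) {
    run_stage("network", function() {
      # simulated TF list: a deterministic slice of the DE mRNAs
      de_mrna_ids <- sort(env$de$mRNA$feature_id[env$de$mRNA$direction != "ns"])
      env$tf_list <- head(de_mrna_ids, config$n_tfs)
      writeLines(env$tf_list, file.path(outdir, "tf_list.txt"))
      nets <- list()
      for (cl in c("miRNA", "tRF")) {
        edges <- pair_filter(env$de[[cl]], env$de$mRNA, env$pairs[[cl]])
        label <- if (cl == "miRNA") "miRNA" else "tRF/tiRNA"
        nets[[cl]] <- build_network(
          edges, env$de[[cl]], env$de$mRNA,
          tf_list = env$tf_list, regulator_type = label
        )
        tag <- tolower(cl)
        readr::write_tsv(edges, file.path(outdir, paste0("edges_", tag, ".tsv")))
        write_sif(nets[[cl]], file.path(outdir, paste0("network_", tag, ".sif")))
        write_network_graphml(
          nets[[cl]], file.path(outdir, paste0("network_", tag, ".graphml"))
        )
        readr::write_tsv(
          network_nodes(nets[[cl]]),
          file.path(outdir, paste0("nodes_", tag, ".tsv"))
        )
        readr::write_tsv(
          hub_ranking(nets[[cl]], k = 10),
          file.path(outdir, paste0("hubs_", tag, ".tsv"))
        )
      }
      env$networks <- nets
      env$merged <- merge_networks(nets$miRNA, nets$tRF)
      write_sif(env$merged, file.path(outdir, "network_combined.sif"))
      write_network_graphml(
        env$merged, file.path(outdir, "network_combined.graphml")
      )
      writeLines(
        tf_overlap(nets$miRNA, nets$tRF),
        file.path(outdir, "tf_overlap.txt")
      )
      note(c(
        "tf_list.txt",
        "edges_mirna.tsv", "network_mirna.sif", "network_mirna.graphml",
        "nodes_mirna.tsv", "hubs_mirna.tsv",
        "edges_trf.tsv", "network_trf.sif", "network_trf.graphml",
        "nodes_trf.tsv", "hubs_trf.tsv",
        "network_combined.sif", "network_combined.graphml", "tf_overlap.txt"
      ), "network")
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", function() {
      nodes <- network_nodes(env$merged)
      gene_list <- sort(nodes$id[nodes$node_type == "mRNA"])
      universe <- env$expr$mRNA$matrix$feature_id
      sets <- simulate_gene_sets(
        universe,
        n_sets = config$n_gene_sets,
        planted_genes = head(gene_list, 20), seed = simcfg$seed
      )
      write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
      writeLines(universe, file.path(outdir, "background.txt"))
      env$enrichment <- enrich(gene_list, sets, universe, mode = "ease")
      readr::write_tsv(env$enrichment, file.path(outdir, "enrichment.tsv"))
      readr::write_tsv(
        bubble_table(env$enrichment, 10), file.path(outdir, "enrichment_top.tsv")
      )
      note(c(
        "gene_sets.gmt", "background.txt", "enrichment.tsv",
        "enrichment_top.tsv"
      ), "enrich")
    })
  }

  if ("ddct" %in% stages) {
    run_stage("ddct", function() {
      env$rq <- ddct(env$ct, calibrator_group = "control")
      readr::write_tsv(env$rq$samples, file.path(outdir, "rq_samples.tsv"))
      readr::write_tsv(env$rq$groups, file.path(outdir, "rq_groups.tsv"))
      readr::write_tsv(
        group_compare(env$rq$samples, "rq", "group"),
        file.path(outdir, "validation_stats.tsv")
      )
      note(c("rq_samples.tsv", "rq_groups.tsv", "validation_stats.tsv"), "ddct")
    })
  }

  man <- dplyr::bind_rows(manifest)
  man$md5 <- unname(tools::md5sum(file.path(outdir, man$file)))
  jsonlite::write_json(
    list(stages = stages, files = man),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(man)
}
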