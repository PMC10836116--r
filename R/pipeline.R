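#' Pipeline configuration
#'
#' A single nested list, serializable to JSON, holding every stage's
#' parameters. The global \code{seed} fans out deterministically to
#' per-stage seeds, so one seed reproduces the whole run.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @param sim named list of [sim_config()] overrides.
#' @param preprocess named list of [preprocess_params()] overrides.
#' @param filter named list of [filter_params()] overrides.
#' @param rhythm list: scheme ("rotation"/"seeded_random"), use_normalized
#'   (default TRUE: detectors run on reads-per-1e7 counts), alpha (0.05),
#'   periods (c(24, 12)).
#' @param diffexp list: p_gate (0.01), lfc_gate (0.5), pc1_remove (TRUE).
#' @param ora list: fdr_threshold (0.05).
#' @return list of class "pipeline_config".
#' @export
pipeline_config <- function(seed = 1L, outdir = "apa_rhythm_out",
                            sim = list(), preprocess = list(),
                            filter = list(), rhythm = list(),
                            diffexp = list(), ora = list()) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    sim = utils::modifyList(list(n_genes = 200L), sim),
    preprocess = preprocess,
    filter = filter,
    rhythm = utils::modifyList(
      list(scheme = "rotation", use_normalized = TRUE, alpha = 0.05,
           periods = c(24, 12)), rhythm),
    diffexp = utils::modifyList(
      list(p_gate = 0.01, lfc_gate = 0.5, pc1_remove = TRUE), diffexp),
    ora = utils::modifyList(list(fdr_threshold = 0.05), ora))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Save / load a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return \code{save_config}: the path; \code{load_config}: the config.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[setdiff(names(x), "outdir")] |>
            (\(y) c(y, list(outdir = x$outdir)))())
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-to-results pipeline
#'
#' simulate -> preprocess -> call-pas -> annotate -> rhythm (24 h and 12 h)
#' -> diffexp -> ora. Every intermediate is written under
#' \code{config$outdir} and a JSON manifest records the package version,
#' seeds, a parameter hash, per-stage row counts and the md5 of every output
#' file, so two runs of the same config produce identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with all in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  od <- config$outdir
  for (d in file.path(od, c("sim", "preprocess", "pas", "annot", "rhythm",
                            "de", "ora")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    say(...)
  }

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  pp <- do.call(preprocess_params, config$preprocess)
  fp <- do.call(filter_params, config$filter)

  note("simulate: n_genes=", scfg$n_genes, " seed=", scfg$seed)
  sim <- run_stage("simulate", {
    s <- simulate_genome(scfg)
    samples <- make_sample_sheet(scfg)
    counts <- simulate_counts(scfg, samples, s$truth)
    tags <- simulate_tags(scfg, s$truth, counts)
    fq <- simulate_fastq(scfg, file.path(od, "sim", "reads.fastq"))
    write_genome_gtf(s, file.path(od, "sim", "genes.gtf"))
    write_tsv_commented(s$truth, file.path(od, "sim", "truth.tsv"),
                        "planted PAS truth; coordinates 1-based; phase in ZT hours")
    write_tsv_commented(samples, file.path(od, "sim", "samples.tsv"),
                        "sample sheet; library_size = uniquely mapped reads")
    write_tags_bed(tags, file.path(od, "sim", "tags.bed"))
    write_tsv_commented(fq$truth, file.path(od, "sim", "read_truth.tsv"),
                        "per-read truth; clean_start 1-based")
    list(genome = s, samples = samples, counts = counts, tags = tags,
         fastq = fq)
  })

  note("preprocess: min_q=", pp$min_q, " min_len=", pp$min_len)
  prep <- run_stage("preprocess", {
    r <- preprocess_fastq(file.path(od, "sim", "reads.fastq"),
                          file.path(od, "preprocess", "clean.fastq"), pp)
    write_tsv_commented(r$summary, file.path(od, "preprocess", "summary.tsv"),
                        "read-level filter summary")
    r
  })

  note("call-pas: window=", fp$cluster_window_nt,
       " lib_cutoff=", fp$lib_size_cutoff)
  pacs <- run_stage("call-pas", {
    p <- call_pas(sim$tags, sim$samples, fp)
    write_pac_table(p, file.path(od, "pas", "pacs.tsv"))
    p
  })

  note("annotate: ", nrow(pacs$info), " PACs")
  ann <- run_stage("annotate", {
    gm <- gene_models(sim$genome$genes, sim$genome$exons)
    a <- annotate_pacs(pacs, gm)
    write_tsv_commented(a, file.path(od, "annot", "annotation.tsv"),
                        "PAC annotation; apa_index 5'->3' in transcript orientation")
    a
  })

  rcfg <- config$rhythm
  rhy <- list()
  for (per in rcfg$periods) {
    note("rhythm: period=", per, "h scheme=", rcfg$scheme,
         " input=", if (rcfg$use_normalized) "normalized" else "raw")
    rhy[[as.character(per)]] <- run_stage(paste0("rhythm", per), {
      mat <- if (rcfg$use_normalized) pacs$norm_counts else pacs$counts
      r <- consensus_rhythm(mat, sim$samples, period_h = per,
                            scheme = rcfg$scheme, seed = config$seed,
                            alpha = rcfg$alpha)
      write_tsv_commented(r, file.path(od, "rhythm",
                                       sprintf("rhythm%d.tsv", per)),
                          "phases in ZT hours of peak (acrophase)")
      r
    })
  }
  bins <- phase_bin(rhy[["24"]][rhy[["24"]]$consensus == TRUE])
  bin_dt <- data.table::data.table(
    center = rep(names(bins), lengths(bins)),
    pac_id = unlist(bins, use.names = FALSE))
  write_tsv_commented(
    if (nrow(bin_dt)) bin_dt
    else data.table::data.table(center = character(), pac_id = character()),
    file.path(od, "rhythm", "phase_bins.tsv"),
    "5 h sliding circular windows; dual membership allowed")

  note("diffexp: gates p<", config$diffexp$p_gate, " |lfc|>",
       config$diffexp$lfc_gate)
  de <- run_stage("diffexp", {
    d <- run_contrasts(pacs$counts, sim$samples, annotations = ann,
                       p_gate = config$diffexp$p_gate,
                       lfc_gate = config$diffexp$lfc_gate,
                       pc1_remove = config$diffexp$pc1_remove)
    write_tsv_commented(d, file.path(od, "de", "de.tsv"),
                        "log2 fold changes treatment vs time-matched control")
    d
  })

  note("ora: FDR<=", config$ora$fdr_threshold)
  ora <- run_stage("ora", {
    universe <- unique(ann$gene_id[ann$gene_id != "INTERGENIC"])
    truth <- sim$genome$truth
    sets <- list(
      planted_cycling_24 = unique(truth$gene_id[truth$period == "24"]),
      planted_cycling_12 = unique(truth$gene_id[truth$period == "12"]),
      planted_sd = unique(truth$gene_id[truth$sd_log2fc != 0]))
    sets <- Filter(length, sets)
    cyc <- rhy[["24"]][consensus == TRUE, pac_id]
    query <- unique(ann$gene_id[ann$pac_id %in% cyc &
                                  ann$gene_id != "INTERGENIC"])
    o <- if (length(query) && length(sets))
      suppressWarnings(hypergeom_ora(query, sets, universe,
                                     config$ora$fdr_threshold))
    else data.table::data.table()
    write_tsv_commented(o, file.path(od, "ora", "ora.tsv"),
                        "hypergeometric upper-tail ORA of consensus 24 h genes")
    o
  })

  files <- sort(list.files(od, recursive = TRUE, full.names = FALSE))
  # config.json embeds the output path; the parameter hash covers its content
  files <- setdiff(files, c("manifest.json", "run.log", "config.json"))
  md5 <- tools::md5sum(file.path(od, files))
  manifest <- list(
    package = "apaRhythm",
    version = as.character(utils::packageVersion("apaRhythm")),
    seed = config$seed,
    # hash the parameters, not the output location
    parameter_hash = {
      save_config(config, file.path(od, "config.json"))
      cfg_noout <- unclass(config); cfg_noout$outdir <- NULL
      substr(paste(md5_of_string(jsonlite::toJSON(
        cfg_noout, auto_unbox = TRUE, digits = NA)), collapse = ""), 1, 32)
    },
    rows = list(truth = nrow(sim$genome$truth),
                samples = nrow(sim$samples),
                tags = nrow(sim$tags),
                reads_out = prep$summary$reads_out,
                pacs = nrow(pacs$info),
                annotated = sum(ann$gene_id != "INTERGENIC"),
                rhythm24_consensus = sum(rhy[["24"]]$consensus),
                rhythm12_consensus = sum(rhy[["12"]]$consensus),
                de_significant = sum(de$significant)),
    files = as.list(setNames(unname(md5), files)))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(od, "run.log"))
  invisible(list(sim = sim, preprocess = prep, pacs = pacs,
                 annotation = ann, rhythm = rhy, phase_bins = bins, de = de,
                 ora = ora, manifest = manifest))
}
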