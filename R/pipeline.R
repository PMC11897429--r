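#' Assemble a simulation configuration
#'
#' One list with per-stage sections, mirroring the command-line flags. Any
#' section may be omitted to use defaults; `counts` needs either a `matrix`
#' CSV used as-is, or a `reference_matrix` CSV to estimate parameters from
#' (with `n_cells` simulated cells). Every stage seed derives
#' deterministically from the single global `seed`.
#'
#' @param transcriptome Transcript FASTA path (required).
#' @param outdir Output directory (required).
#' @param counts,templates,pcr,errors,qc Named lists of stage options; see
#'   [run_pipeline()].
#' @param gtf,genome Optional annotation / genome paths.
#' @param seed Global integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(transcriptome, outdir,
                              counts = list(), templates = list(),
                              pcr = list(), errors = list(), qc = list(),
                              gtf = NULL, genome = NULL, seed = 1L) {
  cfg <- list(
    transcriptome = transcriptome, gtf = gtf, genome = genome,
    outdir = outdir, seed = as.integer(seed),
    counts = counts, templates = templates, pcr = pcr, errors = errors,
    qc = qc
  )
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file with the fields of [simulation_config()].
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(simulation_config, x)
}

#' Write a simulation configuration to YAML
#'
#' @param config A `simulation_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_msg <- function(quiet, stage, ...) {
  if (!quiet) message("[", stage, "] ", ...)
}

#' Run the full simulation pipeline
#'
#' Chains all stages: count simulation (or a user-supplied matrix) ->
#' perfect-read generation -> optional PCR amplification -> error
#' injection -> QC report. Every intermediate is written to
#' `config$outdir`, and a `manifest.json` records the package version,
#' per-stage seeds and MD5 checksums of all outputs, so a run is fully
#' reproducible and auditable.
#'
#' Stage options (all optional):
#' * `counts`: `matrix` (CSV used as ground truth directly) or
#'   `reference_matrix` + `n_cells` (estimate then simulate).
#' * `templates`: `whitelist` (path), `paf` (alignments for the truncation
#'   model), `n_bins`, `intron_retention_prob`, `tau`.
#' * `pcr`: `cycles` (0 disables the stage), `p_dup`, `p_error`,
#'   `sample_size`.
#' * `errors`: `alpha` + `beta`, or `paf` + `mode` to fit the identity
#'   model from alignments; `p_sub`, `p_ins`, `p_del`, `max_quality`.
#' * `qc`: `enabled` (default `TRUE`).
#'
#' @param config A `simulation_config` (or path to its YAML).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the output `paths`, the ground-truth
#'   `molecules` tibble, the simulated `fastq` tibble, the `qc` metrics and
#'   the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seeds <- lapply(
    setNames(nm = c("counts", "templates", "pcr", "errors")),
    function(s) derive_seed(config$seed, s)
  )
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # --- counts ---------------------------------------------------------
  co <- config$counts
  counts <- run_stage("counts", {
    if (!is.null(co$matrix)) {
      stage_msg(quiet, "counts", "using provided matrix ", co$matrix)
      read_count_matrix(co$matrix)
    } else if (!is.null(co$reference_matrix)) {
      ref <- read_count_matrix(co$reference_matrix)
      fit <- estimate_count_params(ref)
      n_cells <- co$n_cells %||% (ncol(ref) - 1L)
      stage_msg(quiet, "counts", "simulating ", n_cells,
                " cells from estimated parameters")
      simulate_counts(fit, n_cells, seed = seeds$counts)
    } else {
      abort("config$counts needs 'matrix' or 'reference_matrix'")
    }
  })
  paths$counts <- file.path(config$outdir, "synthetic_counts.csv")
  write_count_matrix(counts, paths$counts)

  # --- templates ------------------------------------------------------
  te <- config$templates
  index <- run_stage("templates", {
    load_transcriptome(config$transcriptome, config$gtf, config$genome)
  })
  truncation <- run_stage("templates", {
    if (!is.null(te$paf)) {
      estimate_truncation_model(read_paf(te$paf),
                                n_bins = te$n_bins %||% 20L)
    } else {
      full_length_model()
    }
  })
  structure_obj <- read_structure()
  whitelist <- if (!is.null(te$whitelist)) readLines(te$whitelist)
  molecules <- run_stage("templates", {
    stage_msg(quiet, "templates", "generating perfect reads")
    generate_perfect_reads(
      counts, index, structure = structure_obj, truncation = truncation,
      whitelist = whitelist,
      intron_retention_prob = te$intron_retention_prob %||% 0,
      tau = te$tau %||% 2000, seed = seeds$templates
    )
  })
  paths$perfect_fasta <- file.path(config$outdir, "perfect_reads.fasta")
  paths$truth <- file.path(config$outdir, "truth.tsv")
  paths$whitelist <- file.path(config$outdir, "whitelist.txt")
  write_reads_fasta(molecules, paths$perfect_fasta)
  write_truth(molecules, paths$truth)
  writeLines(unique(molecules$cell_barcode), paths$whitelist)
  stage_msg(quiet, "templates", nrow(molecules), " molecules")

  # --- pcr ------------------------------------------------------------
  pc <- config$pcr
  cycles <- pc$cycles %||% 0L
  templates_tbl <- molecules
  if (cycles > 0) {
    pool <- run_stage("pcr", {
      stage_msg(quiet, "pcr", cycles, " cycles, p_dup ",
                pc$p_dup %||% 0.9)
      pcr_amplify(molecules, cycles = cycles,
                  p_dup = pc$p_dup %||% 0.9,
                  p_error = pc$p_error %||% 3.5e-5,
                  sample_size = pc$sample_size, seed = seeds$pcr)
    })
    paths$amplified_fasta <- file.path(config$outdir, "amplified.fasta")
    paths$amplified_truth <- file.path(config$outdir, "amplified.tsv")
    write_reads_fasta(pool, paths$amplified_fasta)
    readr::write_tsv(
      dplyr::select(tibble::as_tibble(pool), "read_id", "origin_read_id",
                    "n_mutations"),
      paths$amplified_truth, progress = FALSE
    )
    templates_tbl <- pool
    stage_msg(quiet, "pcr", nrow(pool), " molecules after amplification")
  }

  # --- errors ---------------------------------------------------------
  er <- config$errors
  fastq <- run_stage("errors", {
    model <- if (!is.null(er$alpha) && !is.null(er$beta)) {
      identity_model(er$alpha, er$beta, er$mode %||% "gap_included")
    } else if (!is.null(er$paf)) {
      mode <- er$mode %||% "gap_included"
      fit_identity_beta(alignment_identity(read_paf(er$paf), mode), mode)
    } else {
      identity_model(30, 3)   # ~91% mean identity, typical of recent pores
    }
    profile <- error_profile(
      p_sub = er$p_sub %||% 1 / 3, p_ins = er$p_ins %||% 1 / 3,
      p_del = er$p_del %||% 1 / 3, max_quality = er$max_quality %||% 40L
    )
    stage_msg(quiet, "errors", "injecting errors (mean identity ",
              signif(model$alpha / (model$alpha + model$beta), 3), ")")
    simulate_fastq(templates_tbl, model, profile, seed = seeds$errors)
  })
  paths$fastq <- file.path(config$outdir, "reads.fastq")
  write_fastq(fastq, paths$fastq)

  # --- qc -------------------------------------------------------------
  qc_metrics <- NULL
  if (config$qc$enabled %||% TRUE) {
    qc_metrics <- run_stage("qc", compute_qc(fastq))
    paths$qc_html <- file.path(config$outdir, "qc_report.html")
    paths$qc_json <- file.path(config$outdir, "qc_report.json")
    run_stage("qc", render_report(qc_metrics, paths$qc_html,
                                  diffable = TRUE))
  }

  manifest <- list(
    package = "scnanosim",
    version = as.character(utils::packageVersion("scnanosim")),
    seed = config$seed,
    stage_seeds = seeds,
    files = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  stage_msg(quiet, "done", "outputs in ", config$outdir)
  invisible(list(paths = paths, molecules = molecules, fastq = fastq,
                 qc = qc_metrics, manifest = manifest))
}

#' Build a self-contained toy configuration
#'
#' Generates a toy reference and count matrix under `dir` and returns a
#' ready-to-run [simulation_config()] (also written to `dir/config.yml`).
#' Useful for demos and end-to-end tests without any external data.
#'
#' @param dir Working directory for fixture files and outputs.
#' @param n_genes,n_cells Toy problem size.
#' @param mean_count Mean UMIs per gene per cell.
#' @param cycles PCR cycles (0 disables PCR).
#' @param seed Global seed.
#' @return A `simulation_config`.
#' @export
toy_config <- function(dir, n_genes = 5, n_cells = 20, mean_count = 2,
                       cycles = 2, seed = 1L) {
  ref <- make_toy_reference(file.path(dir, "ref"), n_genes = n_genes,
                            seed = derive_seed(seed, "reference"))
  counts <- make_toy_counts(sprintf("gene%02d", seq_len(n_genes)), n_cells,
                            mean = mean_count,
                            seed = derive_seed(seed, "counts"))
  matrix_path <- file.path(dir, "counts.csv")
  write_count_matrix(counts, matrix_path)
  cfg <- simulation_config(
    transcriptome = ref$transcripts, gtf = ref$gtf, genome = ref$genome,
    outdir = file.path(dir, "out"),
    counts = list(matrix = matrix_path),
    pcr = list(cycles = cycles),
    seed = seed
  )
  write_config(cfg, file.path(dir, "config.yml"))
  cfg
}
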