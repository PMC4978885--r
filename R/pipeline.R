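#' Default pipeline configuration
#'
#' Clustering and tracer parameters default to the study values: 100 bp
#' kmers at step 15 (85 bp overlap), similarity thresholds 90% identity
#' over 55% overlap, minimum cluster size 0.01% of sampled reads, five
#' replicate runs of 3 M sampled reads.  Simulation fields control the
#' built-in demonstration scenario used when no read/panel files are
#' supplied.
#'
#' @return named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    # file inputs (NULL -> simulate the demonstration scenario)
    reads = NULL, panel = NULL, panel_meta = NULL,
    tree = NULL, species_table = NULL, organelle = NULL,
    # study-default analysis parameters
    n_sample = 3e6, runs = 5, min_identity = 0.90, min_overlap = 0.55,
    min_cluster_frac = 1e-4, kmer = 100, step = 15,
    # preprocessing
    trim = TRUE, organelle_k = 31, organelle_min_hit_frac = 0.5,
    # simulation scenario
    species_name = "sim_species", copies = 20, background_length = 4e5,
    n_reads = 40000, read_length = 100, error_rate = 0.001,
    # divergence-bias assay scale
    bias_grid = c(0, 0.02, 0.04, 0.06, 0.08), bias_seeds = 3,
    bias_reads = 2000, bias_background = 2e5
  )
}

merge_config <- function(config) {
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  cfg
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate`, `preprocess`, `tracers`, `cluster`,
#' `quantify`, `compare-mapping` and `stats` into one reproducible run.
#' Each stage writes its module's outputs under `out_dir` together with a
#' config snapshot and a log recording seeds and parameter values; two runs
#' with identical config produce byte-identical tables.  On error, files
#' written by the failed run are removed.
#'
#' @param out_dir output directory (created if needed).
#' @param config named list overriding [default_config()] fields.
#' @param stages character vector of stages to run, or `"all"`.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(out_dir, config = list(),
                         stages = c("simulate", "tracers", "cluster",
                                    "quantify", "stats")) {
  cfg <- merge_config(config)
  all_stages <- c("simulate", "preprocess", "tracers", "cluster",
                  "quantify", "compare-mapping", "stats")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (f in c("reads", "panel", "panel_meta", "tree", "species_table",
              "organelle"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("input file for --%s not found: %s", f, cfg[[f]]),
           call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path, writer) {
    writer(path)
    written <<- c(written, path)
    path
  }
  logline <- local({
    logpath <- file.path(out_dir, "log.txt")
    first <- TRUE
    function(...) {
      cat(sprintf(...), "\n", sep = "", file = logpath, append = !first)
      if (first) written <<- c(written, logpath)
      first <<- FALSE
    }
  })

  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  logline("ltrtracer %s | R %s.%s | seed %s",
          as.character(utils::packageVersion("ltrtracer")),
          R.version$major, R.version$minor, cfg$seed)
  emit(file.path(out_dir, "config_snapshot.json"), function(p)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, null = "null",
                         digits = NA, pretty = TRUE))

  # ---- inputs: load or simulate -----------------------------------------
  panel <- NULL
  if (!is.null(cfg$panel)) {
    panel <- load_panel(cfg$panel, cfg$panel_meta %||%
                          stop("--panel requires --panel-meta",
                               call. = FALSE))
  } else if (any(stages %in% c("simulate", "tracers", "cluster", "quantify",
                               "compare-mapping"))) {
    specs <- example_family_specs(small = TRUE, copies = cfg$copies)
    panel <- simulate_reference_panel(specs, seed = cfg$seed)
    logline("simulated panel: %d elements", nrow(panel))
  }

  reads <- NULL
  truth <- NULL
  if (!is.null(cfg$reads)) {
    reads <- read_fastq(cfg$reads, species = cfg$species_name)
  } else if ("simulate" %in% stages) {
    specs <- example_family_specs(small = TRUE, copies = cfg$copies)
    genome <- simulate_species_genome(panel, specs, cfg$background_length,
                                      seed = cfg$seed + 1)
    truth <- genome$truth_table
    reads <- simulate_reads(genome, cfg$n_reads, cfg$read_length,
                            cfg$error_rate, seed = cfg$seed + 2)
    logline("simulated genome: %d bases, repeat fraction %.4f",
            genome$length, 1 - genome$background_fraction)
  }

  if ("simulate" %in% stages && is.null(cfg$reads)) {
    emit(file.path(out_dir, "panel.fasta"), function(p)
      write_fasta(setNames(panel$sequence, panel$element_id), p))
    emit(file.path(out_dir, "panel_meta.tsv"), function(p)
      write_tsv(panel[, c("element_id", "superfamily", "sublineage")], p))
    emit(file.path(out_dir, "reads.fastq"), function(p)
      write_fastq(reads, p))
    emit(file.path(out_dir, "truth_table.tsv"), function(p)
      write_tsv(truth, p))
  }

  if ("preprocess" %in% stages && !is.null(reads)) {
    n0 <- nrow(reads)
    if (isTRUE(cfg$trim)) reads <- quality_trim(reads)
    trim_rep <- attr(reads, "report") %||%
      list(n_input = n0, n_retained = nrow(reads), n_discarded = 0)
    org_removed <- 0L
    if (!is.null(cfg$organelle)) {
      reads <- filter_organelle(reads, cfg$organelle, cfg$organelle_k,
                                cfg$organelle_min_hit_frac)
      org_removed <- attr(reads, "report")$n_removed
    }
    emit(file.path(out_dir, "preprocess_report.tsv"), function(p)
      write_tsv(data.frame(n_input = trim_rep$n_input,
                           n_trim_discarded = trim_rep$n_discarded,
                           n_organelle_removed = org_removed,
                           n_retained = nrow(reads)), p))
    emit(file.path(out_dir, "reads_filtered.fastq"), function(p)
      write_fastq(reads, p))
    logline("preprocess: %d -> %d reads", n0, nrow(reads))
  }

  tracers <- NULL
  if (any(stages %in% c("tracers", "cluster", "quantify"))) {
    km <- kmerize_panel(panel, k = cfg$kmer, step = cfg$step)
    tracers <- km$tracers
    if ("tracers" %in% stages) {
      emit(file.path(out_dir, "tracers.fasta"), function(p)
        write_tracer_fasta(tracers, p))
      emit(file.path(out_dir, "tracer_counts.tsv"), function(p)
        write_tsv(km$counts, p))
    }
    logline("tracers: %d kmers from %d elements (k=%d, step=%d)",
            km$total, nrow(km$counts), cfg$kmer, cfg$step)
  }

  if ("cluster" %in% stages) {
    smp <- sample_reads(reads, cfg$n_sample, seed = cfg$seed + 10)
    cl <- cluster_sequences(smp, tracers, cfg$min_identity,
                            cfg$min_overlap)
    fr <- repetitive_fraction(cl, nrow(smp), cfg$min_cluster_frac)
    emit(file.path(out_dir, "cluster_membership.tsv"), function(p)
      write_tsv(cl$membership, p))
    emit(file.path(out_dir, "cluster_summary.tsv"), function(p)
      write_tsv(cl$clusters, p))
    emit(file.path(out_dir, "fraction.json"), function(p)
      jsonlite::write_json(list(
        repetitive_fraction = fr$repetitive_fraction,
        n_sampled = fr$n_sampled, min_cluster_size = fr$min_cluster_size),
        p, auto_unbox = TRUE, digits = NA))
    logline("cluster: fraction %.4f over %d reads", fr$repetitive_fraction,
            fr$n_sampled)
  }

  if ("quantify" %in% stages) {
    qa <- quantify_abundance(reads, tracers, n_runs = cfg$runs,
                             n_per_run = cfg$n_sample,
                             seed = cfg$seed + 100,
                             species = cfg$species_name,
                             min_identity = cfg$min_identity,
                             min_overlap_frac = cfg$min_overlap,
                             min_cluster_frac = cfg$min_cluster_frac)
    emit(file.path(out_dir, "sublineage_profile.tsv"), function(p)
      write_tsv(qa$summary, p))
    emit(file.path(out_dir, "fraction_replicates.json"), function(p)
      jsonlite::write_json(qa$fraction, p, auto_unbox = TRUE, digits = NA))
    logline("quantify: %d runs, mean fraction %.4f (SE %.4g)", cfg$runs,
            qa$fraction$mean, qa$fraction$se)
  }

  if ("compare-mapping" %in% stages) {
    specs <- example_family_specs(small = TRUE, copies = cfg$copies)
    bias <- divergence_bias_assay(
      specs, divergence_grid = cfg$bias_grid, n_seeds = cfg$bias_seeds,
      n_reads = cfg$bias_reads, background_length = cfg$bias_background,
      seed = cfg$seed + 500, min_identity = cfg$min_identity,
      min_overlap_frac = cfg$min_overlap,
      min_cluster_frac = cfg$min_cluster_frac)
    emit(file.path(out_dir, "bias_curve.tsv"), function(p)
      write_tsv(bias$curve, p))
    if (!is.null(bias$summary))
      emit(file.path(out_dir, "bias_summary.json"), function(p)
        jsonlite::write_json(setNames(as.list(bias$summary$rho),
                                      bias$summary$method),
                             p, auto_unbox = TRUE, digits = NA))
    logline("compare-mapping: %s",
            paste(sprintf("%s rho %.3f", bias$summary$method,
                          bias$summary$rho), collapse = ", "))
  }

  if ("stats" %in% stages) {
    tab <- load_species_table(cfg$species_table)
    tree <- load_study_tree(cfg$tree)
    pr <- pearson_correlation(tab$c2_pg, tab$repetitive_fraction_pct)
    keep <- intersect(tree$tip.label, tab$abbreviation)
    tt <- drop_tips(tree, setdiff(tree$tip.label, keep))
    sub <- tab[match(tt$tip.label, tab$abbreviation), ]
    pic <- pic_correlation(tt, setNames(sub$c2_pg, tt$tip.label),
                           setNames(sub$repetitive_fraction_pct,
                                    tt$tip.label))
    emit(file.path(out_dir, "stats.json"), function(p)
      jsonlite::write_json(list(
        pearson = pr, pic = pic,
        note = "pic uses the bundled placeholder branch lengths"),
        p, auto_unbox = TRUE, digits = NA))
    emit(file.path(out_dir, "contrasts.tsv"), function(p)
      write_tsv(data.frame(
        contrast = seq_len(pic$n_contrasts),
        c2_pg = as.numeric(pic_contrasts(tt, setNames(sub$c2_pg,
                                                      tt$tip.label))),
        repetitive_pct = as.numeric(
          pic_contrasts(tt, setNames(sub$repetitive_fraction_pct,
                                     tt$tip.label)))), p))
    logline("stats: pearson r %.4f (p %.4g), pic r %.4f (p %.4g)",
            pr$r, pr$p, pic$r, pic$p)
  }

  ok <- TRUE
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin flag parser over [run_pipeline()]; used by the installed
#' `scripts/ltrtracer.R` wrapper.  The first argument is the subcommand
#' (`simulate`, `preprocess`, `tracers`, `cluster`, `quantify`,
#' `compare-mapping`, `stats` or `all`); remaining arguments are
#' `--flag value` pairs.  Flags override config-file values (`--config`, a
#' YAML file), which override defaults.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
ltr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ltrtracer.R <simulate|preprocess|tracers|cluster|quantify|",
    "compare-mapping|stats|all> [--config file.yaml] [--out dir]",
    "[--reads f] [--panel f] [--panel-meta f] [--tree f]",
    "[--species-table f] [--n-sample n] [--runs n] [--seed n]",
    "[--min-identity x] [--min-overlap x] [--min-cluster-frac x]",
    "[--kmer n] [--step n]")
  status <- tryCatch({
    if (length(args) < 1) stop(usage, call. = FALSE)
    stage <- args[1]
    flags <- args[-1]
    if (length(flags) %% 2 != 0)
      stop("flags must come in --name value pairs", call. = FALSE)
    keys <- gsub("^--", "", flags[c(TRUE, FALSE)])
    vals <- flags[c(FALSE, TRUE)]
    named <- setNames(as.list(vals), gsub("-", "_", keys))

    cfg <- list()
    if (!is.null(named$config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("--config requires the 'yaml' package", call. = FALSE)
      cfg <- yaml::read_yaml(named$config)
      named$config <- NULL
    }
    out_dir <- named$out %||% cfg$out %||% "ltrtracer_out"
    named$out <- NULL
    cfg$out <- NULL
    num_fields <- c("n_sample", "runs", "seed", "min_identity",
                    "min_overlap", "min_cluster_frac", "kmer", "step",
                    "n_reads", "background_length", "copies", "error_rate")
    for (k in names(named))
      cfg[[k]] <- if (k %in% num_fields) as.numeric(named[[k]])
                  else named[[k]]
    run_pipeline(out_dir, cfg,
                 stages = if (stage == "all") "all" else stage)
    0L
  }, error = function(e) {
    message("ltrtracer error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
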