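# Pipeline orchestration: one configured, logged, seeded run of
# simulate -> detect -> classify -> date -> census -> phylo -> enrich.
# The global seed is fanned out per stage by hashing the stage name
# (derive_seed), so toggling one stage never shifts another's randomness.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "retroburst_out",
    stages = list(simulate = TRUE, detect = TRUE, classify = TRUE,
                  date = TRUE, census = TRUE, phylo = FALSE, enrich = TRUE),
    simulate = list(genome_length = 200000L, gc_fraction = 0.5,
                    n_families = 2L, n_insertions = 4L,
                    ages = c(2.5e6, 5e6), ltr_len = 350L,
                    truncation_fraction = 0, solo_ltr_fraction = 0,
                    rate_r = 1.05e-9, transition_fraction = 0.5),
    detect = list(),                      # detector_params() overrides
    date = list(rate_r = 1.05e-9, bin_width = 5e6, max_age = 50e6,
                domain_confirmed_only = FALSE),
    phylo = list(n_replicates = 100L, outgroup = NULL),
    enrich = list(n_genes = 2000L, n_secreted = 100L, alpha = 0.05,
                  min_genome_count = 1L,
                  planted = list(list(term = "GO:0030600",
                                      count_in_secretome = 6L,
                                      count_in_genome = 9L))))
}

validate_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    rb_stop(paste0("unknown config block: ", paste(unknown, collapse = ", ")),
            "rb_config_error")
  cfg <- utils::modifyList(base, config)
  st <- cfg$stages
  if (isTRUE(st$classify) && !isTRUE(st$detect))
    rb_stop("stage 'classify' requires stage 'detect'", "rb_config_error")
  if (isTRUE(st$date) && !isTRUE(st$detect))
    rb_stop("stage 'date' requires stage 'detect'", "rb_config_error")
  if (isTRUE(st$census) && !isTRUE(st$detect))
    rb_stop("stage 'census' requires stage 'detect'", "rb_config_error")
  if (isTRUE(st$phylo) && !isTRUE(st$classify))
    rb_stop("stage 'phylo' requires stage 'classify'", "rb_config_error")
  if (!isTRUE(st$simulate) && is.null(cfg$genome_fasta) && isTRUE(st$detect))
    rb_stop("stage 'detect' needs either stage 'simulate' or a genome_fasta",
            "rb_config_error")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages run in dependency order; a stage failure aborts with an error
#' naming the stage; all outputs are deterministic given the config seed.
#'
#' @param config config list (see `inst/extdata/demo_config.yaml`) or a
#'   YAML path.
#' @return list of class `rb_run_report`: per-stage record counts, output
#'   paths, warnings, elapsed seconds, and the echoed config.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, stages = list(), outputs = character(0),
                 warnings = character(0))
  t0 <- Sys.time()
  path <- function(...) file.path(cfg$out_dir, paste0(...))
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      rb_stop(paste0("stage '", name, "' failed: ", conditionMessage(e)),
              "rb_stage_error")
    })
  }
  genome <- NULL; truth <- NULL; elements <- NULL; dated <- NULL; cen <- NULL

  if (isTRUE(cfg$stages$simulate)) run_stage("simulate", function() {
    sc <- cfg$simulate
    tmpls <- lapply(seq_len(sc$n_families), function(i)
      family_template(sprintf("simfam%02d", i),
                      if (i %% 2L == 1L) "Gypsy" else "Copia",
                      ltr_len = sc$ltr_len,
                      seed = derive_seed(cfg$seed, paste0("template", i))))
    bg <- simulate_background(sc$genome_length, sc$gc_fraction,
                              seed = derive_seed(cfg$seed, "background"))
    sim <- insert_elements(bg, tmpls, simulation_config(
      n_insertions = sc$n_insertions, ages = sc$ages, rate_r = sc$rate_r,
      transition_fraction = sc$transition_fraction,
      truncation_fraction = sc$truncation_fraction,
      solo_ltr_fraction = sc$solo_ltr_fraction,
      seed = derive_seed(cfg$seed, "insert")))
    genome <<- sim$genome; truth <<- sim$truth
    write_genome(genome, path("genome.fasta"))
    write_elements_gff3(truth, path("truth.gff3"))
    report$outputs <<- c(report$outputs, path("genome.fasta"), path("truth.gff3"))
    report$stages$simulate <<- list(n_insertions = nrow(truth))
  }) else if (!is.null(cfg$genome_fasta)) genome <- read_genome(cfg$genome_fasta)

  if (isTRUE(cfg$stages$detect)) run_stage("detect", function() {
    params <- do.call(detector_params, cfg$detect)
    elements <<- detect_ltr_elements(genome, params)
    write_elements_gff3(elements, path("detected.gff3"))
    write_tsv(elements, path("detected.tsv"))
    report$outputs <<- c(report$outputs, path("detected.gff3"), path("detected.tsv"))
    report$stages$detect <<- list(n_candidates = nrow(elements))
  })

  if (isTRUE(cfg$stages$classify)) run_stage("classify", function() {
    elements <<- classify_elements(genome, elements)
    write_elements_gff3(elements, path("classified.gff3"))
    report$outputs <<- c(report$outputs, path("classified.gff3"))
    report$stages$classify <<- list(
      n_gypsy = sum(elements$superfamily == "Gypsy"),
      n_copia = sum(elements$superfamily == "Copia"),
      n_chromoviridae = sum(elements$chromoviridae))
  })

  if (isTRUE(cfg$stages$date)) run_stage("date", function() {
    el <- elements
    if (isTRUE(cfg$date$domain_confirmed_only) && "superfamily" %in% names(el))
      el <- el[el$superfamily != "unknown", ]
    dated <<- date_elements(genome, el, rate_r = cfg$date$rate_r)
    prof <- burst_profile(dated$T_years, cfg$date$bin_width, cfg$date$max_age)
    write_tsv(dated, path("ages.tsv"))
    write_tsv(cbind(prof$bins[, c("bin_start", "bin_end")] / 1e6,
                    count = prof$bins$count), path("burst_profile.tsv"))
    report$outputs <<- c(report$outputs, path("ages.tsv"), path("burst_profile.tsv"))
    report$stages$date <<- list(n_dated = prof$n_dated,
                                n_undatable = prof$n_undatable)
  })

  if (isTRUE(cfg$stages$census)) run_stage("census", function() {
    cen <<- census(genome, elements)
    write_genome(Biostrings::DNAStringSet(cen$consensus_lib), path("consensus.fasta"))
    write_tsv(cen$copies, path("copies.tsv"))
    write_tsv(cen$census, path("census.tsv"))
    report$outputs <<- c(report$outputs, path("consensus.fasta"),
                         path("copies.tsv"), path("census.tsv"))
    report$stages$census <<- list(n_families = length(cen$families),
                                  n_copies = nrow(cen$copies))
  })

  if (isTRUE(cfg$stages$phylo)) run_stage("phylo", function() {
    lib <- cen$consensus_lib
    hits <- lapply(lib, scan_domains)
    ph <- rt_phylogeny(lib, hits, outgroup = cfg$phylo$outgroup,
                       n_replicates = cfg$phylo$n_replicates,
                       seed = derive_seed(cfg$seed, "phylo"))
    ape::write.tree(ph$tree, path("rt_tree.nwk"))
    report$outputs <<- c(report$outputs, path("rt_tree.nwk"))
    report$stages$phylo <<- list(n_taxa = length(ph$tree$tip.label))
  })

  if (isTRUE(cfg$stages$enrich)) run_stage("enrich", function() {
    ec <- cfg$enrich
    planted <- do.call(rbind, lapply(ec$planted, as.data.frame))
    tabs <- simulate_annotation_tables(ec$n_genes, ec$n_secreted, planted,
                                       seed = derive_seed(cfg$seed, "enrich"))
    rep_ <- enrich_report(tabs$gene2go, tabs$secreted, alpha = ec$alpha,
                          min_genome_count = ec$min_genome_count,
                          genes = tabs$genes)
    write_tsv(tabs$gene2go, path("gene2go.tsv"))
    writeLines(tabs$secreted, path("secreted.tsv"))
    write_tsv(rep_, path("enrichment.tsv"))
    report$outputs <<- c(report$outputs, path("gene2go.tsv"),
                         path("secreted.tsv"), path("enrichment.tsv"))
    report$stages$enrich <<- list(n_terms = nrow(rep_),
                                  n_significant = sum(rep_$significant))
  })

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(report, class = "rb_run_report")
}

#' @export
print.rb_run_report <- function(x, ...) {
  cat("retroburst run:", length(x$stages), "stages,",
      sprintf("%.1f s", x$elapsed_s), "\n")
  for (nm in names(x$stages)) {
    rec <- x$stages[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                paste(names(rec), unlist(rec), sep = "=", collapse = "  ")))
  }
  cat("outputs:\n"); for (o in x$outputs) cat("  ", o, "\n")
  invisible(x)
}
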