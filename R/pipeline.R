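#' Run the full post-calling pipeline
#'
#' Orchestrates the post-calling flow end to end: obtain per-caller variant
#' tables (from VCF files or from the seeded simulator), decompose complex
#' records, apply the per-caller filter cascade, build the modality grid
#' (per caller, strict intersections, consensus, each crossed with the three
#' missing-value modalities), then optionally validate against an array
#' truth table (with the accuracy-vs-count regression and sample-mismatch
#' flags), measure inter-experiment repeatability, compute genome summaries
#' and cluster the samples on IBS distance. All results land in `out_dir`
#' and in a deterministic machine-readable `report.json`.
#'
#' @param config A configuration list or the path to a YAML file. Top-level
#'   keys: `seed`; either `simulate` (overrides for [simulation_config()]
#'   plus `chip_markers`, `chip_error_rate`, `second_experiment`) or
#'   `inputs` (`vcfs` named map, optional `truth_table`, `gff3`, `fasta`,
#'   `expression`, `second_vcfs`); optional `params` overriding the
#'   thresholds (`min_qual` 30, `min_agree` 3, `min_maf` 0.05,
#'   `window_size` 100000, `flag_threshold` 90, `min_snps_per_gene` 5,
#'   `linkage` "average", `focus_modality`, `focus_na` "noNA").
#' @param out_dir Output directory, created if needed.
#' @return The run report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_params(config)
  report <- list(seed = config$seed, params = p)

  inp <- pipeline_inputs(config)
  report$inputs <- inp$description

  # per-caller decomposition + filter cascade
  filtered <- list()
  logs <- list()
  for (nm in names(inp$tables)) {
    res <- apply_site_filters(decompose(inp$tables[[nm]]),
                              min_qual = p$min_qual)
    filtered[[nm]] <- res$table
    logs[[nm]] <- res$log
  }
  report$filter_logs <- logs
  cs <- caller_set(filtered)

  grid <- modality_grid(cs)
  report$modality_counts <- grid$counts
  utils::write.table(grid$counts, file.path(out_dir, "modality_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  focus_modality <- p$focus_modality
  if (is.null(focus_modality)) {
    focus_modality <- sprintf("%dCallersConsensus", length(cs$tables) - 1)
  }
  focus <- filter_missing(grid$tables[[focus_modality]], p$focus_na)
  write_vcf(focus, file.path(out_dir, paste0("focus_", focus_modality, "_",
                                             p$focus_na, ".vcf")))
  report$focus <- list(modality = focus_modality, na = p$focus_na,
                       n_sites = n_sites(focus))

  if (!is.null(inp$truth)) {
    pts <- list()
    for (mod in names(grid$tables)) {
      for (na in c("noNA", "2NA", "anyNA")) {
        t <- filter_missing(grid$tables[[mod]], na)
        acc <- tryCatch(
          genotyping_accuracy(match_truth(t, inp$truth))$overall,
          error = function(e) NA_real_)
        pts[[length(pts) + 1]] <- data.frame(
          modality = mod, na = na, n_snps = n_sites(t), accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
    pts <- do.call(rbind, pts)
    report$validation <- list(points = pts)
    ok <- !is.na(pts$accuracy)
    if (sum(ok) >= 3 && stats::var(pts$n_snps[ok]) > 0) {
      reg <- accuracy_vs_count_regression(pts[ok, , drop = FALSE])
      report$validation$regression <- reg[c("slope", "intercept", "r_squared")]
    }
    acc_focus <- genotyping_accuracy(match_truth(focus, inp$truth))
    report$validation$focus_overall <- acc_focus$overall
    report$validation$flagged_samples <-
      flag_sample_mismatches(acc_focus, p$flag_threshold)
    utils::write.table(pts, file.path(out_dir, "accuracy_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(inp$second_tables)) {
    second_filtered <- lapply(inp$second_tables, function(t)
      apply_site_filters(decompose(t), min_qual = p$min_qual)$table)
    cs2 <- caller_set(second_filtered)
    second <- filter_missing(
      consensus_genotypes(cs2, min_agree = p$min_agree), p$focus_na)
    rep2 <- repeatability(focus, second)
    report$repeatability <- rep2[c("shared_fraction",
                                   "genotype_concordant_fraction")]
  }

  if (!is.null(inp$annotation)) {
    ann <- inp$annotation
    maf <- compute_maf(focus)
    dens <- window_density(focus, ann, p$window_size)
    report$summaries <- list(
      maf_mean = mean(maf, na.rm = TRUE),
      maf_gt_threshold = n_sites(filter_maf(focus, p$min_maf)),
      window = dens$summary,
      region_categories = as.list(table(annotate_regions(focus, ann))),
      coding_effects = as.list(table(classify_coding_effect(focus, ann))),
      n_genes_min_snps = length(genes_with_min_snps(focus, ann,
                                                    p$min_snps_per_gene)))
    if (!is.null(inp$expression)) {
      dec <- density_expression_correlation(dens, inp$expression, ann)
      report$summaries$density_expression <-
        dec[c("r_squared", "slope", "n_windows")]
    }
  }

  structural <- filter_maf(focus, p$min_maf)
  if (n_sites(structural) > 0 && n_samples(structural) >= 2) {
    dmat <- ibs_distance(structural)
    dend <- hierarchical_clustering(dmat, linkage = p$linkage)
    writeLines(dend$newick, file.path(out_dir, "tree.nwk"))
    write_distance_matrix(dmat, file.path(out_dir, "distance.tsv"))
    utils::write.table(dend$merges, file.path(out_dir, "merges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$clustering <- list(n_snps = n_sites(structural),
                              linkage = p$linkage, newick = dend$newick)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(report)
}

pipeline_params <- function(config) {
  p <- config$params
  if (is.null(p)) p <- list()
  defaults <- list(min_qual = 30, min_agree = 3, min_maf = 0.05,
                   window_size = 100000, flag_threshold = 90,
                   min_snps_per_gene = 5, linkage = "average",
                   focus_modality = NULL, focus_na = "noNA")
  utils::modifyList(defaults, p)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    extra <- c("chip_markers", "chip_error_rate", "second_experiment",
               "swap_samples")
    opts <- sim_args[intersect(names(sim_args), extra)]
    sim_args <- sim_args[setdiff(names(sim_args), extra)]
    sim_args$seed <- config$seed
    cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_truth(cfg)
    cal <- simulate_callers(sim, cfg)
    out <- list(tables = cal$callers$tables,
                annotation = sim$annotation,
                expression = sim$expression,
                description = list(mode = "simulation",
                                   n_truth_sites = n_sites(sim$truth),
                                   callers = names(cfg$callers)))
    if (!is.null(opts$chip_markers)) {
      out$truth <- simulate_chip(
        sim, n_markers = opts$chip_markers,
        chip_error_rate = if (is.null(opts$chip_error_rate)) 0
                          else opts$chip_error_rate,
        seed = cfg$seed + 3L,
        swap_samples = unlist(opts$swap_samples))
    }
    if (isTRUE(opts$second_experiment)) {
      out$second_tables <- simulate_callers(sim, cfg, run = 2)$callers$tables
    }
    return(out)
  }
  inp <- config$inputs
  if (is.null(inp$vcfs) || length(inp$vcfs) < 2) {
    stop("config must provide either a 'simulate' block or >= 2 caller VCFs")
  }
  out <- list(tables = lapply(inp$vcfs, read_vcf),
              description = list(mode = "files", callers = names(inp$vcfs)))
  if (!is.null(inp$truth_table)) out$truth <- read_truth_table(inp$truth_table)
  if (!is.null(inp$gff3) && !is.null(inp$fasta)) {
    out$annotation <- read_annotation(inp$gff3, inp$fasta)
  }
  if (!is.null(inp$expression)) out$expression <- read_expression(inp$expression)
  if (!is.null(inp$second_vcfs)) {
    out$second_tables <- lapply(inp$second_vcfs, read_vcf)
  }
  out
}
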