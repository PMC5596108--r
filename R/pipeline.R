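pipeline_config_keys <- c("input", "simulate", "scheme", "rarefaction_depth",
                          "permutations", "rule_set", "min_count",
                          "min_samples", "exclude_lineage_patterns",
                          "regression_pairs", "flow", "taxon_pattern",
                          "network", "nmds", "seed", "out_dir")

#' Read and validate a pipeline configuration
#'
#' The configuration is one flat JSON object with a strict schema: unknown
#' keys are rejected so silent misconfiguration is impossible. Exactly one
#' of `input` (paths to `count_table`, `sample_frame`, optional `euk_table`)
#' or `simulate` (arguments to [sim_params()]) must be present. Everything
#' else is optional with survey-convention defaults (rarefaction depth
#' 5,000, 999 permutations, the operative classification rule).
#'
#' @param x Path to a JSON file, or an equivalent named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("no such config file: %s", x)
    jsonlite::read_json(x, simplifyVector = TRUE)
  } else if (is.list(x)) x else stopf("`x` must be a path or a list")
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown)) {
    stopf("unknown config key(s): %s (allowed: %s)",
          paste(unknown, collapse = ", "),
          paste(pipeline_config_keys, collapse = ", "))
  }
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim) {
    stopf("exactly one of `input` or `simulate` must be present")
  }
  cfg$rarefaction_depth <- cfg$rarefaction_depth %||% 5000
  cfg$permutations <- cfg$permutations %||% 999
  cfg$rule_set <- cfg$rule_set %||% "operative"
  cfg$min_count <- cfg$min_count %||% 1
  cfg$min_samples <- cfg$min_samples %||% 1
  cfg$exclude_lineage_patterns <- cfg$exclude_lineage_patterns %||%
    c("Chloroplast", "Archaea")
  cfg$seed <- cfg$seed %||% 1
  cfg$taxon_pattern <- cfg$taxon_pattern %||% "Cyanobacteria"
  nw <- cfg$network %||% list()
  nw$n_permutations <- nw$n_permutations %||% 999
  nw$fdr_alpha <- nw$fdr_alpha %||% 0.05
  nw$min_prevalence <- nw$min_prevalence %||% 0.2
  nw$min_abs_rho <- nw$min_abs_rho %||% 0
  cfg$network <- nw
  nm <- cfg$nmds %||% list()
  nm$k <- nm$k %||% 2
  nm$n_restarts <- nm$n_restarts %||% 20
  nm$max_iter <- nm$max_iter %||% 300
  cfg$nmds <- nm
  fl <- cfg$flow %||% list()
  fl$source_stratum <- fl$source_stratum %||% "epipelagic"
  fl$threshold <- fl$threshold %||% 0.01
  cfg$flow <- fl
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(report, name, expr) {
  value <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  value
}

#' Run the full community-analysis pipeline from one configuration
#'
#' Executes, in order: simulate or load; lineage/blank filtering;
#' relative-abundance normalization; rarefaction; alpha diversity;
#' Bray-Curtis, nMDS, PERMANOVA (habitat and area groupings) and the
#' two-way ANOVA + Tukey comparison of Shannon indices; presence/Venn/
#' classification summaries; cross-stratum coupling, taxon fractions and
#' abundant-OTU flow; and, when a eukaryote table is present, the 16S-18S
#' co-occurrence network. All tabular artifacts are written under
#' `out_dir`, along with a machine-readable `run_report.json` that echoes
#' every parameter and derived seed; the report contains no wall-clock
#' fields, so a rerun with the same config is byte-identical.
#'
#' Stage seeds are derived deterministically from the global seed (seed + 1
#' for rarefaction, + 2 for nMDS, + 3 for PERMANOVA, + 4 for the network).
#'
#' @param config A [pipeline_config()] (or path / list coercible to one).
#' @param out_dir Output directory (default from the config).
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stopf("an output directory is required (`out_dir`)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- if (is.null(config$scheme)) default_stratum_scheme() else {
    s <- config$scheme
    stratum_scheme(s$label, s$habitat, s$lower %||% NA_real_,
                   s$upper %||% NA_real_)
  }
  seed <- as.integer(config$seed)
  report <- list(config = unclass(config), seeds = list(global = seed),
                 stages = list(), package_version = as.character(utils::packageVersion("nodulecomm")))
  art <- function(name) file.path(out_dir, name)

  ## ---- load or simulate --------------------------------------------
  euk_table <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim_args$strata <- scheme
    params <- run_stage(report, "simulate", do.call(sim_params, sim_args))
    sim <- run_stage(report, "simulate", generate_community(params))
    table <- sim$table; frame <- sim$frame; truth <- sim$truth
    if ((params$n_euk_otus %||% 0) > 0) {
      euk <- run_stage(report, "simulate",
                       generate_paired_euk_table(params, truth, frame))
      euk_table <- euk$table; truth <- euk$truth
    }
    write_count_table(table, art("counts.tsv"))
    write_sample_frame(frame, art("samples.tsv"))
    write_truth(truth, art("truth.json"))
    if (!is.null(euk_table)) write_count_table(euk_table, art("euk_counts.tsv"))
    report$stages$simulate <- list(status = "ok",
                                   n_otus = nrow(table$counts),
                                   n_samples = ncol(table$counts),
                                   n_euk_otus = if (is.null(euk_table)) 0 else nrow(euk_table$counts))
  } else {
    inp <- config$input
    table <- run_stage(report, "load",
                       read_count_table(inp$count_table,
                                        dialect = inp$dialect %||% "wide-tsv"))
    frame <- run_stage(report, "load", read_sample_frame(inp$sample_frame, scheme))
    if (!is.null(inp$euk_table)) {
      euk_table <- run_stage(report, "load",
                             read_count_table(inp$euk_table,
                                              dialect = inp$dialect %||% "wide-tsv"))
    }
    report$stages$load <- list(status = "ok", n_otus = nrow(table$counts),
                               n_samples = ncol(table$counts))
  }

  ## ---- preprocess ---------------------------------------------------
  filtered <- run_stage(report, "filter",
                        filter_table(table, frame,
                                     exclude_lineage_patterns = config$exclude_lineage_patterns))
  fr <- attr(filtered, "filter_report")
  report$stages$filter <- list(status = "ok",
                               lineage_removed = length(fr$lineage_removed),
                               blank_removed = length(fr$blank_removed),
                               controls_dropped = fr$control_samples_dropped)
  frame_nc <- frame[frame$habitat != "control", , drop = FALSE]
  rel <- run_stage(report, "normalize", to_relative(filtered))
  report$stages$normalize <- list(status = "ok")

  rare_seed <- seed + 1L
  rt <- run_stage(report, "rarefy",
                  rarefy(filtered, config$rarefaction_depth, rare_seed))
  report$seeds$rarefy <- rare_seed
  report$stages$rarefy <- list(status = "ok",
                               depth = config$rarefaction_depth,
                               dropped = attr(rt, "rarefaction")$dropped_samples)

  ## ---- alpha --------------------------------------------------------
  alpha <- run_stage(report, "alpha",
                     alpha_summary(filtered, frame_nc,
                                   depth = config$rarefaction_depth,
                                   seed = rare_seed))
  utils::write.table(alpha$samples, art("alpha_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(alpha$groups, art("alpha_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$stages$alpha <- list(status = "ok", n_samples = nrow(alpha$samples),
                              dropped = alpha$dropped)

  ## ---- beta ---------------------------------------------------------
  d <- run_stage(report, "beta", bray_curtis(rel))
  write_distance_matrix(d, art("bray_curtis.tsv"))
  meta <- frame_nc[match(rownames(d), frame_nc$sample_id), , drop = FALSE]
  nmds_seed <- seed + 2L
  ord <- run_stage(report, "beta",
                   nmds(d, k = config$nmds$k,
                        n_restarts = config$nmds$n_restarts,
                        max_iter = config$nmds$max_iter, seed = nmds_seed))
  utils::write.table(
    data.frame(sample_id = rownames(ord$points), ord$points,
               check.names = FALSE),
    art("nmds_coordinates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  perm_seed <- seed + 3L
  perm_for <- function(groups) {
    if (length(unique(groups)) < 2) return(NULL)
    run_stage(report, "beta",
              permanova(d, groups, n_permutations = config$permutations,
                        seed = perm_seed))
  }
  perm_habitat <- perm_for(meta$habitat)
  perm_area <- perm_for(meta$area)
  aov_res <- run_stage(report, "beta", {
    a_samp <- alpha$samples
    if (length(unique(a_samp$area)) > 1 && length(unique(a_samp$stratum)) > 1) {
      anova_tukey(a_samp$shannon, a_samp$area, a_samp$stratum)
    } else NULL
  })
  beta_json <- list(
    nmds = list(stress = ord$stress, converged = ord$converged,
                n_restarts = ord$n_restarts, seed = nmds_seed),
    permanova_habitat = if (is.null(perm_habitat)) NULL else unclass(perm_habitat),
    permanova_area = if (is.null(perm_area)) NULL else unclass(perm_area),
    anova_tukey = if (is.null(aov_res)) NULL else
      list(anova = aov_res$anova, tukey = aov_res$tukey)
  )
  jsonlite::write_json(beta_json, art("beta_results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$seeds$nmds <- nmds_seed
  report$seeds$permanova <- perm_seed
  report$stages$beta <- list(status = "ok", stress = ord$stress,
                             permanova_habitat_p = perm_habitat$p_value %||% NA,
                             permanova_area_p = perm_area$p_value %||% NA)

  ## ---- classification ----------------------------------------------
  pres <- run_stage(report, "classify",
                    presence_matrix(filtered, frame_nc, scheme,
                                    min_count = config$min_count,
                                    min_samples = config$min_samples))
  venn <- run_stage(report, "classify", venn_partition(pres, scheme))
  cls <- run_stage(report, "classify",
                   classify_otus(pres, scheme, rule_set = config$rule_set))
  summ <- run_stage(report, "classify", class_summary(cls, filtered, frame_nc))
  utils::write.table(as.data.frame(cls), art("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(regions = as.list(venn$regions),
                            totals = as.list(venn$totals),
                            pairwise = as.list(venn$pairwise),
                            n_otus = venn$n_otus),
                       art("venn.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(summ$per_class, art("class_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$stages$classify <- list(
    status = "ok",
    n_classified = nrow(cls),
    per_class = structure(as.list(summ$per_class$n_otus),
                          names = summ$per_class$label),
    venn_regions = as.list(venn$regions))

  ## ---- coupling -----------------------------------------------------
  pairs <- config$regression_pairs %||% {
    wz <- water_strata(scheme)[1]
    sed <- sediment_strata(scheme)[1]
    nod <- nodule_strata(scheme)[1]
    c(sprintf("%s:%s", wz, nod), sprintf("%s:%s", wz, sed))
  }
  coup <- run_stage(report, "couple",
                    habitat_abundance_regression(rel, frame_nc, scheme, pairs))
  utils::write.table(coup$pairs, art("coupling_regressions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  frac <- run_stage(report, "couple", tryCatch(
    taxon_habitat_fractions(filtered, frame_nc, config$taxon_pattern),
    error = function(e) NULL))
  if (!is.null(frac)) {
    jsonlite::write_json(list(pattern = frac$pattern,
                              by_habitat = as.list(frac$by_habitat_full),
                              by_stratum = as.list(frac$by_stratum)),
                         art("taxon_fractions.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  flow <- run_stage(report, "couple",
                    abundant_flow(rel, frame_nc, scheme,
                                  source_stratum = config$flow$source_stratum,
                                  threshold = config$flow$threshold))
  utils::write.table(as.data.frame(flow), art("abundant_flow.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$couple <- list(
    status = "ok",
    regressions = stats::setNames(as.list(coup$pairs$r2), coup$pairs$pair),
    taxon_pattern = if (is.null(frac)) "no match" else frac$pattern,
    n_abundant_flow_otus = length(unique(flow$otu_id)))

  ## ---- network ------------------------------------------------------
  if (!is.null(euk_table)) {
    net_seed <- seed + 4L
    euk_rel <- run_stage(report, "network", to_relative(euk_table))
    net <- run_stage(report, "network",
                     cooccurrence_network(rel, euk_rel,
                                          n_permutations = config$network$n_permutations,
                                          fdr_alpha = config$network$fdr_alpha,
                                          min_prevalence = config$network$min_prevalence,
                                          min_abs_rho = config$network$min_abs_rho,
                                          seed = net_seed))
    write_edge_list(net, art("network_edges.tsv"))
    write_graphml(net, art("network.graphml"))
    report$seeds$network <- net_seed
    report$stages$network <- list(status = "ok", n_edges = nrow(net),
                                  n_tested = attr(net, "n_tested"))
  } else {
    report$stages$network <- list(status = "skipped",
                                  reason = "no eukaryote table")
  }

  jsonlite::write_json(report, art("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
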