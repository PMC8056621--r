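#' Pipeline run configuration
#'
#' Collects stage toggles, module configurations and paths for
#' [run_pipeline()]. In `"simulate"` mode the synthetic generator
#' produces all inputs; in `"analyze"` mode expression, genotype and
#' panel files are read from `input_dir` (as written by a previous
#' simulate run or by the user in the same formats).
#'
#' @param mode `"simulate"` or `"analyze"`.
#' @param sim A [sim_config()] (simulate mode).
#' @param input_dir Directory holding `expression_parent1.tsv`,
#'   `expression_parent2.tsv`, `genotypes.tsv`, `panel.bed`,
#'   `panel_snps.tsv` (analyze mode).
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param gene_filter A [gene_filter_config()].
#' @param coexpr A [coexpression_config()].
#' @param n_perm,alpha,cis_window_cm,step_cm,error_prob Scan settings
#'   (see [map_eqtl()]).
#' @param window_bp Window width for [window_bias_profile()].
#' @param run_coexpression,run_ratios Stage toggles.
#' @param seed RNG seed for the run (recorded in the provenance log).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "analyze"),
                       sim = sim_config(),
                       input_dir = NULL, out_dir = NULL,
                       gene_filter = gene_filter_config(),
                       coexpr = coexpression_config(),
                       n_perm = 200, alpha = 0.05, cis_window_cm = 10,
                       step_cm = 1, error_prob = 1e-3, window_bp = 2e6,
                       run_coexpression = FALSE, run_ratios = TRUE,
                       seed = 1) {
  mode <- match.arg(mode)
  if (mode == "analyze") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("analyze mode needs an existing 'input_dir'", call. = FALSE)
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, gene_filter = gene_filter,
                 coexpr = coexpr, n_perm = n_perm, alpha = alpha,
                 cis_window_cm = cis_window_cm, step_cm = step_cm,
                 error_prob = error_prob, window_bp = window_bp,
                 run_coexpression = run_coexpression,
                 run_ratios = run_ratios, seed = seed),
            class = "run_config")
}

write_inputs <- function(sim, dir) {
  write_expression(sim$expression$vs_parent1,
                   file.path(dir, "expression_parent1.tsv"))
  write_expression(sim$expression$vs_parent2,
                   file.path(dir, "expression_parent2.tsv"))
  write_expression(sim$expression$truth,
                   file.path(dir, "expression_truth.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_panel(sim$panel, file.path(dir, "panel.bed"),
              file.path(dir, "panel_snps.tsv"))
  write_tsv(sim$expression$truth_table, file.path(dir, "truth_table.tsv"))
  write_tsv(sim$feature_counts, file.path(dir, "feature_counts.tsv"))
  invisible(dir)
}

read_inputs <- function(dir) {
  panel <- read_panel(file.path(dir, "panel.bed"),
                      file.path(dir, "panel_snps.tsv"))
  fc_path <- file.path(dir, "feature_counts.tsv")
  list(expr1 = read_expression(file.path(dir, "expression_parent1.tsv"),
                               reference = "parent1"),
       expr2 = read_expression(file.path(dir, "expression_parent2.tsv"),
                               reference = "parent2"),
       genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
       panel = panel,
       feature_counts = if (file.exists(fc_path)) {
         fc <- read_tsv(fc_path)
         class(fc) <- c("feature_counts", "data.frame")
         fc
       } else NULL)
}

#' Run the full bias-detection pipeline
#'
#' Stages, in order: obtain inputs (simulate or read), filter markers and
#' estimate the genetic map, filter genes, map eQTL against both
#' reference templates with a shared permutation threshold, and produce
#' the bias diagnostics: direction asymmetry per template, between-
#' template discordance, the 2-Mb window profile, the divergence-
#' magnitude regressions per direction class, optionally the
#' coexpression module report and the UTR/SJ ratio tests. A rerun with
#' the same configuration reproduces every output bit-identically; all
#' artifacts plus a provenance log are written to `out_dir` when set.
#'
#' @param config A [run_config()].
#' @return A `bias_report_bundle` list with the stage outputs.
#' @examples
#' \donttest{
#' cfg <- run_config(sim = sim_config(n_genes = 60, n_markers = 60,
#'                                    n_lines = 40, seed = 3),
#'                   n_perm = 30, run_ratios = FALSE)
#' bundle <- run_pipeline(cfg)
#' bundle$bias_parent1
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (config$mode == "simulate") {
    sim <- stage("simulate", {
      sc <- config$sim
      sc$seed <- config$seed
      simulate_dataset(sc)
    })
    expr1 <- sim$expression$vs_parent1
    expr2 <- sim$expression$vs_parent2
    genotypes <- sim$genotypes
    panel <- sim$panel
    feature_counts <- sim$feature_counts
    truth_table <- sim$expression$truth_table
  } else {
    inp <- stage("read-inputs", read_inputs(config$input_dir))
    expr1 <- inp$expr1; expr2 <- inp$expr2
    genotypes <- inp$genotypes; panel <- inp$panel
    feature_counts <- inp$feature_counts
    truth_table <- NULL
  }

  # re-seed so the analysis stages draw the same permutations whether
  # the inputs were just simulated or read back from disk
  set.seed(config$seed)
  genotypes_f <- stage("filter-markers",
                       suppressMessages(filter_markers(genotypes)))
  map <- stage("estimate-map", estimate_map(genotypes_f))
  f1 <- stage("filter-genes",
              suppressMessages(filter_genes(expr1, config$gene_filter)))
  f2 <- stage("filter-genes",
              suppressMessages(filter_genes(expr2, config$gene_filter)))

  probs <- stage("genotype-probabilities",
                 genotype_probabilities(genotypes_f, map, config$step_cm,
                                        config$error_prob))
  threshold <- stage("permutation-threshold",
                     permutation_threshold(probs, config$n_perm,
                                           config$alpha))
  rec1 <- stage("map-eqtl", map_eqtl(f1, genotypes_f, map, panel,
                                     probs = probs, threshold = threshold,
                                     cis_window_cm = config$cis_window_cm))
  rec2 <- stage("map-eqtl", map_eqtl(f2, genotypes_f, map, panel,
                                     probs = probs, threshold = threshold,
                                     cis_window_cm = config$cis_window_cm))

  bias1 <- stage("bias-report", bias_proportion(rec1))
  bias2 <- stage("bias-report", bias_proportion(rec2))
  discord <- stage("bias-report", compare_references(rec1, rec2))
  profile <- stage("window-profile",
                   window_bias_profile(rec1, panel, config$window_bp))
  div_fits <- stage("divergence-regression", {
    co <- cis_only_records(rec1)
    lapply(c(parent1 = "parent1", parent2 = "parent2"), function(d) {
      rc <- co[co$direction %in% d, , drop = FALSE]
      tryCatch(divergence_effect_regression(rc, panel),
               error = function(e) NULL)
    })
  })

  modules_report <- NULL
  if (config$run_coexpression) {
    modules_report <- stage("coexpression", {
      tom <- adjacency_tom(f1, config$coexpr$beta)
      mods <- detect_modules(tom, config$coexpr)
      haplotype_direction(mods, f1, genotypes_f, panel, records = rec1)
    })
  }
  ratios_report <- NULL
  if (config$run_ratios && !is.null(feature_counts)) {
    ratios_report <- stage("ratios", {
      ratios <- suppressMessages(compute_ratios(feature_counts))
      dirs <- cis_only_records(rec1)[, c("gene_id", "direction")]
      if (nrow(dirs) >= 20) ratio_tests(ratios, dirs) else NULL
    })
  }

  bundle <- list(config = config, map = map, records_parent1 = rec1,
                 records_parent2 = rec2, bias_parent1 = bias1,
                 bias_parent2 = bias2, discordance = discord,
                 window_profile = profile, divergence_fits = div_fits,
                 modules = modules_report, ratio_tests = ratios_report,
                 truth_table = truth_table)
  class(bundle) <- "bias_report_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    if (config$mode == "simulate") write_inputs(sim, od)
    write_map(map, file.path(od, "genetic_map.tsv"))
    write_records(rec1, file.path(od, "eqtl_parent1.tsv"))
    write_records(rec2, file.path(od, "eqtl_parent2.tsv"))
    write_tsv(profile$windows, file.path(od, "window_profile.tsv"))
    write_windows_bed(profile, file.path(od, "window_profile.bed"))
    write_report_json(list(bias_parent1 = unclass(bias1),
                           bias_parent2 = unclass(bias2),
                           discordance = unclass(discord)),
                      file.path(od, "bias_report.json"))
    if (!is.null(ratios_report))
      write_report_json(ratios_report, file.path(od, "ratio_tests.json"))
    prov <- list(package = "eqtlbias",
                 version = as.character(utils::packageVersion("eqtlbias")),
                 r_version = R.version.string,
                 seed = config$seed,
                 config = utils::modifyList(
                   lapply(unclass(config), function(x)
                     if (is.list(x)) unclass(x) else x),
                   list(out_dir = NULL, input_dir = NULL)))
    yaml::write_yaml(prov, file.path(od, "provenance.yaml"))
  }
  bundle
}

#' @export
print.bias_report_bundle <- function(x, ...) {
  cat("Mapping-bias report bundle\n")
  cat("-- parent-1 template --\n"); print(x$bias_parent1)
  cat("-- parent-2 template --\n"); print(x$bias_parent2)
  print(x$discordance)
  invisible(x)
}
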