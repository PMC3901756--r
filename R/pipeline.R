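#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file with the same keys):
#' `alignment`, `tree`, `partitions` (input paths), optional `rates`
#' (pre-computed site-rate TSV, e.g. from an external rate estimator),
#' `out_dir`, and optional `grid_points` (default 512), `t_max`
#' (default: root age of the tree), `variants` (default all three),
#' `priors` (list of lists with `kind`, `offset`, `mean`, `sd`),
#' `seed` (default 1), `verbose`.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated, default-filled configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("alignment", "tree", "partitions"))
    if (is.null(config[[key]]))
      stopf("config is missing required field '%s'", key)
  for (key in c("alignment", "tree", "partitions", "rates")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stopf("config field '%s' points to a missing file: %s", key, p)
  }
  if (is.null(config$out_dir)) stopf("config is missing required field 'out_dir'")
  config$grid_points <- config$grid_points %||% 512L
  config$variants <- config$variants %||%
    c("original", "modified", "average_modified")
  config$seed <- config$seed %||% 1L
  config$verbose <- isTRUE(config$verbose)
  if (config$grid_points < 2) stopf("grid_points must be >= 2")
  if (!is.null(config$t_max) && config$t_max <= 0) stopf("t_max must be > 0")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full marker-utility pipeline
#'
#' Executes site classification, per-site rate estimation (or loads a
#' supplied rate table), informativeness profiling, saturation analysis
#' and calibration-prior summaries, writing one TSV per stage into
#' `out_dir`. Every output carries a `#`-prefixed provenance header
#' (package version, seed, input checksums). Outputs are written to a
#' `.partial` file first and renamed on stage completion, so an aborted
#' run leaves its incomplete stage marked.
#'
#' @param config See [read_run_config()].
#' @return Invisibly, a list with the per-stage results and the written
#'   file paths.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(...)

  inputs <- c(alignment = config$alignment, tree = config$tree,
              partitions = config$partitions)
  if (!is.null(config$rates)) inputs <- c(inputs, rates = config$rates)
  prov <- c(tool = paste0("phylopi ", as.character(utils::packageVersion("phylopi"))),
            seed = as.character(config$seed),
            setNames(paste0(basename(inputs), " md5:",
                            unname(tools::md5sum(inputs))),
                     paste0("input_", names(inputs))))

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  emit <- function(df, file) {
    final <- file.path(config$out_dir, file)
    part <- paste0(final, ".partial")
    write_report_tsv(df, part, prov)
    file.rename(part, final)
    final
  }

  say("reading inputs")
  matrix <- stage("read_alignment", function() read_fasta(config$alignment))
  tree <- stage("read_tree", function() read_newick_file(config$tree))
  scheme <- stage("read_partitions", function()
    resolve_partitions(paste(readLines(config$partitions), collapse = "\n"),
                       ncol(matrix)))

  out <- list(paths = character(0))

  say("classifying sites")
  out$site_classes <- stage("classify", function()
    site_class_summary(matrix, scheme))
  out$paths["site_classes"] <- emit(out$site_classes, "site_classes.tsv")

  say("estimating site rates")
  out$rates <- stage("rates", function() {
    if (!is.null(config$rates)) read_rate_table(config$rates)
    else estimate_all_rates(matrix, tree, scheme)
  })
  out$paths["rates"] <- emit(out$rates, "rates.tsv")

  say("informativeness profiles")
  out$profile <- stage("profile", function() {
    t_max <- config$t_max %||% root_age(tree)
    pi_profile(out$rates, scheme, t_max = t_max,
               variants = config$variants, n_grid = config$grid_points)
  })
  out$paths["pi_profile"] <- emit(as.data.frame(out$profile), "pi_profile.tsv")

  say("saturation analysis")
  out$saturation <- stage("saturation", function()
    saturation_table(matrix, tree, scheme))
  out$paths["saturation_pairs"] <- emit(out$saturation$pairs,
                                        "saturation_pairs.tsv")
  out$paths["saturation_summary"] <- emit(out$saturation$summary,
                                          "saturation_summary.tsv")

  if (!is.null(config$priors)) {
    say("calibration priors")
    out$priors <- stage("priors", function() {
      prior_table(lapply(config$priors, function(p)
        calibration_prior(p$kind, p$offset, p$mean, p$sd)))
    })
    out$paths["priors"] <- emit(out$priors, "priors.tsv")
  }

  invisible(out)
}
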