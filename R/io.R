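#' Load and validate a run configuration
#'
#' Reads a YAML configuration for a full subset-study run, fills documented
#' defaults (`k_min = 2`, `k_max = 11`, `workers = 1`, `seed = 0`, no named
#' sets) and rejects unknown keys. Recognized keys: `data`, `scale_map`,
#' `out_dir`, `k_min`, `k_max`, `seed`, `workers`, `n_convention`,
#' `max_restarts`, `named_sets` (a mapping from set name to a list of trait
#' names).
#'
#' @param path Path to a YAML file.
#' @return List of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  known <- c("data", "scale_map", "out_dir", "k_min", "k_max", "seed",
             "workers", "n_convention", "max_restarts", "named_sets")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("data", "scale_map")) {
    if (is.null(raw[[key]])) stop("config is missing required key: ", key)
  }
  cfg <- list(
    data = raw$data, scale_map = raw$scale_map,
    out_dir = raw$out_dir %||% "results",
    k_min = as.integer(raw$k_min %||% 2L),
    k_max = as.integer(raw$k_max %||% 11L),
    seed = as.integer(raw$seed %||% 0L),
    workers = as.integer(raw$workers %||% 1L),
    n_convention = raw$n_convention %||% "N",
    max_restarts = as.integer(raw$max_restarts %||% 5L),
    named_sets = raw$named_sets %||% list()
  )
  if (cfg$k_min > cfg$k_max) {
    stop(sprintf("invalid k range: k_min = %d > k_max = %d",
                 cfg$k_min, cfg$k_max))
  }
  if (cfg$k_min < 1L) stop("k_min must be >= 1")
  if (!cfg$n_convention %in% c("N", "N-1")) {
    stop("n_convention must be 'N' or 'N-1'")
  }
  if (length(cfg$named_sets)) {
    if (is.null(names(cfg$named_sets)) || any(!nzchar(names(cfg$named_sets)))) {
      stop("named_sets must be a mapping from set name to trait list")
    }
    cfg$named_sets <- lapply(cfg$named_sets, function(z) as.character(unlist(z)))
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a configuration's named sets against a scale map
#' @param config A [load_config()] result.
#' @param map A [scale_map()].
#' @return Invisibly `TRUE`; errors name the offending set and trait.
#' @export
validate_config <- function(config, map) {
  for (nm in names(config$named_sets)) {
    unknown <- setdiff(config$named_sets[[nm]], map$scales)
    if (length(unknown)) {
      stop(sprintf("named set '%s' references unknown trait(s): %s",
                   nm, paste(unknown, collapse = ", ")))
    }
  }
  if (config$k_max > map$n_scales) {
    stop(sprintf("k_max = %d exceeds the %d traits in the scale map",
                 config$k_max, map$n_scales))
  }
  invisible(TRUE)
}

#' Read a scale map CSV
#'
#' Expects columns `item_id`, `scale_name`, `reverse_coded`. Row order is
#' item column order.
#'
#' @param path CSV path.
#' @return A [scale_map()] with attribute `"reverse_coded"` (logical per
#'   item), used by [read_responses()] to re-key reversed items.
#' @export
read_scale_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "scale_name", "reverse_coded")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("scale map is missing column(s): ", paste(missing, collapse = ", "))
  }
  map <- scale_map(df$item_id, df$scale_name)
  attr(map, "reverse_coded") <- as.logical(df$reverse_coded)
  map
}

#' Read an item-response CSV and apply reverse coding
#'
#' Loads a response matrix whose header matches the scale map's item IDs and
#' re-scores reverse-coded items as `6 - x` at load time, so all downstream
#' stages see consistently keyed 1..5 responses.
#'
#' @param path CSV path (header = item IDs).
#' @param map A [read_scale_map()] result.
#' @return Numeric matrix with item IDs as column names.
#' @export
read_responses <- function(path, map) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), map$item_ids)) {
    stop("response columns do not match the scale map's item IDs")
  }
  X <- as.matrix(df)
  rev <- attr(map, "reverse_coded")
  if (!is.null(rev) && any(rev)) {
    X[, rev] <- 6 - X[, rev]
  }
  X
}

#' Write the study's output tables
#'
#' Writes `combinations.csv` (one row per subset), `summary_by_k.csv`,
#' `by_trait.csv`, `named_sets.csv` (if any definitions were evaluated) and
#' `manifest.json` into `out_dir`.
#'
#' @param results A [run_all()] table.
#' @param summary A [summarize_combinations()] result.
#' @param out_dir Output directory (created if needed).
#' @param named A [named_sets()] result, or `NULL`.
#' @param extra_manifest Named list merged into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_outputs <- function(results, summary, out_dir, named = NULL,
                          extra_manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(out_dir, "combinations.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$by_k, file.path(out_dir, "summary_by_k.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$by_trait, file.path(out_dir, "by_trait.csv"),
                   row.names = FALSE)
  if (!is.null(named)) {
    utils::write.csv(named$sets, file.path(out_dir, "named_sets.csv"),
                     row.names = FALSE)
    utils::write.csv(named$member_medians,
                     file.path(out_dir, "named_set_members.csv"),
                     row.names = FALSE)
  }
  manifest <- c(
    attr(results, "manifest"),
    list(
      overall_median = summary$overall_median,
      n_excluded = summary$n_excluded,
      package_version = as.character(utils::packageVersion("darkcore")),
      output_checksums = as.list(tools::md5sum(
        list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
      ))
    ),
    extra_manifest
  )
  names(manifest$output_checksums) <-
    basename(names(manifest$output_checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Serialize a fit as JSON
#' @param fit A [fit_bifactor()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  std <- standardized_loadings(fit)
  out <- list(
    n_items = fit$spec$p, n_scales = fit$spec$n_scales,
    chi_square = fit$chi_square, df = fit$df, p_value = fit$p_value,
    rmsea = fit$rmsea, rmsea_ci90 = fit$rmsea_ci90, srmr = fit$srmr,
    fml = fit$fml, converged = fit$converged,
    n_iterations = fit$n_iterations, n_restarts = fit$n_restarts,
    heywood = fit$heywood, n = fit$n,
    parameters = list(
      lambda_general = fit$lambda[, 1L],
      lambda_specific = fit$lambda[cbind(seq_len(fit$spec$p),
                                         fit$spec$scale_idx + 1L)],
      theta = fit$theta, psi = fit$psi
    ),
    standardized = std
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a human-readable run report
#'
#' Collects the output tables of a completed run into one markdown report:
#' the per-size summary (counts, percentiles, medians), the per-trait
#' panels, named-set comparisons, the convergence summary and the manifest.
#'
#' @param out_dir Directory holding the run's outputs.
#' @param path Report destination (default `report.md` inside `out_dir`).
#' @return Invisibly, `path`. Errors list any missing output files.
#' @export
assemble_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  need <- c("combinations.csv", "summary_by_k.csv", "by_trait.csv",
            "manifest.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("missing output file(s): ", paste(missing, collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  by_k <- utils::read.csv(file.path(out_dir, "summary_by_k.csv"))
  by_trait <- utils::read.csv(file.path(out_dir, "by_trait.csv"))
  combos <- utils::read.csv(file.path(out_dir, "combinations.csv"))
  lines <- c(
    "# Subset approximation of the aversive core (D)",
    "",
    sprintf("Traits: %d; subsets of size %d-%d; seed %d.",
            manifest$n_traits, manifest$k_min, manifest$k_max, manifest$seed),
    sprintf("Grand median correlation with full D: %.3f.",
            manifest$overall_median),
    sprintf("Failed reduced fits: %d of %d (excluded from summaries).",
            manifest$n_failed, manifest$n_subsets),
    sprintf("Percentiles: %s.", manifest$percentile_definition),
    "",
    "## Approximation by number of traits combined",
    "",
    paste(utils::capture.output(print(by_k, row.names = FALSE)),
          collapse = "\n"),
    ""
  )
  if (file.exists(file.path(out_dir, "named_sets.csv"))) {
    ns <- utils::read.csv(file.path(out_dir, "named_sets.csv"))
    lines <- c(lines,
      "## Named trait sets vs. same-size combinations", "",
      paste(utils::capture.output(print(ns, row.names = FALSE)),
            collapse = "\n"), "")
  }
  lines <- c(lines,
    "## Per-trait medians (subsets containing the trait)", "",
    paste(utils::capture.output(print(by_trait, row.names = FALSE)),
          collapse = "\n"), "",
    "## Convergence", "",
    sprintf("%d of %d reduced fits converged; %d needed restarts.",
            sum(combos$converged), nrow(combos),
            sum(combos$n_restarts > 0, na.rm = TRUE)),
    "",
    "## Manifest", "",
    "```json",
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    "```"
  )
  writeLines(lines, path)
  invisible(path)
}
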