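#' Analysis configuration
#'
#' Assembles and validates the settings shared by the end-to-end analysis
#' runners. Can be built directly or loaded from a YAML/JSON file with
#' [read_analysis_config()]; explicit arguments override file values.
#'
#' @param point_files Named list (by genotype) of lists with `csv` and
#'   `window` paths to point-pattern inputs; each genotype may list several
#'   eyes (character vectors).
#' @param orientation_file Path to an orientation CSV.
#' @param assay_file Path to a phototaxis assay CSV.
#' @param bin_width,r_max RDF estimation settings, micrometres.
#' @param d_min Hard-core separation for null simulations (mean nipple
#'   diameter), micrometres.
#' @param n_null_sims Number of null simulations per group.
#' @param n_permutations Permutation count for orientation tests.
#' @param seed Integer seed for every stochastic stage.
#' @param mirror_ventral_flag Mirror ventral-eye angles before pooling.
#' @param pure_only Keep only pure-genotype ommatidia (see
#'   [filter_pure_genotype()]).
#' @param out_dir Output directory for reports.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(point_files = NULL, orientation_file = NULL,
                            assay_file = NULL, bin_width = 0.1, r_max = 5,
                            d_min = NULL, n_null_sims = 100,
                            n_permutations = 10000, seed = 1,
                            mirror_ventral_flag = TRUE, pure_only = TRUE,
                            out_dir = ".") {
  cfg <- list(point_files = point_files, orientation_file = orientation_file,
              assay_file = assay_file,
              bin_width = check_positive(bin_width, "bin_width"),
              r_max = check_positive(r_max, "r_max"),
              d_min = if (!is.null(d_min)) check_positive(d_min, "d_min") else NULL,
              n_null_sims = check_count(n_null_sims, "n_null_sims", 1L),
              n_permutations = check_count(n_permutations, "n_permutations", 1L),
              seed = check_count(abs(seed), "seed"),
              mirror_ventral_flag = isTRUE(mirror_ventral_flag),
              pure_only = isTRUE(pure_only),
              out_dir = out_dir)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path A YAML (`.yml`/`.yaml`) or JSON configuration file whose keys
#'   match the arguments of `analysis_config`.
#' @param ... Overrides applied on top of the file values.
#' @export
read_analysis_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(analysis_config, vals)
}

check_input_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("[%s] input file missing: %s", what,
                 if (is.null(path)) "<not set>" else path), call. = FALSE)
  }
  path
}

provenance_block <- function(cfg, stage) {
  list(stage = stage, seed = cfg$seed,
       settings = cfg[c("bin_width", "r_max", "d_min", "n_null_sims",
                        "n_permutations", "mirror_ventral_flag", "pure_only")],
       multiple_comparison_note = "no multiple-comparison adjustment applied across groups")
}

write_report_json <- function(report, cfg, name) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  path <- file.path(cfg$out_dir, paste0(name, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the corneal-nipple spatial-order analysis
#'
#' For each genotype group: loads its point patterns, estimates and averages
#' their RDFs, simulates a density-matched hard-core null ensemble, compares
#' the group curve to the null mean with a paired Wilcoxon test, fits the
#' hard-core disk model, and scores deviation from the null mean by the
#' \eqn{R^2 < 0.9} criterion. Writes one JSON report (plus a per-group CSV
#' of curves) under `cfg$out_dir`.
#'
#' Instead of file paths, `patterns` may supply a named list (by genotype)
#' of [point_pattern()] lists directly, which is the natural entry point for
#' synthetic data.
#'
#' @param cfg An [analysis_config()]; `d_min` must be set.
#' @param patterns Optional in-memory named list of point-pattern lists,
#'   overriding `cfg$point_files`.
#' @return The report, invisibly; a list with one entry per genotype
#'   (`mean_rdf`, `null_mean`, `wilcoxon`, `fit`, `order_score`) plus a
#'   provenance block.
#' @export
run_nipple_analysis <- function(cfg, patterns = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(cfg$d_min)) stop("[nipple] cfg$d_min must be set", call. = FALSE)
  if (is.null(patterns)) {
    if (is.null(cfg$point_files) || length(cfg$point_files) < 2L) {
      stop("[nipple] point-pattern inputs for >= 2 genotypes are required",
           call. = FALSE)
    }
    patterns <- lapply(names(cfg$point_files), function(gt) {
      spec <- cfg$point_files[[gt]]
      mapply(function(csv, win) {
        read_point_pattern(check_input_file(csv, "nipple"),
                           check_input_file(win, "nipple"))
      }, spec$csv, spec$window, SIMPLIFY = FALSE)
    })
    names(patterns) <- names(cfg$point_files)
  }
  if (length(patterns) < 2L) {
    stop("[nipple] >= 2 genotype groups are required", call. = FALSE)
  }
  report <- list(provenance = provenance_block(cfg, "nipple_order"), groups = list())
  gi <- 0L
  for (gt in names(patterns)) {
    gi <- gi + 1L
    curves <- lapply(patterns[[gt]], estimate_rdf,
                     bin_width = cfg$bin_width, r_max = cfg$r_max)
    mean_curve <- average_rdfs(curves)
    ens <- simulate_null_rdfs(patterns[[gt]][[1]], cfg$d_min, cfg$n_null_sims,
                              cfg$bin_width, cfg$r_max,
                              seed = cfg$seed + 1000L * gi)
    wil <- compare_rdf_wilcoxon(mean_curve, ens$mean_curve)
    fit <- tryCatch(fit_hardcore(mean_curve),
                    error = function(e) NULL)
    score <- rdf_r_squared(mean_curve, ens$mean_curve)
    report$groups[[gt]] <- list(
      n_eyes = length(curves),
      mean_rdf = list(r_center_um = mean_curve$r_centers,
                      g_value = mean_curve$g_values),
      null_mean = ens$mean_curve$g_values,
      null_sd = ens$sd_g,
      wilcoxon = unclass(wil),
      fit = if (is.null(fit)) NULL else {
        list(d_um = fit$params$d, A = fit$params$A,
             lambda_um = fit$params$lambda, P_um = fit$params$P,
             r_squared = fit$r_squared, converged = fit$converged)
      },
      order_score = unclass(score)
    )
    df <- data.frame(r_center_um = mean_curve$r_centers,
                     g_value = mean_curve$g_values,
                     null_mean = ens$mean_curve$g_values,
                     null_sd = ens$sd_g)
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    utils::write.csv(df, file.path(cfg$out_dir, paste0("rdf_", gt, ".csv")),
                     row.names = FALSE)
  }
  write_report_json(report, cfg, "nipple_order_report")
  invisible(report)
}

#' Run the ommatidial-orientation analysis
#'
#' Loads (or accepts) a two-genotype orientation table, optionally mirrors
#' ventral-eye angles into the dorsal frame and filters to pure-genotype
#' ommatidia, then reports per-group circular summaries and two stratified
#' permutation tests (Watson U-squared and resultant-length difference).
#' A single-eye dataset is analyzed with a warning (one stratum).
#'
#' @param cfg An [analysis_config()].
#' @param data Optional in-memory orientation data frame overriding
#'   `cfg$orientation_file`.
#' @return The report, invisibly; JSON written under `cfg$out_dir`.
#' @export
run_orientation_analysis <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(data)) {
    path <- check_input_file(cfg$orientation_file, "orientation")
    data <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  data <- validate_orientation_df(data)
  if (cfg$mirror_ventral_flag) data <- mirror_ventral(data)
  if (cfg$pure_only) data <- filter_pure_genotype(data)
  if (length(unique(data$eye_id)) == 1L) {
    warning("[orientation] single eye present; permutation has one stratum",
            call. = FALSE)
  }
  u2 <- stratified_permutation_test(data, "watson_u2",
                                    cfg$n_permutations, cfg$seed)
  rd <- compare_resultant_lengths(data, cfg$n_permutations, cfg$seed + 1L)
  report <- list(
    provenance = provenance_block(cfg, "orientation"),
    per_group = lapply(u2$per_group, unclass),
    watson_u2 = unclass(u2)[c("observed_stat", "p_value", "n_permutations",
                              "statistic_kind")],
    resultant_diff = unclass(rd)[c("observed_stat", "p_value",
                                   "n_permutations", "statistic_kind")],
    n_eyes_used = u2$n_eyes_used
  )
  write_report_json(report, cfg, "orientation_report")
  invisible(report)
}

#' Run the phototaxis analysis
#'
#' Scores every assay by its final-tube fraction and summarizes by genotype
#' and sex.
#'
#' @param cfg An [analysis_config()].
#' @param assays Optional in-memory list of [phototaxis_assay()] objects
#'   overriding `cfg$assay_file`.
#' @return The report, invisibly; JSON and a summary CSV written under
#'   `cfg$out_dir`.
#' @export
run_phototaxis_analysis <- function(cfg, assays = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(assays)) {
    assays <- read_assays_csv(check_input_file(cfg$assay_file, "phototaxis"))
  }
  by_gt <- summarize_by_group(assays, "genotype")
  by_gt_sex <- summarize_by_group(assays, c("genotype", "sex"))
  report <- list(provenance = provenance_block(cfg, "phototaxis"),
                 by_genotype = by_gt, by_genotype_sex = by_gt_sex)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  utils::write.csv(by_gt_sex, file.path(cfg$out_dir, "phototaxis_summary.csv"),
                   row.names = FALSE)
  write_report_json(report, cfg, "phototaxis_report")
  invisible(report)
}

#' Write and read orientation CSVs
#'
#' Columns: `eye_id, ommatidium_id, genotype, angle_deg` (plus any optional
#' columns such as `side` or `pure`).
#'
#' @param data Orientation data frame.
#' @param path CSV path.
#' @return `write_orientation_csv` returns `path` invisibly;
#'   `read_orientation_csv` returns the data frame.
#' @export
write_orientation_csv <- function(data, path) {
  utils::write.csv(validate_orientation_df(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_csv
#' @export
read_orientation_csv <- function(path) {
  if (!file.exists(path)) stop("orientation CSV not found: ", path, call. = FALSE)
  validate_orientation_df(utils::read.csv(path, stringsAsFactors = FALSE))
}
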