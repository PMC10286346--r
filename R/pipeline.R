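# End-to-end orchestration: configuration, stage sequencing, report
# bundle.  Every analysis choice the method leaves open (test
# selection, correlation method, retention rule, rounding, CI method)
# is a config key so a run is fully reproducible from its manifest.

all_stages <- c("screen", "factor", "reliability", "performance")

#' Build a run configuration
#'
#' @param seed integer seed for the generator (ignored when
#'   `cohort_path` is given).
#' @param cohort_path path to a cohort CSV; exactly one of `seed`
#'   generation or `cohort_path` is the input source.
#' @param out_dir output directory for artifacts.
#' @param stages character subset of
#'   `c("screen", "factor", "reliability", "performance")`.
#' @param alpha item-screen significance level.
#' @param correlation_method `"pearson_phi"` or `"tetrachoric"`.
#' @param retention `"kaiser"` or `"fixed_k"` (with `n_components`).
#' @param n_components component count for `retention = "fixed_k"`.
#' @param loading_threshold assignment threshold (default 0.36).
#' @param reliability_floor retention floor (default 0.70).
#' @param convergence_floor scaling-success floor (default 0.40).
#' @param rounding_rule `"floor"` or `"ceiling"` for the cutoff.
#' @param ci_method `"hanley_mcneil"` or `"delong"`.
#' @param rho latent-factor correlation of the generator.
#' @return a list of class `spa_config`.
#' @export
run_config <- function(seed = 7L, cohort_path = NULL, out_dir = NULL,
                       stages = all_stages, alpha = 0.05,
                       correlation_method = "pearson_phi",
                       retention = "kaiser", n_components = NULL,
                       loading_threshold = 0.36,
                       reliability_floor = 0.70,
                       convergence_floor = 0.40,
                       rounding_rule = "floor",
                       ci_method = "hanley_mcneil", rho = 0.3) {
  cfg <- structure(as.list(environment()), class = "spa_config")
  errs <- config_errors(cfg)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

config_errors <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  num_in <- function(x, lo, hi)
    is.numeric(x) && length(x) == 1 && !is.na(x) && x >= lo && x <= hi
  if (!is.null(cfg$cohort_path) && !is.null(cfg$seed) &&
      !identical(cfg$seed, 7L))
    errs <- c(errs,
              "input source must be exclusive: set either seed or cohort_path")
  chk(num_in(cfg$alpha, 0, 1) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(num_in(cfg$loading_threshold, 0, 1),
      "loading_threshold must lie in [0, 1]")
  chk(num_in(cfg$reliability_floor, 0, 1),
      "reliability_floor must lie in [0, 1]")
  chk(num_in(cfg$convergence_floor, 0, 1),
      "convergence_floor must lie in [0, 1]")
  chk(num_in(cfg$rho, -0.999, 0.999), "rho must lie in (-1, 1)")
  chk(isTRUE(cfg$correlation_method %in% c("pearson_phi", "tetrachoric")),
      "correlation_method must be 'pearson_phi' or 'tetrachoric'")
  chk(isTRUE(cfg$retention %in% c("kaiser", "fixed_k")),
      "retention must be 'kaiser' or 'fixed_k'")
  if (identical(cfg$retention, "fixed_k"))
    chk(num_in(cfg$n_components, 1, 50),
        "n_components is required (1..50) for fixed_k retention")
  chk(isTRUE(cfg$rounding_rule %in% c("floor", "ceiling")),
      "rounding_rule must be 'floor' or 'ceiling'")
  chk(isTRUE(cfg$ci_method %in% c("hanley_mcneil", "delong")),
      "ci_method must be 'hanley_mcneil' or 'delong'")
  chk(all(cfg$stages %in% all_stages),
      paste("stages must be a subset of:",
            paste(all_stages, collapse = ", ")))
  errs
}

#' Validate a configuration file
#'
#' Reads a flat YAML key-value document and either returns the
#' validated `spa_config` or stops with every collected error (not
#' just the first).
#'
#' @param path YAML file path.
#' @return a `spa_config`.
#' @export
validate_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config: ",
                                           conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  known <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("invalid configuration:\n  unknown keys: ",
         paste(unknown, collapse = ", "))
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  if (!is.null(raw$seed) && !is.null(raw$cohort_path))
    stop("invalid configuration:\n  ",
         "input source must be exclusive: set either seed or cohort_path")
  do.call(run_config, raw)
}

#' Run the full validation pipeline
#'
#' Generates (or loads) the cohort, then runs the enabled stages in
#' order: item screening, factorability + component extraction +
#' rotation + assignment, reliability/validity item reduction with the
#' merged scale and cutoff, and ROC screening performance.  When
#' `out_dir` is set, each stage writes its artifact files and a run
#' manifest is emitted.
#'
#' @param config a `spa_config` from [run_config()] /
#'   [validate_config()].
#' @return object of class `spa_run_report`: list with `config`,
#'   `cohort`, per-stage results, and `warnings` (degeneracy notes).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "spa_config"))
  warnings <- character(0)
  note <- function(code, msg)
    warnings <<- c(warnings, paste0("[", code, "] ", msg))

  cohort <- if (!is.null(config$cohort_path))
    read_cohort(config$cohort_path)
  else {
    sp <- default_specs()
    generate_cohort(sp$groups, sp$items, seed = config$seed,
                    rho = config$rho)
  }

  out <- list(config = config, cohort = cohort)
  dir_ok <- !is.null(config$out_dir)
  if (dir_ok)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  if (dir_ok && is.null(config$cohort_path))
    write_cohort(cohort, path("cohort.csv"))

  if ("screen" %in% config$stages) {
    out$screen <- screen_items(cohort, alpha = config$alpha)
    if (dir_ok)
      write_screen_report(out$screen, path("item_screen.tsv"),
                          path("item_screen_summary.json"))
  }

  need_factor <- any(c("factor", "reliability", "performance") %in%
                       config$stages)
  if (need_factor) {
    cm <- correlation_matrix(cohort, method = config$correlation_method)
    if (length(cm$degenerate))
      note("degenerate_items",
           paste("zero-variance items:",
                 paste(cm$degenerate, collapse = ", ")))
    out$factorability <- list(
      kmo = tryCatch(kmo_index(cm), error = function(e) {
        note("kmo_undefined", conditionMessage(e)); NA_real_
      }),
      bartlett = tryCatch(bartlett_sphericity(cm), error = function(e) {
        note("bartlett_undefined", conditionMessage(e)); NULL
      }))
    sol <- extract_components(cm, retention = config$retention,
                              k = config$n_components)
    sol <- withCallingHandlers(
      varimax_rotate(sol),
      warning = function(w) {
        note("varimax_nonconvergence", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    out$solution <- sol
    out$assignment <- assign_items(sol, config$loading_threshold)
    if (length(out$assignment$unassigned))
      note("unassigned_items",
           paste(out$assignment$unassigned, collapse = ", "))
    if (dir_ok)
      write_factor_report(sol, out$assignment,
                          json_path = path("factor_solution.json"),
                          tsv_path = path("loadings.tsv"),
                          factorability = list(
                            kmo = out$factorability$kmo,
                            bartlett = out$factorability$bartlett))
  }

  if (any(c("reliability", "performance") %in% config$stages)) {
    out$reliability <- reliability_report(
      cohort, out$assignment,
      reliability_floor = config$reliability_floor,
      convergence_floor = config$convergence_floor)
    retained <- retention_filter(out$reliability,
                                 floor = config$reliability_floor)
    if (length(retained) == 0) {
      note("no_component_retained",
           "no component passed the retention rule")
    } else {
      out$scale <- merge_scale(cohort, out$assignment, retained,
                               rounding_rule = config$rounding_rule)
    }
    if (dir_ok)
      write_reliability_report(out$reliability, out$scale,
                               tsv_path = path("reliability.tsv"),
                               json_path = path("merged_scale.json"))
  }

  if ("performance" %in% config$stages && !is.null(out$scale)) {
    out$performance <- evaluate_all(cohort, out$scale,
                                    ci_method = config$ci_method)
    for (a in out$performance)
      if (length(a$operating$flags))
        note("operating_point_degenerate",
             paste(a$comparison, a$operating$flags, collapse = " "))
    if (dir_ok) write_roc_report(out$performance, config$out_dir)
  }

  out$warnings <- warnings
  if (dir_ok) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("spascreen")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = config_as_list(config),
      warnings = warnings)
    jsonlite::write_json(manifest, path("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(out, class = "spa_run_report")
}

config_as_list <- function(cfg) {
  x <- unclass(cfg)
  x[!vapply(x, is.null, TRUE)]
}

#' @export
print.spa_run_report <- function(x, ...) {
  cat("Pipeline run (seed ",
      if (!is.null(x$config$cohort_path)) "from file" else x$config$seed,
      ")\n", sep = "")
  if (!is.null(x$screen)) print(x$screen)
  if (!is.null(x$factorability) && !is.na(x$factorability$kmo))
    cat(sprintf("KMO %.3f; Bartlett chi2 %.1f (df %d, p %.3g)\n",
                x$factorability$kmo, x$factorability$bartlett$chi2,
                x$factorability$bartlett$df, x$factorability$bartlett$p))
  if (!is.null(x$assignment)) print(x$assignment)
  if (!is.null(x$scale)) print(x$scale)
  if (!is.null(x$performance)) print(x$performance)
  if (length(x$warnings))
    cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Score a cohort file against a saved scale
#'
#' Reads a cohort CSV and a merged-scale JSON (as written by
#' [write_reliability_report()] or [run_pipeline()]), scores every
#' subject and writes a referral TSV.
#'
#' @param cohort_path cohort CSV path.
#' @param scale_path merged-scale JSON path.
#' @param out_path output TSV path (`NULL` for no file).
#' @return the referral data.frame, invisibly.
#' @export
score_command <- function(cohort_path, scale_path, out_path = NULL) {
  cohort <- read_cohort(cohort_path)
  sc <- jsonlite::read_json(scale_path, simplifyVector = TRUE)
  if (is.null(sc$items) || is.null(sc$cutoff))
    stop("scale file must contain 'items' and 'cutoff'")
  res <- score_subjects(cohort, list(items = sc$items,
                                     cutoff = sc$cutoff))
  if (!is.null(out_path))
    utils::write.table(res, out_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(res)
}
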