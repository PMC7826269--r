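fits_to_cleanex_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    s <- f$site
    data.frame(duplex = s$duplex_id, position = s$position, base = s$base,
               partner_mod = s$partner_modification %||% "",
               k1h = f$k1h, k1h_err = f$k1h_err, ra = f$ra,
               ra_err = f$ra_err, rb = f$rb, rb_err = f$rb_err,
               chi2_reduced = f$chi2_reduced, detected = f$detected)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

fits_to_exchange_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    s <- f$site
    data.frame(duplex = s$duplex_id, position = s$position, base = s$base,
               partner_mod = s$partner_modification %||% "",
               r20 = f$r20, r20_err = f$r20_err, kex = f$kex,
               kex_err = f$kex_err, phi_ex = f$phi_ex,
               phi_ex_err = f$phi_ex_err, pb = f$pb, dw = f$dw,
               chi2_reduced = f$chi2_reduced,
               rex_observed = f$rex_observed,
               mode = f$parameterization_mode)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

summaries_to_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    st <- s$site
    data.frame(duplex = st$duplex_id, position = st$position,
               base = st$base,
               partner_mod = st$partner_modification %||% "",
               k1h_norm = s$k1h_norm, k1h_norm_err = s$k1h_norm_err,
               kclose = s$kclose_approx, kclose_err = s$kclose_err,
               rel_kopen_index = s$rel_kopen_index, ex2_ok = s$ex2_ok)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fit every build-up curve of a study table
#'
#' @param tab A data frame in the `buildup` schema.
#' @param control A [cleanex_control()]; per-site Monte-Carlo seeds are
#'   derived from `control$seed` deterministically.
#' @return Named list of [cleanex_fit()] objects.
#' @export
fit_cleanex_table <- function(tab, control = cleanex_control()) {
  curves <- buildup_curves(tab)
  fits <- vector("list", length(curves))
  names(fits) <- names(curves)
  for (i in seq_along(curves)) {
    ctl <- control
    ctl$seed <- control$seed + i
    fits[[i]] <- fit_cleanex(curves[[i]], ctl)
  }
  fits
}

#' Fit every dispersion curve of a study table
#'
#' @param tab A data frame in the `dispersion` schema.
#' @param control A [dispersion_control()].
#' @return Named list of [exchange_fit()] objects.
#' @export
fit_dispersion_table <- function(tab, control = dispersion_control()) {
  curves <- dispersion_curves(tab)
  fits <- vector("list", length(curves))
  names(fits) <- names(curves)
  for (i in seq_along(curves)) {
    ctl <- control
    ctl$seed <- control$seed + i
    fits[[i]] <- fit_dispersion(curves[[i]], ctl)
  }
  fits
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> fit-cleanex -> fit-dispersion ->
#' normalize -> combine -> report. Either both input tables are supplied,
#' or `simulate = TRUE` generates them from the configuration's design
#' and the default ground truths. Dispersion data may be omitted, in
#' which case the summaries carry `NA` closing rates (partial-data
#' contract). When `out_dir` is given, all tables, a JSON manifest
#' (config hash, seed, package version, every defaulted parameter) and a
#' stage log are written; outputs are byte-identical across runs with the
#' same configuration and seed. A failing stage halts the pipeline with
#' an error naming the stage.
#'
#' @param config A [study_config()] (or `NULL`/list/path accepted by it).
#' @param out_dir Optional output directory (created if needed).
#' @param buildup Optional data frame or path, `buildup` schema.
#' @param dispersion Optional data frame or path, `dispersion` schema.
#' @param simulate Logical; generate synthetic inputs (default when no
#'   `buildup` is supplied).
#' @return A list of class `"pipeline_result"` with the fit lists, the
#'   kinetics summaries, the comparative report and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, buildup = NULL,
                         dispersion = NULL, simulate = is.null(buildup)) {
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  truths <- NULL
  if (simulate) {
    study <- stage("simulate", {
      design <- config_design(cfg)
      truths <- default_ground_truths(design,
                                      noise_sigma = cfg$design$noise_sigma)
      generate_study(design, truths, seed = cfg$seed)
    })
    buildup_tab <- study$buildup
    dispersion_tab <- study$dispersion
    note("simulate: %d build-up rows, %d dispersion rows, seed %d",
         nrow(buildup_tab), nrow(dispersion_tab), cfg$seed)
  } else {
    if (is.null(buildup))
      stop_invalid("either supply a buildup table or set simulate = TRUE")
    buildup_tab <- stage("read-buildup",
      if (is.character(buildup)) read_table(buildup, "buildup")
      else buildup)
    dispersion_tab <- if (is.null(dispersion)) NULL else
      stage("read-dispersion",
        if (is.character(dispersion)) read_table(dispersion, "dispersion")
        else dispersion)
    note("inputs: %d build-up rows, %s dispersion rows",
         nrow(buildup_tab),
         if (is.null(dispersion_tab)) "no" else nrow(dispersion_tab))
  }

  cx_control <- cleanex_control(error_method = cfg$fit$error_method,
                                mc_draws = cfg$fit$mc_draws,
                                seed = cfg$seed)
  cx_fits <- stage("fit-cleanex", fit_cleanex_table(buildup_tab, cx_control))
  note("fit-cleanex: %d sites, %d detected", length(cx_fits),
       sum(vapply(cx_fits, `[[`, logical(1), "detected")))

  ex_fits <- NULL
  if (!is.null(dispersion_tab)) {
    di_control <- dispersion_control(mode = cfg$fit$mode,
                                     pb_fixed = cfg$fit$pb,
                                     error_method = cfg$fit$error_method,
                                     mc_draws = cfg$fit$mc_draws,
                                     seed = cfg$seed + 10000L)
    ex_fits <- stage("fit-dispersion",
                     fit_dispersion_table(dispersion_tab, di_control))
    note("fit-dispersion: %d sites, %d with Rex", length(ex_fits),
         sum(vapply(ex_fits, `[[`, logical(1), "rex_observed")))
  }

  pka <- config_pka(cfg)
  summaries <- stage("normalize-combine", {
    lapply(names(cx_fits), function(key) {
      f <- cx_fits[[key]]
      norm <- normalize_k1h(f, table = pka,
                            convention = cfg$normalization)
      combine_kinetics(norm, ex_fits[[key]], f$site,
                       ex2_threshold = cfg$ex2_threshold)
    })
  })
  note("normalize-combine: %d summaries (%s convention)",
       length(summaries), cfg$normalization)

  report <- stage("report", {
    ref <- cfg$reference_duplex
    present <- unique(vapply(summaries,
                             function(s) s$site$duplex_id, character(1)))
    if (!ref %in% present) ref <- present[1]
    comparative_report(summaries, ref)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("iminokinetics")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    simulated = simulate,
    truths = if (simulate) study$manifest$truths else NULL,
    log = log_lines)

  result <- structure(
    list(cleanex_fits = cx_fits, exchange_fits = ex_fits,
         summaries = summaries, report = report,
         buildup = buildup_tab, dispersion = dispersion_tab,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(buildup_tab, file.path(out_dir, "buildup.tsv"), "buildup")
    if (!is.null(dispersion_tab))
      write_table(dispersion_tab, file.path(out_dir, "dispersion.tsv"),
                  "dispersion")
    write_table(fits_to_cleanex_table(cx_fits),
                file.path(out_dir, "cleanex_fits.tsv"), "cleanex_fit")
    if (!is.null(ex_fits))
      write_table(fits_to_exchange_table(ex_fits),
                  file.path(out_dir, "exchange_fits.tsv"), "exchange_fit")
    write_table(summaries_to_table(summaries),
                file.path(out_dir, "kinetics.tsv"), "kinetics")
    report_out <- report
    report_out$ex2_ok <- as.character(report_out$ex2_ok)
    utils::write.table(report_out, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d cleanex fits, %s exchange fits, %d summaries\n",
              length(x$cleanex_fits),
              if (is.null(x$exchange_fits)) "no"
              else length(x$exchange_fits),
              length(x$summaries)))
  invisible(x)
}
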