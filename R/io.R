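table_schemas <- list(
  buildup = list(
    columns = c("duplex", "position", "base", "partner_mod", "tau_m_s",
                "ratio", "ratio_err"),
    numeric = c("position", "tau_m_s", "ratio", "ratio_err"),
    checks = list(
      tau_m_s = function(v) v > 0,
      ratio = function(v) v >= 0,
      ratio_err = function(v) v > 0)),
  dispersion = list(
    columns = c("duplex", "position", "base", "partner_mod", "nu1_hz",
                "r1rho_s", "r1rho_err_s", "T_s"),
    numeric = c("position", "nu1_hz", "r1rho_s", "r1rho_err_s", "T_s"),
    checks = list(
      nu1_hz = function(v) v > 0,
      r1rho_s = function(v) v > 0,
      r1rho_err_s = function(v) v > 0,
      T_s = function(v) v > 0)),
  cleanex_fit = list(
    columns = c("duplex", "position", "base", "partner_mod", "k1h",
                "k1h_err", "ra", "ra_err", "rb", "rb_err", "chi2_reduced",
                "detected"),
    numeric = c("position", "k1h", "k1h_err", "ra", "ra_err", "rb",
                "rb_err", "chi2_reduced"),
    checks = list()),
  exchange_fit = list(
    columns = c("duplex", "position", "base", "partner_mod", "r20",
                "r20_err", "kex", "kex_err", "phi_ex", "phi_ex_err", "pb",
                "dw", "chi2_reduced", "rex_observed", "mode"),
    numeric = c("position", "r20", "r20_err", "kex", "kex_err", "phi_ex",
                "phi_ex_err", "pb", "dw", "chi2_reduced"),
    checks = list()),
  kinetics = list(
    columns = c("duplex", "position", "base", "partner_mod", "k1h_norm",
                "k1h_norm_err", "kclose", "kclose_err", "rel_kopen_index",
                "ex2_ok"),
    numeric = c("position", "k1h_norm", "k1h_norm_err", "kclose",
                "kclose_err", "rel_kopen_index"),
    checks = list()))

#' Read an interchange table
#'
#' Reads a tab-delimited interchange table with a mandatory header and
#' `#` comment lines. Windows line endings are tolerated. The column set
#' must match the schema exactly; numeric columns are validated cell by
#' cell and schema-specific range checks (e.g. positive mixing times) are
#' applied, reporting the offending row on failure.
#'
#' @param path Path to the file.
#' @param schema One of `"buildup"`, `"dispersion"`, `"cleanex_fit"`,
#'   `"exchange_fit"`, `"kinetics"`.
#' @return A data frame with the schema's columns.
#' @seealso [write_table()]
#' @export
read_table <- function(path, schema) {
  sch <- table_schemas[[match.arg(schema, names(table_schemas))]]
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  names(tab) <- sub("\r$", "", names(tab))
  for (j in seq_along(tab)) tab[[j]] <- sub("\r$", "", tab[[j]])
  missing <- setdiff(sch$columns, names(tab))
  unknown <- setdiff(names(tab), sch$columns)
  if (length(missing) || length(unknown))
    stop_invalid("schema mismatch for '", schema, "': ",
                 if (length(missing))
                   paste0("missing column(s) ",
                          paste(missing, collapse = ", "), "; ") else "",
                 if (length(unknown))
                   paste0("unknown column(s) ",
                          paste(unknown, collapse = ", ")) else "")
  tab <- tab[sch$columns]
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & nzchar(tab[[col]]))
    if (length(bad))
      stop_invalid("non-numeric value '", tab[[col]][bad[1]],
                   "' in column '", col, "', row ", bad[1])
    tab[[col]] <- v
  }
  for (col in names(sch$checks)) {
    ok <- sch$checks[[col]](tab[[col]])
    if (any(!ok))
      stop_invalid("invalid value in column '", col, "', row ",
                   which(!ok)[1], " (", tab[[col]][which(!ok)[1]], ")")
  }
  if ("detected" %in% names(tab)) tab$detected <- as.logical(tab$detected)
  if ("rex_observed" %in% names(tab))
    tab$rex_observed <- as.logical(tab$rex_observed)
  if ("ex2_ok" %in% names(tab)) tab$ex2_ok <- as.logical(tab$ex2_ok)
  tab
}

#' Write an interchange table
#'
#' Writes a data frame as a tab-delimited interchange table with a header
#' row; numeric columns are serialized at full double precision so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param tab Data frame matching the schema's columns.
#' @param path Output path.
#' @param schema Schema name, see [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, schema) {
  sch <- table_schemas[[match.arg(schema, names(table_schemas))]]
  missing <- setdiff(sch$columns, names(tab))
  if (length(missing))
    stop_invalid("cannot write '", schema, "' table: missing column(s) ",
                 paste(missing, collapse = ", "))
  out <- tab[sch$columns]
  for (col in sch$numeric)
    out[[col]] <- vapply(out[[col]], function(v)
      if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a build-up table into curves
#'
#' @param tab A data frame in the `buildup` schema.
#' @return Named list of [build_up_curve()] objects, keyed
#'   `"duplex:position"`.
#' @export
buildup_curves <- function(tab) {
  split_rows <- split(tab, paste(tab$duplex, tab$position, sep = ":"))
  lapply(split_rows, function(rows) {
    rows <- rows[order(rows$tau_m_s), ]
    mod <- if (rows$base[1] == "T") NULL else rows$partner_mod[1]
    site <- duplex_site(rows$duplex[1], rows$position[1], rows$base[1], mod)
    build_up_curve(site, rows$tau_m_s, rows$ratio, rows$ratio_err)
  })
}

#' Split a dispersion table into curves
#'
#' @param tab A data frame in the `dispersion` schema.
#' @return Named list of [dispersion_curve()] objects, keyed
#'   `"duplex:position"`.
#' @export
dispersion_curves <- function(tab) {
  split_rows <- split(tab, paste(tab$duplex, tab$position, sep = ":"))
  lapply(split_rows, function(rows) {
    rows <- rows[order(rows$nu1_hz), ]
    mod <- if (rows$base[1] == "T") NULL else rows$partner_mod[1]
    site <- duplex_site(rows$duplex[1], rows$position[1], rows$base[1], mod)
    dispersion_curve(site, rows$nu1_hz, rows$r1rho_s, rows$r1rho_err_s,
                     rows$T_s[1])
  })
}

config_defaults <- function() {
  list(
    seed = 1L,
    reference_duplex = "C/C",
    design = list(
      duplexes = default_duplexes,
      positions = 6:9,
      mixing_times_ms = c(5, 10, 15, 20, 50, 100, 200),
      spinlock_min_khz = 0.5,
      spinlock_max_khz = 15,
      spinlock_points = 12L,
      relax_period_s = 0.02,
      sequence = "GTGACACGTGTC",
      baseline_sigma = 0.0035,
      noise_sigma = 0.0015),
    fit = list(
      mode = "fast_exchange",
      pb = 0.001,
      error_method = "mc",
      mc_draws = 200L),
    normalization = "paper_rounded",
    pka = list(C = 4.5, `5mC` = 4.4, `5hmC` = 4.0, N1G = 9.4),
    ex2_threshold = 1000)
}

check_known_keys <- function(given, known, where) {
  unknown <- setdiff(names(given), known)
  if (length(unknown))
    stop_invalid("unknown configuration key", if (length(unknown) > 1) "s",
                 " in ", where, ": ", paste(unknown, collapse = ", "))
}

#' Build or load a study configuration
#'
#' A validated configuration governing the whole pipeline: study design,
#' fit settings, normalization convention, pKa overrides and the EX2
#' threshold. Any key not understood is rejected with a message naming
#' it. A single `seed` governs every stochastic step (noise generation
#' and Monte-Carlo error draws), split deterministically per stage.
#'
#' @param x `NULL` for the defaults, a named list of overrides, or the
#'   path to a YAML file with the same structure.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(x = NULL) {
  cfg <- config_defaults()
  if (is.character(x)) {
    if (!file.exists(x)) stop_invalid("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.null(x)) {
    stopifnot(is.list(x))
    check_known_keys(x, names(cfg), "config")
    for (key in intersect(names(x), c("design", "fit")))
      check_known_keys(x[[key]], names(cfg[[key]]),
                       paste0("config$", key))
    if ("pka" %in% names(x))
      check_known_keys(x$pka, c(modification_states, "N1G"), "config$pka")
    cfg <- modifyList(cfg, x)
  }
  if (cfg$fit$pb <= 0 || cfg$fit$pb > 0.5)
    stop_invalid("fit$pb = ", cfg$fit$pb,
                 " exceeds the minor-state bound (0, 0.5]")
  if (!cfg$fit$mode %in% c("fast_exchange", "full"))
    stop_invalid("fit$mode must be fast_exchange or full")
  if (!cfg$normalization %in% c("paper_rounded", "full_precision"))
    stop_invalid("normalization must be paper_rounded or full_precision")
  if (!cfg$fit$error_method %in% c("mc", "covariance"))
    stop_invalid("fit$error_method must be mc or covariance")
  structure(cfg, class = "study_config")
}

#' Materialize the acquisition design of a configuration
#'
#' @param cfg A [study_config()].
#' @return A [study_design()].
#' @export
config_design <- function(cfg) {
  d <- cfg$design
  study_design(
    duplexes = d$duplexes, positions = d$positions,
    mixing_times = d$mixing_times_ms / 1000,
    spinlock_nu1 = exp(seq(log(d$spinlock_min_khz * 1000),
                           log(d$spinlock_max_khz * 1000),
                           length.out = d$spinlock_points)),
    relax_period = d$relax_period_s, baseline_sigma = d$baseline_sigma,
    sequence = d$sequence)
}

#' Materialize the pKa table of a configuration
#'
#' @param cfg A [study_config()].
#' @return A [pka_table()].
#' @export
config_pka <- function(cfg) {
  p <- cfg$pka
  n3 <- unlist(p[setdiff(names(p), "N1G")])
  pka_table(pka_n3 = n3, pka_n1_g = p$N1G)
}
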