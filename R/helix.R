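#' Read a helical-parameter trajectory table
#'
#' Reads per-frame DNA helical-parameter tables as produced by 3DNA-style
#' trajectory analysis, in a simple long-format delimited dialect with
#' columns `frame`, `position`, `parameter`, `value` (angles in degrees),
#' or an already-loaded data frame with those columns. Wide tables with
#' one column per parameter (`frame`, `position`, then parameter columns)
#' are reshaped automatically.
#'
#' @param x Path to a tab-delimited file, or a data frame.
#' @return A data frame of class `"helical_trajectory"` with columns
#'   `frame`, `position`, `parameter`, `value`.
#' @export
helical_trajectory <- function(x) {
  tab <- if (is.character(x)) {
    read.delim(x, comment.char = "#", check.names = FALSE,
               stringsAsFactors = FALSE)
  } else as.data.frame(x)
  if (!all(c("frame", "position") %in% names(tab)))
    stop_invalid("a helical trajectory table needs 'frame' and ",
                 "'position' columns")
  if (!all(c("parameter", "value") %in% names(tab))) {
    # wide dialect: every remaining column is one helical parameter
    value_cols <- setdiff(names(tab), c("frame", "position"))
    if (!length(value_cols))
      stop_invalid("no parameter columns found")
    long <- do.call(rbind, lapply(value_cols, function(p) {
      data.frame(frame = tab$frame, position = tab$position,
                 parameter = p, value = as.numeric(tab[[p]]))
    }))
    tab <- long
  }
  if (!is.numeric(tab$value) || any(!is.finite(tab$value)))
    stop_invalid("helical parameter values must all be finite")
  class(tab) <- c("helical_trajectory", "data.frame")
  tab
}

#' Summarize a helical-parameter trajectory
#'
#' Arithmetic mean and sample (n-1) standard deviation of every helical
#' parameter at every base-pair position across trajectory frames, for
#' comparing the width of angular-parameter distributions between
#' differently modified duplexes. Positions with missing frames for a
#' parameter are summarized over the frames present, never imputed.
#'
#' @param table A [helical_trajectory()] (or anything it accepts).
#' @param reference Optional second trajectory; when given, difference
#'   columns `d_mean` and `d_sd` (this minus reference) are appended for
#'   matching (position, parameter) cells.
#' @return A data frame with columns `position`, `parameter`, `n_frames`,
#'   `mean`, `sd` (and `d_mean`, `d_sd` when `reference` is given).
#' @export
summarize_helical <- function(table, reference = NULL) {
  tab <- helical_trajectory(table)
  if (length(unique(tab$frame)) < 2)
    stop_invalid("at least 2 frames are required")
  agg <- aggregate(value ~ position + parameter, data = tab,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  out <- data.frame(position = agg$position, parameter = agg$parameter,
                    n_frames = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  out <- out[order(out$parameter, out$position), ]
  rownames(out) <- NULL
  if (!is.null(reference)) {
    ref <- summarize_helical(reference)
    key <- paste(out$position, out$parameter)
    ref_key <- paste(ref$position, ref$parameter)
    idx <- match(key, ref_key)
    out$d_mean <- out$mean - ref$mean[idx]
    out$d_sd <- out$sd - ref$sd[idx]
  }
  out
}
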