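hills_columns <- function(ncv) {
  c("time", paste0("cv", seq_len(ncv)), paste0("sigma_cv", seq_len(ncv)),
    "height", "biasf")
}

#' Hills log: time-ordered Gaussian depositions
#'
#' Tibble of deposited metadynamics hills, one row per hill, with columns
#' `time` (ps, strictly increasing), `cv1` (and `cv2` for two-CV runs),
#' `sigma_cv1` (`sigma_cv2`), `height` (kJ mol^-1, > 0) and `biasf` (the
#' bias factor, constant across the log). This mirrors the PLUMED HILLS
#' table dialect read and written by [read_hills()] / [write_hills()].
#'
#' @param df A data frame with the columns above.
#' @param temperature Temperature associated with the run, K (metadata).
#' @return A tibble of class `hills_log`.
#' @export
hills_log <- function(df, temperature = 300) {
  ncv <- if ("cv2" %in% names(df)) 2L else 1L
  cols <- hills_columns(ncv)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort(paste0("hills table lacks column(s): ", paste(missing, collapse = ", ")))
  df <- as_tibble(df[, cols])
  if (nrow(df) > 0) {
    if (any(diff(df$time) <= 0)) abort("hill times must be strictly increasing")
    if (any(df$height <= 0)) abort("hill heights must be > 0")
    sig <- as.matrix(df[, paste0("sigma_cv", seq_len(ncv)), drop = FALSE])
    if (any(sig <= 0)) abort("hill widths must be > 0")
    if (length(unique(df$biasf)) > 1)
      abort("bias factor must be constant across a hills log")
  }
  attr(df, "ncv") <- ncv
  attr(df, "temperature") <- temperature
  class(df) <- c("hills_log", class(df))
  df
}

empty_hills_log <- function(ncv, temperature = 300) {
  cols <- hills_columns(ncv)
  df <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  attr(df, "ncv") <- as.integer(ncv)
  attr(df, "temperature") <- temperature
  class(df) <- c("hills_log", class(df))
  df
}

hills_ncv <- function(hills) {
  attr(hills, "ncv") %||% (if ("cv2" %in% names(hills)) 2L else 1L)
}

hills_bias_factor <- function(hills) {
  if (nrow(hills) > 0) hills$biasf[1] else NA_real_
}
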