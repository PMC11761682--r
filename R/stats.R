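# Correlation analyses relating clone prevalence to Sanger hit frequency
# and to measured affinity.

#' Pearson correlation with optional log10 transforms
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param log_x,log_y log10-transform the variable first (values must then
#'   be strictly positive).
#' @return list with `r` and `r_squared`.
#' @export
pearson_r2 <- function(x, y, log_x = FALSE, log_y = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (log_x) {
    if (any(x <= 0)) stop("log transform requires strictly positive x")
    x <- log10(x)
  }
  if (log_y) {
    if (any(y <= 0)) stop("log transform requires strictly positive y")
    y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(x, y, method = "pearson")
  list(r = r, r_squared = r^2)
}

#' Prevalence-versus-affinity correlation table
#'
#' Pairs each clone's NGS repeat count with its measured dissociation
#' constant and reports the Pearson correlation under three axis
#' conventions -- raw repeats vs log10 KD (primary), both raw, and both
#' log10 -- because an R-squared is only interpretable together with its
#' axis scaling, and conventions differ across reports.
#'
#' @param records data.frame with columns `clone_id`, `kd` (molar, > 0) and
#'   `ngs_repeats` (>= 0); at least 3 rows.
#' @return list with `table` (the paired values) and `correlations`
#'   (data.frame variant, r, r_squared).
#' @export
prevalence_affinity_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("clone_id", "kd", "ngs_repeats") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 clones")
  if (any(records$kd <= 0)) stop("kd must be strictly positive")
  if (any(records$ngs_repeats < 0)) stop("ngs_repeats must be non-negative")
  tab <- records[, c("clone_id", "ngs_repeats", "kd")]
  variants <- list(
    raw_vs_log10kd = list(log_x = FALSE, log_y = TRUE),
    raw_vs_raw = list(log_x = FALSE, log_y = FALSE),
    log10_vs_log10 = list(log_x = TRUE, log_y = TRUE)
  )
  rows <- lapply(names(variants), function(v) {
    tr <- variants[[v]]
    if ((tr$log_x && any(tab$ngs_repeats <= 0)))
      return(data.frame(variant = v, r = NA_real_, r_squared = NA_real_))
    p <- pearson_r2(tab$ngs_repeats, tab$kd, log_x = tr$log_x,
                    log_y = tr$log_y)
    data.frame(variant = v, r = p$r, r_squared = p$r_squared,
               stringsAsFactors = FALSE)
  })
  list(table = tab, correlations = do.call(rbind, rows))
}
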