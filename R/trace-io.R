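#' Write an MCMC trace as tab-separated text
#'
#' One header row plus one row per recorded generation, full double
#' precision (17 significant digits).
#'
#' @param trace Data frame of trace records (as in `im_fit$trace`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!is.data.frame(trace) || !nrow(trace))
    stop("trace must be a nonempty data frame")
  out <- vapply(trace, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col),
    character(nrow(trace)))
  if (nrow(trace) == 1L) out <- matrix(out, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(trace), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_trace <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Posterior summaries of the six IM parameters
#'
#' For each parameter: posterior mean, histogram-mode estimate (midpoint of
#' the highest-count bin among `bins` equal-width bins spanning
#' `[0, bound]`), and the central 90% credible interval.
#'
#' @param trace Trace data frame containing the six parameter columns.
#' @param priors [im_priors()] supplying the histogram range.
#' @param bins Number of histogram bins (>= 2).
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(trace, priors = im_priors(), bins = 50L) {
  if (!nrow(trace)) stop("empty trace")
  if (bins < 2L) stop("bins must be >= 2")
  b <- unclass(priors)[PAR_NAMES]
  rows <- lapply(PAR_NAMES, function(pn) {
    x <- trace[[pn]]
    brk <- seq(0, b[[pn]], length.out = bins + 1L)
    cnt <- tabulate(pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                              1L), bins), bins)
    mode_mid <- (brk[which.max(cnt)] + brk[which.max(cnt) + 1L]) / 2
    qq <- quantile(x, c(0.05, 0.95), names = FALSE)
    data.frame(parameter = pn, mean = mean(x), mode = mode_mid,
               q05 = qq[1L], q95 = qq[2L])
  })
  do.call(rbind, rows)
}

#' Write posterior summaries as tab-separated text
#'
#' @inheritParams posterior_summary
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(trace, priors = im_priors(), bins = 50L,
                                    path) {
  s <- posterior_summary(trace, priors, bins)
  write.table(format(s, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
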