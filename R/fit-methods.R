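#' @export
print.im_fit <- function(x, ...) {
  cat("Isolation-with-migration MCMC fit\n")
  cat(sprintf("  loci: %s\n",
              paste(sprintf("%s (%s, %s)", x$data_summary$loci,
                            x$data_summary$models, x$data_summary$sizes),
                    collapse = ", ")))
  cat(sprintf("  chains: %d, burn-in %d, sampling %d (thin %d), seed %d\n",
              x$n_chains, x$burn_in, x$generations, x$sample_every, x$seed))
  cat(sprintf("  acceptance: parameters %.2f, genealogies %.2f%s\n",
              x$acceptance[["params"]], x$acceptance[["trees"]],
              if (!is.na(x$swap_rate))
                sprintf(", swaps %.2f", x$swap_rate) else ""))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.im_fit <- function(object, ...) {
  vapply(PAR_NAMES, function(pn) mean(object$trace[[pn]]), numeric(1))
}

#' @export
summary.im_fit <- function(object, bins = 50L, ...) {
  s <- posterior_summary(object$trace, object$priors, bins)
  s$sd <- vapply(PAR_NAMES, function(pn) sd(object$trace[[pn]]), numeric(1))
  structure(list(table = s[, c("parameter", "mean", "sd", "mode",
                               "q05", "q95")],
                 acceptance = object$acceptance,
                 swap_rate = object$swap_rate,
                 n_samples = nrow(object$trace)),
            class = "summary.im_fit")
}

#' @export
print.summary.im_fit <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d samples)\n", x$n_samples))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("acceptance: parameters %.2f, genealogies %.2f\n",
              x$acceptance[["params"]], x$acceptance[["trees"]]))
  invisible(x)
}

#' @export
plot.im_fit <- function(x, which = PAR_NAMES, ...) {
  op <- par(mfrow = c(length(which), 2L), mar = c(3.5, 3.5, 1.5, 0.5),
            mgp = c(2, 0.7, 0))
  on.exit(par(op))
  for (pn in which) {
    v <- x$trace[[pn]]
    plot.default(x$trace$generation, v, type = "l", xlab = "generation",
                 ylab = pn, ...)
    hist(v, breaks = 40, main = "", xlab = pn, freq = FALSE)
    abline(v = mean(v), col = 2, lwd = 2)
  }
  invisible(x)
}
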