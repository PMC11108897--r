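#' Random-matrix-theory choice of the correlation cutoff
#'
#' Scans a grid of candidate cutoffs. At each cutoff `t` the correlation
#' matrix is hard-thresholded (entries with `|r| < t` zeroed, unit
#' diagonal kept) and its eigenvalue nearest-neighbour spacing
#' distribution (NNSD) is examined. A dense, noise-dominated matrix
#' follows Gaussian orthogonal ensemble (GOE, Wigner-Dyson) statistics;
#' once the cutoff removes the noise and only modular structure remains,
#' the NNSD collapses to Poisson statistics. The chosen threshold is the
#' smallest grid point whose NNSD fits the Poisson law better than the
#' GOE law with an acceptable chi-square.
#'
#' Degenerate eigenvalues are collapsed before unfolding; the cumulative
#' spectral function is unfolded by smoothing the eigenvalue-rank curve
#' (cubic smoothing spline), and spacings are normalised to unit mean.
#'
#' @param corr A `corr_matrix` (dimension >= 30 for a meaningful
#'   spectrum).
#' @param grid Ascending candidate thresholds within `(0, 1)`.
#' @param bins Number of chi-square bins for the NNSD comparison.
#' @param alpha Significance level for the Poisson goodness-of-fit
#'   critical value.
#' @return Object of class `rmt_scan`: data frame `scan` with per-threshold
#'   `threshold`, `n_eigen` (distinct eigenvalues), `chisq_poisson`,
#'   `chisq_goe`, `usable`; plus `chosen_threshold` (`NA` if no grid point
#'   qualifies) and `critical_value`.
#' @export
rmt_threshold <- function(corr, grid = seq(0.2, 0.8, by = 0.05), bins = 12,
                          alpha = 0.05) {
  if (any(diff(grid) <= 0) || any(grid < 0) || any(grid >= 1)) {
    stop("grid must be strictly ascending within [0, 1)")
  }
  r <- corr$r
  if (nrow(r) < 30) stop("matrix dimension >= 30 required for spectral statistics")
  crit <- stats::qchisq(1 - alpha, df = bins - 1)
  rows <- lapply(grid, function(t) {
    a <- r
    a[abs(a) < t] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    s <- nnsd_spacings(ev)
    if (is.null(s)) {
      return(data.frame(threshold = t, n_eigen = length(unique(round(ev, 8))),
                        chisq_poisson = NA_real_, chisq_goe = NA_real_,
                        usable = FALSE))
    }
    data.frame(
      threshold = t,
      n_eigen = attr(s, "n_eigen"),
      chisq_poisson = nnsd_chisq(s, "poisson", bins),
      chisq_goe = nnsd_chisq(s, "goe", bins),
      usable = TRUE
    )
  })
  scan <- do.call(rbind, rows)
  ok <- scan$usable & scan$chisq_poisson < scan$chisq_goe &
    scan$chisq_poisson < crit
  chosen <- if (any(ok)) scan$threshold[which(ok)[1]] else NA_real_
  structure(
    list(scan = scan, chosen_threshold = chosen, critical_value = crit,
         bins = bins),
    class = "rmt_scan"
  )
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("rmt_scan over %d thresholds; chosen = %s\n",
              nrow(x$scan),
              if (is.na(x$chosen_threshold)) "none" else
                format(x$chosen_threshold)))
  invisible(x)
}

# Unfolded nearest-neighbour spacings of an eigenvalue set, or NULL when
# fewer than 20 distinct eigenvalues remain (degenerate spectrum).
nnsd_spacings <- function(ev, min_eigen = 20L) {
  ev <- sort(unique(round(ev, 8)))
  n <- length(ev)
  if (n < min_eigen) return(NULL)
  df <- min(10, max(4, floor(n / 10)))
  fit <- stats::smooth.spline(ev, seq_len(n), df = df)
  unfolded <- stats::predict(fit, ev)$y
  s <- pmax(diff(unfolded), 0)
  s <- s / mean(s)
  attr(s, "n_eigen") <- n
  s
}

# Chi-square distance between the empirical NNSD and a reference law,
# using equal-width bins on [0, 3] plus an open tail bin.
nnsd_chisq <- function(s, law = c("poisson", "goe"), bins = 12) {
  law <- match.arg(law)
  breaks <- c(seq(0, 3, length.out = bins), Inf)
  cdf <- if (law == "poisson") {
    function(x) 1 - exp(-x)
  } else {
    function(x) 1 - exp(-pi * x^2 / 4)
  }
  pr <- diff(vapply(breaks, function(b) if (is.infinite(b)) 1 else cdf(b),
                    numeric(1)))
  obs <- tabulate(findInterval(s, breaks), nbins = length(breaks) - 1)
  expct <- length(s) * pr
  keep <- expct > 1e-12
  sum((obs[keep] - expct[keep])^2 / expct[keep])
}
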