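#' Coefficient of variation, percent
#'
#' 100 times the sample standard deviation (n-1 denominator) over the mean.
#' Requires at least two values and a positive mean.
#'
#' @param values numeric vector.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for a CV")
  100 * sd(values) / m
}

#' Pearson correlation with a two-sided p value
#'
#' Product-moment correlation; the p value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-degenerate.
#' @return object of class `strucell_cor`: `r`, `r_squared`, `p_two_sided`,
#'   `n`.
#' @export
pearson <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate (zero-variance) input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, r_squared = r^2, p_two_sided = p, n = n),
            class = "strucell_cor")
}

#' @export
print.strucell_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (R^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_two_sided, x$n))
  invisible(x)
}

#' Ordinary least-squares line
#'
#' Simple linear regression by the normal equations, with
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate x")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

#' Bin responses by Voronoi area
#'
#' Half-open bins `[lo, hi)` of a fixed width starting at 0; a value lying
#' exactly on an edge belongs to the upper bin. Bins up to the largest
#' observed area are reported, including empty ones (count 0, statistics
#' `NA`). Per-bin mean, standard error of the mean (sd/sqrt(count)) and CV.
#'
#' @param areas Voronoi areas, um^2 (non-negative).
#' @param responses per-cell responses aligned with `areas`.
#' @param width bin width in um^2 (default 1000).
#' @return data frame: `bin_lo`, `bin_hi`, `count`, `mean`, `sem`,
#'   `cv_percent`.
#' @export
bin_by_area <- function(areas, responses, width = 1000) {
  stopifnot(length(areas) == length(responses), width > 0)
  if (any(areas < 0)) stop("negative areas")
  bin <- floor(areas / width)  # 0-based bin index; edge values go up
  n_bins <- max(bin) + 1L
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1) * width,
                    bin_hi = seq_len(n_bins) * width,
                    count = 0L, mean = NA_real_, sem = NA_real_,
                    cv_percent = NA_real_)
  for (b in seq_len(n_bins)) {
    v <- responses[bin == b - 1L]
    out$count[b] <- length(v)
    if (length(v) >= 1L) out$mean[b] <- mean(v)
    if (length(v) >= 2L) {
      out$sem[b] <- sd(v) / sqrt(length(v))
      if (mean(v) > 0) out$cv_percent[b] <- 100 * sd(v) / mean(v)
    }
  }
  out
}
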