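#' Pearson chi-square statistic of a contingency table
#'
#' `sum((O - E)^2 / E)` with `E_ij = row_i * col_j / total`, without
#' continuity correction. Intended for group x resource-category count
#' tables, whose expected counts are typically too small for the
#' asymptotic chi-square distribution -- use [monte_carlo_chi2()] for the
#' p-value.
#'
#' @param tab Numeric matrix of non-negative counts, at least 2 x 2.
#' @return The statistic (single number).
#' @export
chi2_statistic <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2 x 2 table")
  if (any(tab < 0)) stop("negative counts")
  if (sum(tab) == 0) stop("empty table")
  rm <- rowSums(tab); cm <- colSums(tab)
  if (any(rm == 0) || any(cm == 0))
    stop("zero row or column margin: drop empty rows/columns ",
         "(see drop_empty_margins()) before testing")
  E <- outer(rm, cm) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Drop all-zero rows and columns of a contingency table
#'
#' @param tab Count matrix.
#' @param quiet Suppress the warning naming the dropped margins.
#' @return The reduced matrix.
#' @export
drop_empty_margins <- function(tab, quiet = FALSE) {
  tab <- as.matrix(tab)
  r0 <- rowSums(tab) == 0; c0 <- colSums(tab) == 0
  if (any(r0) || any(c0)) {
    if (!quiet)
      warning("dropping empty margins: ",
              paste(c(rownames(tab)[r0], colnames(tab)[c0]),
                    collapse = ", "))
    tab <- tab[!r0, !c0, drop = FALSE]
  }
  tab
}

#' Sample a random table with fixed margins
#'
#' Draws one contingency table from the distribution of non-negative
#' integer tables conditional on both margins (the null of the
#' Monte-Carlo chi-square test). Cells are filled sequentially: each row
#' is a multivariate hypergeometric draw against the remaining column
#' totals, which yields the same conditional (Fisher) distribution as
#' Patefield's algorithm.
#'
#' @param row_margins,col_margins Non-negative integer vectors with equal
#'   sums.
#' @return An integer matrix with exactly the requested margins.
#' @export
sample_fixed_margin_table <- function(row_margins, col_margins) {
  row_margins <- as.integer(row_margins)
  col_margins <- as.integer(col_margins)
  if (any(row_margins < 0) || any(col_margins < 0))
    stop("margins must be non-negative")
  if (sum(row_margins) != sum(col_margins))
    stop("row and column margins must have equal sums")
  r <- length(row_margins); cc <- length(col_margins)
  out <- matrix(0L, r, cc)
  colrem <- col_margins
  for (i in seq_len(r)) {
    need <- row_margins[i]
    if (i == r) { out[i, ] <- colrem; break }
    rest <- sum(colrem)
    for (j in seq_len(cc)) {
      if (j == cc) { out[i, j] <- need; break }
      rest <- rest - colrem[j]
      x <- stats::rhyper(1L, colrem[j], rest, need)
      out[i, j] <- x
      need <- need - x
      if (need == 0L) break
    }
    colrem <- colrem - out[i, ]
  }
  out
}

#' Monte-Carlo chi-square test of dietary composition
#'
#' Compares the observed Pearson statistic with its distribution over
#' random tables sharing the observed margins (default) or over
#' row-multinomial resampling. The p-value uses the add-one estimator
#' `p = (1 + #\{chi2_rep >= chi2_obs\}) / (reps + 1)`, which includes the
#' observed table among the replicates and therefore can never be 0.
#'
#' Rank-level count tables from sparse diet data routinely violate the
#' expected-count conditions of the asymptotic chi-square test; the
#' simulated p-value is exact up to Monte-Carlo error regardless of cell
#' size.
#'
#' @param tab Count matrix (e.g. a count-mode rank table matrix); empty
#'   rows/columns are dropped with a warning.
#' @param reps Number of null replicates (>= 1); 2000 is a common choice.
#' @param seed Optional integer seed, recorded in the result.
#' @param null `"fixed_margins"` (both margins conditioned on, the
#'   default) or `"row_multinomial"` (row totals fixed, columns drawn
#'   from the pooled column proportions).
#' @return An object of class `mc_chi2`: list with `chi2_obs`, `df`,
#'   `reps`, `p_mc`, `seed`, `method`, and the replicate exceedance
#'   count `n_ge`.
#' @export
monte_carlo_chi2 <- function(tab, reps = 2000, seed = NULL,
                             null = c("fixed_margins",
                                      "row_multinomial")) {
  null <- match.arg(null)
  if (reps < 1) stop("reps must be >= 1")
  tab <- drop_empty_margins(as.matrix(tab))
  obs <- chi2_statistic(tab)
  rm <- as.integer(round(rowSums(tab)))
  cm <- as.integer(round(colSums(tab)))
  if (!is.null(seed)) set.seed(seed)
  E <- outer(rm, cm) / sum(tab)
  pcol <- cm / sum(cm)
  n_ge <- 0L
  for (b in seq_len(reps)) {
    t_b <- if (null == "fixed_margins")
      sample_fixed_margin_table(rm, cm)
    else
      t(vapply(rm, function(n)
        as.integer(stats::rmultinom(1L, n, pcol)), integer(length(cm))))
    stat <- sum((t_b - E)^2 / E)
    if (stat >= obs - 1e-9) n_ge <- n_ge + 1L
  }
  structure(list(chi2_obs = obs,
                 df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
                 reps = as.integer(reps),
                 p_mc = (1 + n_ge) / (reps + 1),
                 n_ge = n_ge, seed = seed, method = null),
            class = "mc_chi2")
}

#' @export
print.mc_chi2 <- function(x, ...) {
  cat(sprintf(paste0("Monte-Carlo chi-square (%s null)\n",
                     "  X-squared = %.4f, df = %d (reference only)\n",
                     "  p = %.4g  (%d replicates%s)\n"),
              x$method, x$chi2_obs, x$df, x$p_mc, x$reps,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}
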