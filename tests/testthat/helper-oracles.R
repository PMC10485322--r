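# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths.

# enumerate all non-negative integer tables with the given margins,
# together with their conditional (multivariate hypergeometric)
# probabilities: P(T) = prod(r_i!) prod(c_j!) / (N! prod(t_ij!))
enumerate_fixed_margin_tables <- function(rm, cm) {
  r <- length(rm); cc <- length(cm)
  tables <- list()
  fill <- function(tab, i, colrem) {
    if (i > r) {
      if (all(colrem == 0)) tables[[length(tables) + 1L]] <<- tab
      return(invisible())
    }
    rows <- list()
    row_fill <- function(row, j, left) {
      if (j > cc) {
        if (left == 0) rows[[length(rows) + 1L]] <<- row
        return(invisible())
      }
      for (x in 0:min(left, colrem[j]))
        row_fill(c(row, x), j + 1L, left - x)
    }
    row_fill(integer(0), 1L, rm[i])
    for (row in rows) fill(rbind(tab, row), i + 1L, colrem - row)
  }
  fill(matrix(0L, 0, cc), 1L, cm)
  logp <- vapply(tables, function(t)
    sum(lfactorial(rm)) + sum(lfactorial(cm)) -
      lfactorial(sum(rm)) - sum(lfactorial(t)), numeric(1))
  list(tables = tables, prob = exp(logp))
}

# exact conditional p-value of the Pearson statistic by enumeration
exact_chi2_p <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab)
  enum <- enumerate_fixed_margin_tables(rm, cm)
  E <- outer(rm, cm) / sum(tab)
  stat <- function(t) sum((t - E)^2 / E)
  obs <- stat(tab)
  sum(enum$prob[vapply(enum$tables, stat, numeric(1)) >= obs - 1e-9])
}

# brute-force niche indices straight from the definitions
oracle_profile <- function(v, mode) {
  if (mode == "presence") (v > 0) / sum(v > 0) else v / sum(v)
}
oracle_levins <- function(v, mode, R = length(v)) {
  p <- oracle_profile(v, mode)
  B <- 1 / sum(p^2)
  c(B = B, B_A = (B - 1) / (R - 1))
}
oracle_shannon <- function(v, mode, R = length(v)) {
  p <- oracle_profile(v, mode); p <- p[p > 0]
  H <- -sum(p * log(p))
  c(H = H, J = H / log(R))
}
oracle_pianka <- function(v1, v2, mode) {
  p1 <- oracle_profile(v1, mode); p2 <- oracle_profile(v2, mode)
  sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))
}

# random presence matrix with no empty rows/columns
random_presence_matrix <- function(ngroup, nres) {
  repeat {
    m <- matrix(rbinom(ngroup * nres, 1, 0.4), ngroup, nres,
                dimnames = list(paste0("g", seq_len(ngroup)),
                                paste0("r", seq_len(nres))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

study_fixture_fit <- local({
  memo <- NULL
  function(...) {
    if (is.null(memo)) {
      fx <- study_fixture()
      memo <<- list(fx = fx,
                    otu = otu_table_from_df(fx$table))
    }
    memo
  }
})
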