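#' Resource-use profile of one group
#'
#' Converts one row of an incidence (or rank count) matrix into a
#' proportion vector over the shared resource universe. Under presence
#' weighting every resource used receives equal weight `1/n_used`; under
#' count weighting proportions follow the counts. The universe size `R`
#' is the number of resources observed across all groups of the matrix --
#' the denominator of every standardized breadth index.
#'
#' @param row Numeric vector of presences or counts (one matrix row).
#' @param mode `"presence"` or `"count"`.
#' @param group_id Optional label.
#' @return A `resource_profile`: list with `p` (proportions, summing to
#'   1), `n_used`, `R`, `group_id`.
#' @export
resource_profile <- function(row, mode = c("presence", "count"),
                             group_id = NULL) {
  mode <- match.arg(mode)
  row <- as.numeric(row)
  if (any(row < 0)) stop("negative resource values")
  if (sum(row) == 0) stop("empty diet: group uses no resources")
  p <- if (mode == "presence") (row > 0) / sum(row > 0) else row / sum(row)
  structure(list(p = as.numeric(p), n_used = sum(row > 0),
                 R = length(row), group_id = group_id),
            class = "resource_profile")
}

#' Levins niche breadth
#'
#' `B = 1 / sum(p_i^2)` ranges from 1 (a single resource) to `R` (uniform
#' use of the whole universe); the standardized form
#' `B_A = (B - 1) / (R - 1)` rescales it to \[0, 1\] so that 0 marks an
#' extreme specialist and 1 a complete generalist.
#'
#' @param profile A [resource_profile()].
#' @return Named numeric vector `c(B, B_A)`.
#' @export
levins_breadth <- function(profile) {
  stopifnot(inherits(profile, "resource_profile"))
  if (profile$R < 2) stop("standardization needs a universe of R >= 2")
  B <- 1 / sum(profile$p^2)
  c(B = B, B_A = (B - 1) / (profile$R - 1))
}

#' Shannon-Wiener niche breadth
#'
#' `H = -sum(p_i log p_i)` in nats (zero-probability terms contribute 0),
#' standardized as `J = H / log(R)`. Shannon breadth weights rare
#' resources more heavily than Levins breadth, so the two indices are
#' complementary descriptions of the same profile.
#'
#' @param profile A [resource_profile()].
#' @return Named numeric vector `c(H, J)`.
#' @export
shannon_breadth <- function(profile) {
  stopifnot(inherits(profile, "resource_profile"))
  if (profile$R < 2) stop("standardization needs a universe of R >= 2")
  p <- profile$p[profile$p > 0]
  H <- -sum(p * log(p))
  c(H = H, J = H / log(profile$R))
}

check_universe <- function(pj, pk) {
  if (pj$R != pk$R)
    stop("profiles live on different resource universes (R = ",
         pj$R, " vs ", pk$R, ")")
}

#' MacArthur-Levins directional niche overlap
#'
#' `M_jk = sum(p_ij p_ik) / sum(p_ij^2)` measures the overlap of group k
#' on group j (and `M_kj` the reverse); the two directions differ unless
#' the profiles have equal breadth. Under presence weighting the closed
#' forms are `M_jk = shared / n_k` and `M_kj = shared / n_j`.
#'
#' @param pj,pk [resource_profile()]s on the same universe.
#' @return Named numeric vector `c(M_jk, M_kj)`.
#' @export
macarthur_levins_overlap <- function(pj, pk) {
  stopifnot(inherits(pj, "resource_profile"),
            inherits(pk, "resource_profile"))
  check_universe(pj, pk)
  cross <- sum(pj$p * pk$p)
  c(M_jk = cross / sum(pj$p^2), M_kj = cross / sum(pk$p^2))
}

#' Pianka symmetric niche overlap
#'
#' `O = sum(p_ij p_ik) / sqrt(sum(p_ij^2) sum(p_ik^2))`, the cosine of
#' the angle between the two proportion vectors: 0 for disjoint diets, 1
#' exactly when the profiles are proportional (Cauchy-Schwarz equality).
#' Under presence weighting `O = shared / sqrt(n_j n_k)`.
#'
#' @param pj,pk [resource_profile()]s on the same universe.
#' @return A single number in \[0, 1\].
#' @export
pianka_overlap <- function(pj, pk) {
  stopifnot(inherits(pj, "resource_profile"),
            inherits(pk, "resource_profile"))
  check_universe(pj, pk)
  sum(pj$p * pk$p) / sqrt(sum(pj$p^2) * sum(pk$p^2))
}

#' Niche breadth table for all groups
#'
#' @param m An `incidence_matrix` or `rank_table`.
#' @param mode Weighting mode; defaults to the object's own mode.
#' @return data.frame with one row per group: `group`, `R`, `n_used`,
#'   `B`, `B_A`, `H`, `J`.
#' @export
niche_breadth <- function(m, mode = NULL) {
  m <- as_incidence(m)
  if (is.null(mode)) mode <- attr(m, "mode")
  rows <- lapply(rownames(m), function(g) {
    pr <- resource_profile(m[g, ], mode = mode, group_id = g)
    lb <- levins_breadth(pr)
    sb <- shannon_breadth(pr)
    data.frame(group = g, R = pr$R, n_used = pr$n_used,
               B = lb[["B"]], B_A = lb[["B_A"]],
               H = sb[["H"]], J = sb[["J"]])
  })
  do.call(rbind, rows)
}

#' Pairwise niche overlap table
#'
#' Computes MacArthur-Levins overlap in both directions and Pianka
#' overlap for every unordered pair of groups, in row order of the
#' matrix. `M_jk` uses the first-listed group's proportions in the
#' denominator.
#'
#' @inheritParams niche_breadth
#' @return data.frame with columns `group_j`, `group_k`, `shared`,
#'   `M_jk`, `M_kj`, `O`.
#' @export
niche_overlap <- function(m, mode = NULL) {
  m <- as_incidence(m)
  if (is.null(mode)) mode <- attr(m, "mode")
  g <- rownames(m)
  if (length(g) < 2) stop("overlap needs at least two groups")
  out <- list()
  for (j in seq_len(length(g) - 1L)) for (k in (j + 1L):length(g)) {
    pj <- resource_profile(m[j, ], mode = mode, group_id = g[j])
    pk <- resource_profile(m[k, ], mode = mode, group_id = g[k])
    ml <- macarthur_levins_overlap(pj, pk)
    out[[length(out) + 1L]] <- data.frame(
      group_j = g[j], group_k = g[k],
      shared = sum(m[j, ] > 0 & m[k, ] > 0),
      M_jk = ml[["M_jk"]], M_kj = ml[["M_kj"]],
      O = pianka_overlap(pj, pk))
  }
  do.call(rbind, out)
}

#' Exclusive-subset (Venn) resource counts
#'
#' For two or three groups, counts the resources present in each
#' exclusive subset of groups (only A, only B, A and B only, ...). The
#' counts sum to the number of resources present anywhere, so they are
#' the numeric content of a Venn diagram.
#'
#' @param m An `incidence_matrix` or `rank_table` with 2 or 3 groups.
#' @return Named integer vector; names join group labels with `&`.
#' @export
venn_counts <- function(m) {
  m <- as_incidence(m)
  g <- rownames(m)
  if (length(g) < 2 || length(g) > 3)
    stop("venn_counts supports 2 or 3 groups; use niche_overlap()'s ",
         "'shared' column for more")
  pres <- m > 0
  key <- apply(pres, 2L, function(col) {
    paste(g[col], collapse = "&")
  })
  key <- key[nzchar(key)]
  combos <- unlist(lapply(seq_along(g), function(k)
    utils::combn(g, k, paste, collapse = "&")))
  out <- integer(length(combos))
  names(out) <- combos
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  out
}

as_incidence <- function(m) {
  if (inherits(m, "rank_table")) return(m$matrix)
  if (inherits(m, "incidence_matrix")) return(m)
  stop("expected an incidence_matrix or rank_table")
}
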