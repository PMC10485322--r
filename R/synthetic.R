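#' Specify a synthetic incidence structure
#'
#' A synthetic diet survey is described by exact presence structure: how
#' many resources (OTUs) each group uses and how many fall in each
#' exclusive group subset. The structure must satisfy inclusion-exclusion
#' consistency: for every group, the subset counts of the subsets
#' containing it must sum to its richness.
#'
#' @param groups Character vector of group (species) identifiers.
#' @param richness Named integer vector, resources used per group.
#' @param sharing Named integer vector of exclusive subset counts; names
#'   are group subsets joined with `"+"` (e.g. `"A"`, `"A+C"`); subsets
#'   omitted are taken as 0.
#' @param pools_per_group Pools (pooled population samples) per group.
#' @param orders Pool of order names available to the taxonomy sampler.
#' @param depth_probs Probabilities that an OTU's lineage stops at class,
#'   order, family, genus or species (in that order; recycled to sum 1).
#' @param read_meanlog,read_sdlog Log-normal parameters for positive read
#'   counts (rounded up to a minimum of 1).
#' @param seed Integer seed used by [generate_diet_data()] for everything
#'   random (names, depths, read counts, pool allocation).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(groups, richness, sharing,
                           pools_per_group = 2,
                           orders = c("Araneae", "Coleoptera", "Diptera",
                                      "Hemiptera", "Hymenoptera",
                                      "Isopoda", "Lepidoptera",
                                      "Orthoptera"),
                           depth_probs = c(class = 0.18, order = 0.24,
                                           family = 0.21, genus = 0.22,
                                           species = 0.15),
                           read_meanlog = 4, read_sdlog = 1,
                           seed = 1L) {
  if (!length(groups) || anyDuplicated(groups))
    stop("groups must be distinct and non-empty")
  if (!all(groups %in% names(richness)))
    stop("richness must be named for every group")
  subsets <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, paste, collapse = "+")))
  full <- stats::setNames(integer(length(subsets)), subsets)
  bad <- setdiff(names(sharing), subsets)
  if (length(bad))
    stop("sharing names not valid group subsets: ",
         paste(bad, collapse = ", "),
         " (join sorted group ids with '+')")
  full[names(sharing)] <- as.integer(sharing)
  if (any(full < 0)) stop("sharing counts must be non-negative")
  for (g in groups) {
    members <- subsets[vapply(strsplit(subsets, "+", fixed = TRUE),
                              function(s) g %in% s, logical(1))]
    got <- sum(full[members])
    if (got != richness[[g]])
      stop("inclusion-exclusion violated for group '", g, "': subsets ",
           "containing it sum to ", got, " but richness is ",
           richness[[g]])
  }
  structure(list(groups = groups,
                 richness = as.integer(richness[groups]),
                 sharing = full, total_R = sum(full),
                 pools_per_group = as.integer(pools_per_group),
                 orders = orders,
                 depth_probs = depth_probs / sum(depth_probs),
                 read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec: ", length(x$groups), " groups, total R = ",
      x$total_R, "\n  richness: ",
      paste(x$groups, x$richness, sep = "=", collapse = " "),
      "\n  shared subsets: ",
      paste(names(x$sharing)[x$sharing > 0 &
                               grepl("+", names(x$sharing),
                                     fixed = TRUE)],
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic OTU table and metadata
#'
#' The presence structure (which OTU is used by which groups) is laid out
#' exactly as the spec demands -- not sampled -- so downstream
#' presence-level quantities (richness, subset counts, presence-mode
#' niche indices) are deterministic functions of the spec. Randomness
#' under `spec$seed` affects only taxonomy names and depths, read counts,
#' and the allocation of each OTU to one or more pools of each using
#' group (always at least one).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (data.frame in the TSV dialect of
#'   [read_otu_table()]), `metadata` (pool metadata data.frame) and
#'   `truth` (list: `richness`, `sharing`, `membership` per OTU,
#'   `order_of` per OTU, `depth` per OTU).
#' @seealso [write_diet_data()]
#' @export
generate_diet_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$total_R
  ids <- sprintf("OTU_%03d", seq_len(n))
  subset_of <- rep(names(spec$sharing), spec$sharing)
  membership <- strsplit(subset_of, "+", fixed = TRUE)
  names(membership) <- ids

  pools <- unlist(lapply(spec$groups, function(g)
    paste0(g, "_p", seq_len(spec$pools_per_group))))
  metadata <- data.frame(
    pool_id = pools,
    species = rep(spec$groups, each = spec$pools_per_group),
    site = paste0("site_", seq_along(pools)),
    habitat = "synthetic",
    elevation_m = 1000 + 100 * seq_along(pools),
    stringsAsFactors = FALSE)

  depth_levels <- c("class", "order", "family", "genus", "species")
  depth <- sample(depth_levels, n, replace = TRUE,
                  prob = spec$depth_probs)
  order_of <- sample(spec$orders, n, replace = TRUE)
  classes <- c(Araneae = "Arachnida", Isopoda = "Malacostraca")
  taxonomy <- vapply(seq_len(n), function(i) {
    cl <- if (order_of[i] %in% names(classes))
      classes[[order_of[i]]] else "Insecta"
    seg <- c(p = "Arthropoda", c = cl)
    d <- match(depth[i], depth_levels)
    if (d >= 2) seg <- c(seg, o = order_of[i])
    if (d >= 3) seg <- c(seg, f = paste0(order_of[i], "_fam",
                                         1 + i %% 3))
    if (d >= 4) seg <- c(seg, g = paste0("genus_", i))
    if (d >= 5) seg <- c(seg, s = paste0("sp_", i))
    paste(paste0(names(seg), "__", seg), collapse = ";")
  }, character(1))
  # order bookkeeping only counts OTUs whose lineage reaches order
  order_of[depth == "class"] <- NA_character_

  counts <- matrix(0L, n, length(pools), dimnames = list(ids, pools))
  for (i in seq_len(n)) for (g in membership[[i]]) {
    gp <- pools[metadata$species == g]
    use <- gp[stats::runif(length(gp)) < 0.5]
    if (!length(use)) use <- sample(gp, 1L)
    counts[i, use] <- pmax(1L, round(stats::rlnorm(
      length(use), spec$read_meanlog, spec$read_sdlog)))
  }

  table <- data.frame(otu_id = ids, counts, taxonomy = taxonomy,
                      confidence = round(stats::runif(n, 0.75, 0.99), 2),
                      check.names = FALSE, stringsAsFactors = FALSE)
  truth <- list(richness = stats::setNames(spec$richness, spec$groups),
                sharing = spec$sharing, membership = membership,
                order_of = stats::setNames(order_of, ids),
                depth = stats::setNames(depth, ids))
  list(table = table, metadata = metadata, truth = truth)
}

#' Write generated diet data as TSV files
#'
#' @param gen Result of [generate_diet_data()] (or any list with `table`
#'   and `metadata` data.frames).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_diet_data <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  utils::write.table(gen$table, paths[["otu_table"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Generate per-group OTU counts over orders
#'
#' Draws each group's composition from a symmetric Dirichlet and its
#' counts from a multinomial, recording the true proportions -- a count
#' surrogate for rank-level bar charts. Large `concentration` approaches
#' uniform use of all orders.
#'
#' @param groups Character vector of group ids.
#' @param orders Character vector of order names.
#' @param concentration Symmetric Dirichlet parameter (> 0).
#' @param totals Integer total OTU count per group (recycled).
#' @param seed Integer seed.
#' @return List with `matrix` (count-mode `incidence_matrix`) and `truth`
#'   (matrix of the sampled proportions).
#' @export
generate_order_counts <- function(groups, orders, concentration = 1,
                                  totals, seed = 1L) {
  stopifnot(concentration > 0, all(totals > 0))
  set.seed(seed)
  totals <- rep_len(as.integer(totals), length(groups))
  p <- t(vapply(groups, function(g) {
    x <- stats::rgamma(length(orders), shape = concentration)
    x / sum(x)
  }, numeric(length(orders))))
  m <- t(vapply(seq_along(groups), function(i)
    as.integer(stats::rmultinom(1L, totals[i], p[i, ])),
    integer(length(orders))))
  dimnames(m) <- list(groups, orders)
  dimnames(p) <- dimnames(m)
  keep <- colSums(m) > 0
  list(matrix = incidence_matrix(m[, keep, drop = FALSE],
                                 mode = "count"),
       truth = p)
}
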