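#' Collapse an incidence matrix to a taxonomic rank
#'
#' Maps each resource (OTU) of `incidence` to its name at `rank` and
#' aggregates per group. OTUs without an assignment at `rank` are excluded
#' and reported in `n_unassigned` -- they are not lumped into an "Unknown"
#' category, so rank-level analyses use exactly the identifiable subset.
#'
#' In count mode each cell is the number of the group's OTUs belonging to
#' the taxon, so a group's row total equals its richness among assigned
#' OTUs; in presence mode cells record whether any such OTU is present.
#' Count mode is the basis for rank-level niche metrics: two groups using
#' the same set of orders can still differ in how their OTU richness is
#' spread across them.
#'
#' @param incidence A presence-mode `incidence_matrix` (see
#'   [build_incidence()]).
#' @param x The [otu_table()] supplying lineages for every resource.
#' @param rank A canonical rank, see [DIET_RANKS].
#' @param mode `"count"` or `"presence"`.
#' @return A `rank_table`: list with `matrix` (an `incidence_matrix` of
#'   groups x taxa), `rank`, `mode`, `n_assigned`, `n_unassigned`.
#' @export
collapse_to_rank <- function(incidence, x, rank,
                             mode = c("count", "presence")) {
  stopifnot(inherits(incidence, "incidence_matrix"),
            inherits(x, "otu_table"))
  mode <- match.arg(mode)
  if (!rank %in% DIET_RANKS) stop("unknown rank: ", rank)
  ids <- colnames(incidence)
  missing <- setdiff(ids, rownames(x$lineage))
  if (length(missing))
    stop("no lineage for resource(s): ", paste(missing, collapse = ", "))
  taxon <- x$lineage[ids, rank]
  assigned <- !is.na(taxon) & nzchar(taxon)
  taxa <- sort(unique(taxon[assigned]))
  m <- matrix(0L, nrow(incidence), length(taxa),
              dimnames = list(rownames(incidence), taxa))
  for (tx in taxa) {
    cols <- which(assigned & taxon == tx)
    m[, tx] <- rowSums(incidence[, cols, drop = FALSE])
  }
  if (mode == "presence") m <- (m > 0L) * 1L
  m <- m[, colSums(m) > 0, drop = FALSE]
  structure(list(matrix = incidence_matrix(m, mode = mode),
                 rank = rank, mode = mode,
                 n_assigned = sum(assigned),
                 n_unassigned = sum(!assigned)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("rank_table at rank '", x$rank, "' (", x$mode, " mode): ",
      ncol(x$matrix), " taxa; ", x$n_assigned, " OTUs assigned, ",
      x$n_unassigned, " unassigned\n", sep = "")
  print(unclass(x$matrix))
  invisible(x)
}

#' Write a rank table as TSV (groups x taxa)
#'
#' @param rt A `rank_table`.
#' @param path Output path.
#' @export
write_rank_table <- function(rt, path) {
  stopifnot(inherits(rt, "rank_table"))
  df <- data.frame(group = rownames(rt$matrix), unclass(rt$matrix),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rank=%s mode=%s n_assigned=%d n_unassigned=%d",
                     rt$rank, rt$mode, rt$n_assigned, rt$n_unassigned),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Taxonomic assignment depth summary
#'
#' Counts, for each canonical rank, how many OTUs carry an assignment at
#' that rank. Because lineages cannot skip ranks the counts are
#' non-increasing from phylum to species.
#'
#' @param x An [otu_table()].
#' @return Named integer vector over [DIET_RANKS].
#' @export
assignment_summary <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (nrow(x$lineage) == 0L) {
    out <- integer(length(DIET_RANKS))
    names(out) <- DIET_RANKS
    return(out)
  }
  out <- colSums(!is.na(x$lineage) & nzchar(x$lineage))
  names(out) <- DIET_RANKS
  out
}
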