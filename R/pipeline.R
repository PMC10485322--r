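#' Dietary niche analysis of a metabarcoding OTU table
#'
#' Runs the full incidence pipeline: read (or accept) an OTU table and
#' pool metadata, filter to target phyla, exclude host co-amplification,
#' truncate low-confidence assignments, build a presence/absence
#' incidence matrix for the chosen grouping, and -- at each requested
#' taxonomic resolution -- compute niche breadth, pairwise overlap,
#' exclusive-subset counts and (for rank-collapsed count tables) a
#' Monte-Carlo chi-square test of composition.
#'
#' The `"otu"` rank analyses presence/absence of individual OTUs with
#' equal weight per OTU used; coarser ranks analyse counts of OTUs per
#' taxon, so that groups using the same taxa with different richness
#' still differ. Each rank has its own resource universe R (all
#' resources observed across groups at that rank).
#'
#' @param otu OTU table: an [otu_table()] or a TSV path.
#' @param metadata Pool metadata: a data.frame or a TSV path.
#' @param ranks Resolutions to analyse: `"otu"` and/or entries of
#'   [DIET_RANKS].
#' @param group_by Grouping of pools, see [build_incidence()].
#' @param keep_phyla,host_taxa,min_confidence Filtering rules, see
#'   [filter_otus()].
#' @param min_reads Detection threshold, see [build_incidence()].
#' @param reps,seed Monte-Carlo settings, see [monte_carlo_chi2()];
#'   `reps = 0` skips the tests.
#' @param dialect,rank_map Taxonomy dialect when `otu` is a path.
#' @return A `diet_niche` object: list with `breadth`, `overlap`, `venn`
#'   and `chi2` per rank, the `incidence` matrix, `assignment` summary,
#'   the filtering `log`, and the call parameters.
#' @examples
#' fx <- study_fixture()
#' fit <- diet_niche(with(fx, otu_table_from_df(table)), fx$metadata,
#'                   host_taxa = "Sceloporus", reps = 200, seed = 1)
#' fit
#' @export
diet_niche <- function(otu, metadata, ranks = c("otu", "order"),
                       group_by = "species",
                       keep_phyla = c("Arthropoda", "Chordata"),
                       host_taxa = NULL, min_confidence = 0.7,
                       min_reads = 1, reps = 2000, seed = NULL,
                       dialect = "greengenes", rank_map = NULL) {
  if (is.character(metadata)) metadata <- read_pool_metadata(metadata)
  else metadata <- validate_metadata(metadata)
  if (is.character(otu))
    otu <- read_otu_table(otu, dialect = dialect, rank_map = rank_map,
                          metadata = metadata)
  stopifnot(inherits(otu, "otu_table"))
  if (nrow(otu$counts) == 0L)
    stop("read_otu_table: empty OTU table")
  bad <- setdiff(ranks, c("otu", DIET_RANKS))
  if (length(bad)) stop("unknown rank(s): ", paste(bad, collapse = ", "))

  n_in <- nrow(otu$counts)
  kept_phyla <- filter_otus(otu, keep_phyla = keep_phyla,
                            host_taxa = NULL,
                            min_confidence = min_confidence)
  filtered <- filter_otus(otu, keep_phyla = keep_phyla,
                          host_taxa = host_taxa,
                          min_confidence = min_confidence)
  log <- list(n_input = n_in,
              n_phylum_dropped = n_in - nrow(kept_phyla$counts),
              n_host_excluded = nrow(kept_phyla$counts) -
                nrow(filtered$counts),
              n_retained = nrow(filtered$counts))

  inc <- build_incidence(filtered, metadata, group_by = group_by,
                         min_reads = min_reads)
  res <- list()
  for (rk in ranks) {
    if (rk == "otu") {
      m <- inc
      rank_info <- NULL
    } else {
      rt <- collapse_to_rank(inc, filtered, rk, mode = "count")
      m <- rt$matrix
      rank_info <- rt[c("n_assigned", "n_unassigned")]
    }
    empty <- rowSums(m) == 0
    if (any(empty)) {
      warning("group(s) with empty diet at rank '", rk, "' excluded: ",
              paste(rownames(m)[empty], collapse = ", "))
      m <- m[!empty, , drop = FALSE]
    }
    chi <- NULL
    if (rk != "otu" && reps >= 1 && nrow(m) >= 2 && ncol(m) >= 2)
      chi <- monte_carlo_chi2(drop_empty_margins(unclass(m),
                                                 quiet = TRUE),
                              reps = reps, seed = seed)
    res[[rk]] <- list(
      rank = rk, matrix = m, info = rank_info,
      breadth = niche_breadth(m),
      overlap = if (nrow(m) >= 2) niche_overlap(m) else NULL,
      venn = if (nrow(m) %in% 2:3) venn_counts(m) else NULL,
      chi2 = chi)
  }
  structure(list(ranks = res, incidence = inc,
                 assignment = assignment_summary(filtered),
                 log = log, group_by = group_by, reps = reps,
                 seed = seed),
            class = "diet_niche")
}

#' Build an otu_table from an in-memory data.frame
#'
#' Convenience for tables in the TSV column layout (`otu_id`, pool
#' columns, `taxonomy`, optional `confidence`) that were never written
#' to disk, e.g. the output of [generate_diet_data()].
#'
#' @param df The data.frame.
#' @param dialect,rank_map See [parse_lineage()].
#' @return An [otu_table()].
#' @export
otu_table_from_df <- function(df, dialect = "greengenes",
                              rank_map = NULL) {
  pool_cols <- setdiff(names(df), c("otu_id", "taxonomy", "confidence"))
  counts <- as.matrix(df[pool_cols])
  storage.mode(counts) <- "numeric"
  rownames(counts) <- df$otu_id
  otu_table(counts,
            parse_lineage(df$taxonomy, dialect = dialect,
                          rank_map = rank_map),
            if ("confidence" %in% names(df)) df$confidence else NULL)
}

#' @export
print.diet_niche <- function(x, digits = 3, ...) {
  cat("Dietary niche analysis (grouped by ", x$group_by, ")\n",
      sep = "")
  cat(sprintf(paste0("  OTUs: %d input, %d off-target phylum, ",
                     "%d host, %d retained\n"),
              x$log$n_input, x$log$n_phylum_dropped,
              x$log$n_host_excluded, x$log$n_retained))
  for (r in x$ranks) {
    cat("-- rank: ", r$rank, " (R = ", ncol(r$matrix), ")",
        if (!is.null(r$info))
          sprintf("; %d OTUs assigned, %d unassigned",
                  r$info$n_assigned, r$info$n_unassigned),
        "\n", sep = "")
    b <- r$breadth
    b[c("B", "B_A", "H", "J")] <- round(b[c("B", "B_A", "H", "J")],
                                        digits)
    print(b, row.names = FALSE)
    if (!is.null(r$overlap)) {
      o <- r$overlap
      o[c("M_jk", "M_kj", "O")] <- round(o[c("M_jk", "M_kj", "O")],
                                         digits)
      print(o, row.names = FALSE)
    }
    if (!is.null(r$chi2))
      cat(sprintf("  composition: X-squared = %.3f, MC p = %.4g (%d reps)\n",
                  r$chi2$chi2_obs, r$chi2$p_mc, r$chi2$reps))
  }
  invisible(x)
}

#' @export
summary.diet_niche <- function(object, ...) {
  cat("Assignment depth: ",
      paste(names(object$assignment), object$assignment, sep = "=",
            collapse = " "), "\n", sep = "")
  print(object)
}

#' Bar plot of a rank-level diet composition
#'
#' @param x A `diet_niche` object.
#' @param rank Which analysed rank to draw (default: first non-OTU
#'   rank, else the first).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.diet_niche <- function(x, rank = NULL, ...) {
  if (is.null(rank)) {
    nm <- names(x$ranks)
    rank <- if (any(nm != "otu")) nm[nm != "otu"][1L] else nm[1L]
  }
  m <- x$ranks[[rank]]$matrix
  graphics::barplot(unclass(m), beside = TRUE,
                    legend.text = rownames(m),
                    ylab = "OTUs", las = 2, ...)
  invisible(x)
}

#' Write a report bundle
#'
#' Writes, per rank, TSVs of the breadth, overlap and Venn tables plus
#' the rank matrix and Monte-Carlo test results, and a machine-readable
#' `run.json` log. With identical inputs and seed the outputs are
#' byte-identical.
#'
#' @param x A `diet_niche` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "diet_niche"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  chi_rows <- list()
  for (r in x$ranks) {
    wt(r$breadth, paste0("breadth_", r$rank, ".tsv"))
    if (!is.null(r$overlap))
      wt(r$overlap, paste0("overlap_", r$rank, ".tsv"))
    if (!is.null(r$venn))
      wt(data.frame(subset = names(r$venn), n = as.integer(r$venn)),
         paste0("venn_", r$rank, ".tsv"))
    wt(data.frame(group = rownames(r$matrix), unclass(r$matrix),
                  check.names = FALSE),
       paste0("matrix_", r$rank, ".tsv"))
    if (!is.null(r$chi2))
      chi_rows[[r$rank]] <- data.frame(
        rank = r$rank, chi2_obs = r$chi2$chi2_obs, df = r$chi2$df,
        reps = r$chi2$reps, p_mc = r$chi2$p_mc,
        seed = if (is.null(r$chi2$seed)) NA else r$chi2$seed)
  }
  if (length(chi_rows)) wt(do.call(rbind, chi_rows), "chi2.tsv")
  jsonlite::write_json(
    list(package = "dietniche",
         version = as.character(utils::packageVersion("dietniche")),
         group_by = x$group_by, seed = x$seed, reps = x$reps,
         filter_log = x$log,
         assignment = as.list(x$assignment)),
    file.path(dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
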