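#' Canonical taxonomic ranks
#'
#' Rank labels used throughout the package, ordered from coarsest to finest.
#' Lineages are stored phylum-first; a lineage may stop at any rank but may
#' not skip ranks.
#'
#' @format Character vector of length 6.
#' @export
DIET_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct an OTU table
#'
#' An `otu_table` bundles the three pieces of information the pipeline needs
#' per OTU: read counts (or presences) per pooled sample, the taxonomy
#' lineage, and the classifier bootstrap support of the deepest assigned
#' rank.
#'
#' @param counts Numeric matrix, OTUs x pools; non-negative; rownames are
#'   unique OTU identifiers, colnames are pool identifiers.
#' @param lineage Character matrix, OTUs x 6, columns named as
#'   [DIET_RANKS]; `NA` marks ranks without an assignment. Assigned ranks
#'   must be contiguous from phylum downward.
#' @param confidence Optional numeric vector in \[0, 1\] (values in
#'   (1, 100\] are treated as percentages), the bootstrap support of each
#'   OTU's deepest assignment; `NA` when unknown.
#' @return An object of class `otu_table`.
#' @seealso [read_otu_table()], [filter_otus()], [build_incidence()]
#' @export
otu_table <- function(counts, lineage, confidence = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop("counts must have unique rownames (otu_id)")
  if (any(counts < 0)) stop("counts must be non-negative")
  lineage <- as.matrix(lineage)
  if (!identical(colnames(lineage), DIET_RANKS))
    stop("lineage must have columns ", paste(DIET_RANKS, collapse = ", "))
  if (nrow(lineage) != nrow(counts))
    stop("lineage and counts must describe the same OTUs")
  rownames(lineage) <- rownames(counts)
  # contiguity: no assignment below a missing rank
  gap <- apply(lineage, 1L, function(l) {
    a <- !is.na(l) & nzchar(l)
    any(diff(a) > 0L)
  })
  if (any(gap))
    stop("lineage skips a rank for OTU(s): ",
         paste(utils::head(rownames(counts)[gap], 5L), collapse = ", "))
  if (is.null(confidence)) confidence <- rep(NA_real_, nrow(counts))
  confidence <- as.numeric(confidence)
  confidence[!is.na(confidence) & confidence > 1] <-
    confidence[!is.na(confidence) & confidence > 1] / 100
  if (any(!is.na(confidence) & (confidence < 0 | confidence > 1)))
    stop("confidence must lie in [0, 1] (or [0, 100] as percent)")
  structure(list(counts = counts, lineage = lineage,
                 confidence = confidence),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  depth <- rank_depth(x$lineage)
  cat("otu_table: ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " pools\n", sep = "")
  cat("  deepest rank: ",
      paste(sprintf("%s=%d", c("none", DIET_RANKS),
                    tabulate(depth + 1L, nbins = 7L)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# depth index per OTU: 0 = no assignment, 6 = species
rank_depth <- function(lineage) {
  apply(lineage, 1L, function(l) {
    a <- which(!is.na(l) & nzchar(l))
    if (length(a)) max(a) else 0L
  })
}

#' Parse taxonomy lineage strings
#'
#' Supports the greengenes-style dialect (`p__X;c__X;o__X;...`, empty
#' segments allowed) and a plain dialect of semicolon-separated names whose
#' ranks are given positionally by `rank_map`.
#'
#' @param x Character vector of lineage strings; `""`/`NA` yield an empty
#'   lineage.
#' @param dialect `"greengenes"` or `"plain"`.
#' @param rank_map For `dialect = "plain"`, a character vector of ranks
#'   (subset of [DIET_RANKS], in canonical order) naming the positions of
#'   the split string.
#' @return Character matrix with one row per input and columns
#'   [DIET_RANKS].
#' @export
parse_lineage <- function(x, dialect = c("greengenes", "plain"),
                          rank_map = NULL) {
  dialect <- match.arg(dialect)
  prefixes <- c(phylum = "p__", class = "c__", order = "o__",
                family = "f__", genus = "g__", species = "s__")
  out <- matrix(NA_character_, nrow = length(x), ncol = 6L,
                dimnames = list(NULL, DIET_RANKS))
  if (dialect == "plain") {
    if (is.null(rank_map))
      stop("dialect 'plain' requires a rank_map")
    if (!all(rank_map %in% DIET_RANKS) || anyDuplicated(rank_map) ||
        is.unsorted(match(rank_map, DIET_RANKS)))
      stop("rank_map must list distinct canonical ranks in order")
  }
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(trimws(s))) next
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    if (dialect == "greengenes") {
      for (p in parts) {
        if (!nzchar(p)) next
        hit <- which(startsWith(p, prefixes))
        if (!length(hit))
          stop("unparseable lineage segment '", p, "' in row ", i)
        name <- substring(p, 4L)
        if (!nzchar(name)) next
        if (!is.na(out[i, hit]))
          stop("duplicate rank '", names(prefixes)[hit], "' in row ", i)
        out[i, hit] <- name
      }
    } else {
      if (length(parts) > length(rank_map))
        stop("lineage in row ", i, " has more segments than rank_map")
      keep <- nzchar(parts)
      out[i, rank_map[seq_along(parts)][keep]] <- parts[keep]
    }
    # a name below an unnamed rank is not interpretable
    a <- !is.na(out[i, ])
    if (any(diff(a) > 0L))
      stop("lineage skips a rank in row ", i, ": '", s, "'")
  }
  out
}

#' Read an OTU table from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `otu_id`, one
#' numeric (or logical) column per pool, `taxonomy`, and optionally
#' `confidence`. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param dialect Taxonomy dialect, see [parse_lineage()].
#' @param rank_map Rank map for the plain dialect.
#' @param metadata Optional pool metadata (see [read_pool_metadata()]);
#'   when supplied, every pool column must appear in `metadata$pool_id`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("greengenes", "plain"),
                           rank_map = NULL, metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("otu_id", "taxonomy")
  if (!all(need %in% names(df)))
    stop("OTU table must contain columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty OTU table: ", path)
  if (anyDuplicated(df$otu_id))
    stop("duplicate otu_id in ", path, ": ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  pool_cols <- setdiff(names(df), c("otu_id", "taxonomy", "confidence"))
  if (!length(pool_cols)) stop("no pool columns found in ", path)
  if (!is.null(metadata)) {
    bad <- setdiff(pool_cols, metadata$pool_id)
    if (length(bad))
      stop("pool column(s) absent from metadata: ",
           paste(bad, collapse = ", "))
  }
  counts <- as.matrix(df[pool_cols])
  if (is.logical(counts)) counts <- counts * 1L
  storage.mode(counts) <- "numeric"
  if (anyNA(counts)) stop("missing detection values in ", path)
  rownames(counts) <- df$otu_id
  lineage <- parse_lineage(df$taxonomy, dialect = dialect,
                           rank_map = rank_map)
  conf <- if ("confidence" %in% names(df)) df$confidence else NULL
  otu_table(counts, lineage, conf)
}

#' Read pool metadata from TSV
#'
#' @param path TSV with columns `pool_id`, `species`, `site`, `habitat`,
#'   `elevation_m`, and optionally `n_individuals`.
#' @return A validated data.frame.
#' @export
read_pool_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("pool_id", "species", "site", "habitat", "elevation_m")
  if (!all(need %in% names(md)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$pool_id)) stop("duplicate pool_id in metadata")
  if (anyDuplicated(md[c("species", "site")]))
    stop("duplicate (species, site) pair in metadata")
  if (any(md$elevation_m < 0)) stop("elevation_m must be non-negative")
  md
}

#' Filter OTU records
#'
#' Applies the three post-classification rules used for diet metabarcoding
#' tables: retain only target phyla, exclude host co-amplification by
#' taxonomy match, and truncate assignments whose bootstrap support falls
#' below a threshold. Truncation removes the deepest assigned rank rather
#' than the record, so low-confidence OTUs remain available for analyses
#' at coarser ranks.
#'
#' @param x An [otu_table()].
#' @param keep_phyla Character vector of phyla to retain; OTUs with a
#'   different or missing phylum are dropped.
#' @param host_taxa Character vector of host genus or "Genus species"
#'   names; OTUs whose lineage matches any entry are dropped. `NULL`
#'   disables host exclusion.
#' @param min_confidence Bootstrap support threshold in \[0, 1\]; the
#'   deepest rank of records with support below it is unassigned.
#' @return A filtered [otu_table()]. The operation is idempotent.
#' @export
filter_otus <- function(x, keep_phyla = c("Arthropoda", "Chordata"),
                        host_taxa = NULL, min_confidence = 0.7) {
  stopifnot(inherits(x, "otu_table"))
  if (!length(keep_phyla)) stop("keep_phyla must be non-empty")
  if (!is.null(host_taxa) && !length(host_taxa))
    stop("host exclusion enabled but host list is empty")
  if (min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must lie in [0, 1]")
  keep <- !is.na(x$lineage[, "phylum"]) &
    x$lineage[, "phylum"] %in% keep_phyla
  if (!is.null(host_taxa)) {
    genus_sp <- ifelse(is.na(x$lineage[, "species"]), NA,
                       paste(x$lineage[, "genus"], x$lineage[, "species"]))
    is_host <- x$lineage[, "genus"] %in% host_taxa |
      genus_sp %in% host_taxa |
      x$lineage[, "species"] %in% host_taxa
    keep <- keep & !is_host
  }
  lineage <- x$lineage
  conf <- x$confidence
  low <- !is.na(conf) & conf < min_confidence
  for (i in which(low)) {
    d <- rank_depth(lineage[i, , drop = FALSE])
    if (d > 0L) lineage[i, d] <- NA_character_
    conf[i] <- NA_real_  # support referred to the removed rank
  }
  otu_table(x$counts[keep, , drop = FALSE],
            lineage[keep, , drop = FALSE], conf[keep])
}

#' Build a presence/absence incidence matrix
#'
#' Converts detections to incidence for a chosen grouping of pools. A
#' resource is present in a group when its read count reaches `min_reads`
#' in at least one pool of the group, so grouping unions the pools'
#' detections -- the only aggregation consistent with presence/absence
#' data.
#'
#' @param x An [otu_table()].
#' @param metadata Pool metadata, see [read_pool_metadata()].
#' @param group_by One of `"pool"`, `"species"`, `"site"`,
#'   `"species_site"`.
#' @param min_reads Minimum read count that counts as a detection
#'   (default 1).
#' @return An `incidence_matrix`: a 0/1 matrix groups x resources with
#'   attribute `mode = "presence"`; resource columns are sorted
#'   lexicographically and resources absent everywhere are dropped.
#' @export
build_incidence <- function(x, metadata,
                            group_by = c("pool", "species", "site",
                                         "species_site"),
                            min_reads = 1) {
  stopifnot(inherits(x, "otu_table"))
  group_by <- match.arg(group_by)
  metadata <- validate_metadata(metadata)
  if (min_reads < 1) stop("min_reads must be >= 1")
  bad <- setdiff(colnames(x$counts), metadata$pool_id)
  if (length(bad))
    stop("pools absent from metadata: ", paste(bad, collapse = ", "))
  md <- metadata[match(colnames(x$counts), metadata$pool_id), ]
  grp <- switch(group_by,
                pool = md$pool_id,
                species = md$species,
                site = md$site,
                species_site = paste(md$species, md$site, sep = "|"))
  groups <- unique(grp)
  if (any(!nzchar(groups))) stop("grouping produced an empty group label")
  pres <- x$counts >= min_reads
  inc <- t(vapply(groups, function(g) {
    cols <- which(grp == g)
    if (!length(cols)) stop("group '", g, "' contains no pools")
    as.integer(rowSums(pres[, cols, drop = FALSE]) > 0)
  }, integer(nrow(x$counts))))
  colnames(inc) <- rownames(x$counts)
  inc <- inc[, order(colnames(inc)), drop = FALSE]
  inc <- inc[, colSums(inc) > 0, drop = FALSE]
  incidence_matrix(inc, mode = "presence")
}

#' Incidence matrix constructor
#'
#' @param m Numeric matrix, groups x resources; 0/1 in presence mode,
#'   non-negative integers in count mode.
#' @param mode `"presence"` or `"count"`.
#' @return The matrix with class `incidence_matrix` and a `mode`
#'   attribute.
#' @export
incidence_matrix <- function(m, mode = c("presence", "count")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("incidence matrix needs group rownames and resource colnames")
  if (any(m < 0) || any(m != round(m)))
    stop("incidence values must be non-negative integers")
  if (mode == "presence" && any(m > 1))
    stop("presence mode admits only 0/1 values")
  structure(m, mode = mode, class = c("incidence_matrix", "matrix"))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("incidence_matrix (", attr(x, "mode"), "): ", nrow(x),
      " groups x ", ncol(x), " resources\n", sep = "")
  print(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE])
  if (ncol(x) > 8L) cat("... ", ncol(x) - 8L, " more columns\n", sep = "")
  invisible(x)
}

#' Write / read an incidence matrix as TSV
#'
#' The round trip `read_incidence(write_incidence(m))` reproduces the
#' matrix exactly, including group and resource order and mode.
#'
#' @param m An `incidence_matrix`.
#' @param path Output/input TSV path.
#' @return `write_incidence` returns `path` invisibly; `read_incidence`
#'   returns an `incidence_matrix`.
#' @export
write_incidence <- function(m, path) {
  stopifnot(inherits(m, "incidence_matrix"))
  df <- data.frame(group = rownames(m), unclass(m), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode=", attr(m, "mode")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- sub("^# mode=", "", first)
  if (identical(mode, first)) mode <- "presence"
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$group
  incidence_matrix(m, mode = mode)
}
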