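#' Reference incidence structure of a three-species lizard diet survey
#'
#' `fixture_f0_spec()` is the minimal presence structure used throughout
#' the test suite: three congeneric lizard species with prey-OTU richness
#' 15, 13 and 28, pairwise sharing 4 (jarrovii-virgatus), 1
#' (slevini-virgatus) and 0 (jarrovii-slevini), and a universe of R = 51
#' prey OTUs. All presence-mode breadth and overlap indices follow in
#' closed form from these seven numbers.
#'
#' @param seed Seed forwarded to the generator (names/reads/pool
#'   allocation only; the presence structure is exact).
#' @return A [synthetic_spec()].
#' @export
fixture_f0_spec <- function(seed = 1L) {
  g <- c("S_jarrovii", "S_slevini", "S_virgatus")
  synthetic_spec(
    groups = g,
    richness = c(S_jarrovii = 15, S_slevini = 13, S_virgatus = 28),
    sharing = c("S_jarrovii" = 11, "S_slevini" = 12, "S_virgatus" = 23,
                "S_jarrovii+S_virgatus" = 4, "S_slevini+S_virgatus" = 1),
    seed = seed)
}

# -- full synthetic study emulation -----------------------------------------
#
# A 53-row OTU table (51 prey + 2 host) over 6 population pools that
# reproduces the published summary statistics of a three-species
# Sceloporus diet survey: per-species OTU richness 15/13/28 with sharing
# 4/1/0; 42 OTUs assigned to 8 arthropod orders (32 to family, 21 to
# genus, 10 to species); species x order OTU counts and their population
# splits recovered by exhaustive enumeration from the published breadth
# and overlap indices. It is a synthetic stand-in, not the study's real
# supplementary table: presence structure and taxonomy depths are exact
# by construction, read counts and taxon names are invented.

study_pools <- function() {
  data.frame(
    pool_id = c("JAR_TC", "JAR_BP", "SLE_AWRR", "SLE_BP",
                "VIR_CC", "VIR_TC"),
    species = c("Sceloporus jarrovii", "Sceloporus jarrovii",
                "Sceloporus slevini", "Sceloporus slevini",
                "Sceloporus virgatus", "Sceloporus virgatus"),
    site = c("Turkey Creek", "Barfoot Park",
             "Appleton-Whittell Research Ranch", "Barfoot Park",
             "Cave Creek Canyon", "Turkey Creek"),
    habitat = c("Madrean Pine-oak", "Montane Conifer Forest",
                "Semi-desert Grassland", "Montane Conifer Forest",
                "Madrean Oak Woodland", "Madrean Pine-oak"),
    elevation_m = c(2070, 2505, 1430, 2505, 1700, 2070),
    n_individuals = c(42, 39, 32, 38, 44, 33),
    stringsAsFactors = FALSE)
}

# per-order name pools for the synthetic taxonomy
study_name_pools <- function() {
  list(
    class = c(Araneae = "Arachnida", Isopoda = "Malacostraca"),
    family = list(
      Araneae = c("Lycosidae", "Salticidae", "Thomisidae"),
      Coleoptera = c("Elateridae", "Scarabaeidae", "Carabidae",
                     "Curculionidae"),
      Diptera = c("Cecidomyiidae", "Tachinidae", "Muscidae"),
      Hemiptera = c("Rhopalidae", "Rhyparochromidae", "Pentatomidae"),
      Hymenoptera = c("Formicidae"),
      Isopoda = c("Armadillidiidae", "Porcellionidae"),
      Lepidoptera = c("Geometridae", "Noctuidae", "Erebidae"),
      Orthoptera = c("Acrididae", "Gryllidae", "Tettigoniidae")),
    genus = c(Lycosidae = "Pardosa", Salticidae = "Phidippus",
              Thomisidae = "Xysticus", Elateridae = "Limonius",
              Scarabaeidae = "Phyllophaga", Carabidae = "Harpalus",
              Curculionidae = "Sitona", Cecidomyiidae = "Asphondylia",
              Tachinidae = "Tachina", Muscidae = "Musca",
              Rhopalidae = "Boisea", Rhyparochromidae = "Emblethis",
              Pentatomidae = "Chlorochroa", Formicidae = "Formica",
              Armadillidiidae = "Armadillidium",
              Porcellionidae = "Porcellio", Geometridae = "Digrammia",
              Noctuidae = "Euxoa", Erebidae = "Drasteria",
              Acrididae = "Melanoplus", Gryllidae = "Gryllus",
              Tettigoniidae = "Scudderia"))
}

#' Synthetic emulation of the full study OTU table
#'
#' Builds the 53-OTU, six-pool table described above, entirely in code.
#' The incidence structure, order assignments and taxonomy depths are
#' deterministic; only read counts vary with `seed`. Two host OTUs
#' (genus *Sceloporus*) are included so the host-exclusion filter has
#' work to do.
#'
#' @param seed Integer seed for the read-count draw.
#' @return List with `table`, `metadata` (as in
#'   [generate_diet_data()]) and `truth`, which records the species x
#'   order count table (`order_counts`), the pool x order count table
#'   (`pool_order_counts`), per-species richness and sharing, and the
#'   depth counts.
#' @export
study_fixture <- function(seed = 101L) {
  metadata <- study_pools()
  # one row per distinct prey OTU: order ("" = unassigned past class)
  # and the pools that detect it; shared OTUs list one pool per species
  own <- rbind(
    data.frame(order = c("Orthoptera"), pool = "JAR_TC", n = 1),
    data.frame(order = c("Coleoptera", "Lepidoptera", "Orthoptera"),
               pool = "JAR_BP", n = c(2, 5, 1)),
    data.frame(order = c("Araneae", "Coleoptera"),
               pool = "SLE_AWRR", n = c(1, 2)),
    data.frame(order = c("Araneae", "Diptera", "Hemiptera",
                         "Hymenoptera"), pool = "SLE_BP", n = 1),
    data.frame(order = c("Araneae", "Coleoptera", "Hymenoptera",
                         "Orthoptera"), pool = "VIR_CC",
               n = c(1, 1, 1, 3)),
    data.frame(order = c("Araneae", "Coleoptera", "Diptera",
                         "Hemiptera", "Isopoda", "Orthoptera"),
               pool = "VIR_TC", n = c(1, 1, 2, 1, 6, 4)),
    data.frame(order = "", pool = c("JAR_TC", "JAR_BP", "SLE_AWRR",
                                    "SLE_AWRR", "SLE_BP", "SLE_BP",
                                    "SLE_BP", "VIR_CC", "VIR_TC"),
               n = 1))
  shared <- data.frame(
    order = c("Coleoptera", "Diptera", "Isopoda", "Orthoptera",
              "Araneae"),
    pool_a = c("JAR_TC", "JAR_BP", "JAR_TC", "JAR_BP", "SLE_BP"),
    pool_b = c("VIR_TC", "VIR_CC", "VIR_TC", "VIR_CC", "VIR_TC"),
    stringsAsFactors = FALSE)

  rows <- own[rep(seq_len(nrow(own)), own$n), c("order", "pool")]
  prey <- data.frame(order = c(rows$order, shared$order),
                     pool1 = c(rows$pool, shared$pool_a),
                     pool2 = c(rep(NA, nrow(rows)), shared$pool_b),
                     stringsAsFactors = FALSE)
  # stable layout: assigned OTUs first, by order then pool
  prey <- prey[order(prey$order == "", prey$order, prey$pool1,
                     !is.na(prey$pool2)), ]
  n_prey <- nrow(prey)  # 51

  # taxonomy depth classes for the 42 order-assigned OTUs: exactly
  # 10 order-only, 11 family, 11 genus, 10 species, scattered
  # deterministically (11 is coprime with 42)
  assigned <- which(prey$order != "")
  depth_class <- rep(c("order", "family", "genus", "species"),
                     c(10, 11, 11, 10))
  perm <- ((seq_along(assigned) - 1L) * 11L) %% length(assigned) + 1L
  prey$depth <- "class"
  prey$depth[assigned[order(perm)]] <- depth_class

  pools <- study_name_pools()
  fam_counter <- stats::setNames(integer(8), sort(unique(shared$order)))
  sp_counter <- 0L
  epithets <- c("arizonensis", "chiricahuae", "sonorae", "cochisei",
                "madrensis", "apachensis", "huachucae", "pinaleno",
                "santaritae", "animasensis")
  tax <- character(n_prey)
  conf <- numeric(n_prey)
  fam_i <- list()
  for (i in seq_len(n_prey)) {
    o <- prey$order[i]
    cl <- if (o %in% names(pools$class)) pools$class[[o]] else "Insecta"
    seg <- c(p = "Arthropoda", c = cl)
    d <- prey$depth[i]
    if (d != "class") seg <- c(seg, o = o)
    if (d %in% c("family", "genus", "species")) {
      fams <- pools$family[[o]]
      k <- (fam_i[[o]] <- (if (is.null(fam_i[[o]])) 0L
                           else fam_i[[o]]) + 1L)
      fam <- fams[(k - 1L) %% length(fams) + 1L]
      seg <- c(seg, f = fam)
      if (d %in% c("genus", "species")) {
        seg <- c(seg, g = unname(pools$genus[fam]))
        if (d == "species") {
          sp_counter <- sp_counter + 1L
          seg <- c(seg, s = epithets[sp_counter])
        }
      }
    }
    tax[i] <- paste(paste0(names(seg), "__", seg), collapse = ";")
    conf[i] <- 0.72 + 0.27 * ((i * 7L) %% 10L) / 10
  }

  ids <- sprintf("OTU_%02d", seq_len(n_prey + 2L))
  set.seed(seed)
  counts <- matrix(0L, n_prey + 2L, nrow(metadata),
                   dimnames = list(ids, metadata$pool_id))
  for (i in seq_len(n_prey)) {
    for (p in stats::na.omit(c(prey$pool1[i], prey$pool2[i])))
      counts[i, p] <- pmax(1L, round(stats::rlnorm(1L, 4, 1)))
  }
  host_tax <- paste0("p__Chordata;c__Reptilia;o__Squamata;",
                     "f__Phrynosomatidae;g__Sceloporus;s__",
                     c("jarrovii", "virgatus"))
  counts[n_prey + 1L, c("JAR_TC", "JAR_BP")] <-
    pmax(1L, round(stats::rlnorm(2L, 6, 1)))
  counts[n_prey + 2L, c("VIR_CC", "VIR_TC")] <-
    pmax(1L, round(stats::rlnorm(2L, 6, 1)))

  table <- data.frame(otu_id = ids, counts,
                      taxonomy = c(tax, host_tax),
                      confidence = c(conf, 0.99, 0.99),
                      check.names = FALSE, stringsAsFactors = FALSE)
  rownames(table) <- NULL

  orders8 <- names(pools$family)
  species <- metadata$species[match(c(prey$pool1), metadata$pool_id)]
  oc <- table(factor(species, levels = unique(metadata$species)),
              factor(prey$order, levels = orders8))
  sp2 <- metadata$species[match(prey$pool2, metadata$pool_id)]
  oc2 <- table(factor(sp2, levels = unique(metadata$species)),
               factor(prey$order, levels = orders8))
  poc <- table(factor(prey$pool1, levels = metadata$pool_id),
               factor(prey$order, levels = orders8)) +
    table(factor(prey$pool2, levels = metadata$pool_id),
          factor(prey$order, levels = orders8))
  strip <- function(m) {
    m <- unclass(m)
    storage.mode(m) <- "integer"
    names(dimnames(m)) <- NULL
    m
  }
  truth <- list(
    order_counts = strip(oc + oc2),
    pool_order_counts = strip(poc),
    richness = c("Sceloporus jarrovii" = 15, "Sceloporus slevini" = 13,
                 "Sceloporus virgatus" = 28),
    shared = c("jarrovii&virgatus" = 4, "slevini&virgatus" = 1,
               "jarrovii&slevini" = 0),
    depth_counts = c(order = 42, family = 32, genus = 21, species = 10))
  list(table = table, metadata = metadata, truth = truth)
}
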