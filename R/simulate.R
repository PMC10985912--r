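#' Configuration for the paired-community simulator
#'
#' Defaults reproduce the sampling design of the field study the pipeline is
#' built around: three (sub-)alpine forest locations sampled snow-free and
#' snow covered (13/12, 19/14 and 13/8 samples; 79 in total), per-sample
#' sequencing depths of about 6,500 +/- 2,320 fungal and 60,000 +/- 16,000
#' bacterial reads, and a fungi << bacteria richness asymmetry (150 fungal
#' vs 600 bacterial ASVs at desk scale). Planted cross-kingdom edges define
#' the latent ground truth used for recovery scoring.
#'
#' @param groups data.frame with columns `location`, `condition`, `n`
#'   giving the number of samples per location x condition cell.
#' @param n_fungi,n_bacteria numbers of ASVs per kingdom.
#' @param depth_mean,depth_sd named numeric vectors (`fungi`, `bacteria`)
#'   of sequencing-depth mean and sd; depths are truncated below at
#'   `depth_floor`.
#' @param depth_floor minimum depth (avoids degenerate CLR samples).
#' @param n_core named integer vector: how many ASVs per kingdom are forced
#'   to be detected in every location (the "core").
#' @param occupancy_shape,occupancy_decay shape parameters of the Beta
#'   occupancy distribution `Beta(occupancy_shape, occupancy_decay)`;
#'   the defaults give a heavy-tailed prevalence profile in which the
#'   median ASV is detected in 2-3 of 79 samples and roughly a tenth of
#'   ASVs survive an occurrence-10 filter, the desk-scale analogue of the
#'   reference dataset's prevalence structure.
#' @param abundance_sd sd of the per-ASV log-normal mean abundance.
#' @param planted_edges data.frame with columns `fungus`, `bacterium`
#'   (ASV indices within kingdom), `rho` (signed latent correlation in
#'   (-1, 1)) and `condition` in `{"snow_free", "snow_covered", "both"}`.
#'   Defaults plant 10 edges of |rho| = 0.7 (4 in both conditions, 3
#'   snow-free-only, 3 snow-covered-only; mixed signs) between core ASVs.
#' @param planted_occupancy minimum occupancy probability given to planted
#'   edge endpoints so the planted signal is identifiable.
#' @param planted_abundance log-scale floor on the mean abundance of
#'   planted edge endpoints: planted associations emulate links between
#'   consistently detected, reasonably abundant taxa, the regime in which
#'   association studies report recurrent links; rare endpoints would be
#'   dominated by count noise and carry no recoverable signal.
#' @param genus_coverage fraction of ASVs receiving a genus annotation.
#' @param seed default seed used by [simulate_communities()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(groups = default_groups(),
                       n_fungi = 150L, n_bacteria = 600L,
                       depth_mean = c(fungi = 6500, bacteria = 60000),
                       depth_sd = c(fungi = 2320, bacteria = 16000),
                       depth_floor = 100,
                       n_core = c(fungi = 8L, bacteria = 72L),
                       occupancy_shape = 0.3,
                       occupancy_decay = 4.0,
                       abundance_sd = 1.5,
                       planted_edges = default_planted_edges(),
                       planted_occupancy = 1.0,
                       planted_abundance = 1.5,
                       genus_coverage = 0.7,
                       seed = 1L) {
  stopifnot(all(c("location", "condition", "n") %in% names(groups)),
            all(groups$n >= 1L),
            n_fungi >= 2L, n_bacteria >= 2L,
            occupancy_shape > 0, occupancy_decay > 0, abundance_sd > 0,
            planted_occupancy > 0, planted_occupancy <= 1)
  groups$condition <- normalize_condition(groups$condition)
  pe <- planted_edges
  if (nrow(pe)) {
    stopifnot(all(c("fungus", "bacterium", "rho", "condition") %in% names(pe)),
              all(abs(pe$rho) > 0), all(abs(pe$rho) < 1),
              all(pe$fungus >= 1L), all(pe$fungus <= n_fungi),
              all(pe$bacterium >= 1L), all(pe$bacterium <= n_bacteria),
              all(pe$condition %in% c(CONDITIONS, "both")))
    if (anyDuplicated(pe$fungus) || anyDuplicated(pe$bacterium)) {
      stop("planted edges must have disjoint endpoints")
    }
  }
  structure(list(groups = groups, n_fungi = as.integer(n_fungi),
                 n_bacteria = as.integer(n_bacteria),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 depth_floor = depth_floor, n_core = n_core,
                 occupancy_shape = occupancy_shape,
                 occupancy_decay = occupancy_decay,
                 abundance_sd = abundance_sd,
                 planted_edges = pe,
                 planted_occupancy = planted_occupancy,
                 planted_abundance = planted_abundance,
                 genus_coverage = genus_coverage, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_groups <- function() {
  data.frame(
    location = rep(c("Kuehtai", "Patscherkofel", "Praxmar"), each = 2L),
    condition = rep(c("snow_free", "snow_covered"), 3L),
    n = c(13L, 12L, 19L, 14L, 13L, 8L),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_planted_edges <- function() {
  data.frame(
    fungus = 1:10,
    bacterium = 1:10,
    rho = 0.7 * rep(c(1, -1), 5L),
    condition = c(rep("both", 4L), rep("snow_free", 3L),
                  rep("snow_covered", 3L)),
    stringsAsFactors = FALSE
  )
}

fungal_phyla <- c("Basidiomycota", "Ascomycota", "Mortierellomycotina",
                  "Mucoromycotina")
bacterial_phyla <- c("Proteobacteria", "Acidobacteriota", "Actinobacteriota",
                     "Verrucomicrobiota", "Bacteroidota", "Firmicutes",
                     "Planctomycetota", "Myxococcota")
fungal_genera <- c("Russula", "Mortierella", "Basidioascus", "Rhizopogon",
                   "Solicoccozyma", "Tetracladium", "Umbelopsis",
                   "Cladophialophora", "Pseudotomentella", "Mucor",
                   "Suillus", "Phenoliferia")
bacterial_genera <- c("Acidothermus", "Granulicella", "Mycobacterium",
                      "Bryobacter", "Mucilaginibacter", "Conexibacter",
                      "Methylocella", "Acidibacter", "Psychrobacillus",
                      "Acidicapsa", "Pajaroellobacter", "Bradyrhizobium")

# truncated-normal depths by rejection; mean >> floor so this is cheap
draw_depths <- function(n, mean, sd, floor) {
  d <- round(rnorm(n, mean, sd))
  while (any(bad <- d < floor)) d[bad] <- round(rnorm(sum(bad), mean, sd))
  as.integer(d)
}

make_taxonomy <- function(ids, phyla, genera, genus_coverage) {
  n <- length(ids)
  data.frame(
    asv_id = ids,
    phylum = rep_len(phyla, n),
    class = rep_len(paste0(phyla, "_class"), n),
    order = rep_len(paste0(phyla, "_order"), n),
    family = rep_len(paste0(genera, "aceae"), n),
    genus = ifelse(seq_len(n) %% 10L < 10L * genus_coverage,
                   rep_len(genera, n), NA_character_),
    species = ifelse(seq_len(n) %% 10L %in% c(1L, 4L, 7L),
                     paste0(tolower(rep_len(genera, n)), "_sp", seq_len(n)),
                     NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Simulate paired fungal/bacterial communities with planted associations
#'
#' Per sample, a latent multivariate-normal vector over all ASVs (unit
#' marginals; correlation `rho` on planted edges active in that sample's
#' condition, zero elsewhere) is mapped through per-ASV log-normal abundance
#' profiles, masked by a heavy-tailed Bernoulli occupancy pattern, and
#' converted to counts by multinomial sampling at a truncated-normal depth.
#' Core ASVs are guaranteed to be detected in at least one sample of every
#' location. A Gaussian copula is used because the downstream inference
#' works on CLR-space partial correlations, so planted edges keep a
#' controllable magnitude and sign there.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return a list of class `fb_simulation` with elements `fungi` and
#'   `bacteria` ([asv_table()]s), `taxonomy`, `metadata`, and `truth`
#'   (planted edges as ASV id pairs plus the per-kingdom core ids).
#' @export
simulate_communities <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  pF <- config$n_fungi; pB <- config$n_bacteria; p <- pF + pB
  fid <- sprintf("F%04d", seq_len(pF))
  bid <- sprintf("B%04d", seq_len(pB))

  g <- config$groups
  meta <- data.frame(
    sample_id = character(0), location = character(0),
    condition = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    tag <- paste0(toupper(substr(g$location[i], 1L, 2L)),
                  ifelse(g$condition[i] == "snow_free", "_SF_", "_SC_"))
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("%s%02d", tag, seq_len(g$n[i])),
      location = g$location[i],
      condition = as.character(g$condition[i]),
      stringsAsFactors = FALSE))
  }
  meta$condition <- normalize_condition(meta$condition)
  n <- nrow(meta)

  # per-ASV profiles
  mu <- rnorm(p, 0, config$abundance_sd)            # log mean abundance
  occ <- rbeta(p, config$occupancy_shape, config$occupancy_decay)  # occupancy
  core_f <- fid[seq_len(config$n_core[["fungi"]])]
  core_b <- bid[seq_len(config$n_core[["bacteria"]])]
  pe <- config$planted_edges
  idxF <- pe$fungus; idxB <- pF + pe$bacterium
  occ[c(idxF, idxB)] <- pmax(occ[c(idxF, idxB)], config$planted_occupancy)
  mu[c(idxF, idxB)] <- pmax(mu[c(idxF, idxB)], config$planted_abundance)

  # latent draws; block-diagonal correlation is sampled pair by pair
  z <- matrix(rnorm(n * p), n, p)
  for (e in seq_len(nrow(pe))) {
    rows <- if (pe$condition[e] == "both") seq_len(n) else
      which(meta$condition == pe$condition[e])
    r <- pe$rho[e]
    a <- idxF[e]; b <- idxB[e]
    z[rows, b] <- r * z[rows, a] + sqrt(1 - r^2) * z[rows, b]
  }

  mask <- matrix(runif(n * p) < rep(occ, each = n), n, p)
  # core forcing at the mask level; count-level repair below is the guarantee
  for (ids in list(match(core_f, fid), pF + match(core_b, bid))) {
    for (loc in unique(meta$location)) {
      rows <- which(meta$location == loc)
      none <- ids[colSums(mask[rows, ids, drop = FALSE]) == 0L]
      if (length(none)) {
        mask[cbind(sample(rows, length(none), replace = TRUE), none)] <- TRUE
      }
    }
  }

  w <- exp(sweep(z, 2L, mu, "+")) * mask
  counts <- matrix(0L, n, p)
  depths <- list()
  for (k in seq_len(2L)) {
    cols <- if (k == 1L) seq_len(pF) else pF + seq_len(pB)
    kng <- KINGDOMS[k]
    depth <- draw_depths(n, config$depth_mean[[kng]], config$depth_sd[[kng]],
                         config$depth_floor)
    depths[[kng]] <- setNames(depth, meta$sample_id)
    for (i in seq_len(n)) {
      wi <- w[i, cols]
      if (all(wi == 0)) wi[which.max(mu[cols])] <- 1   # degenerate sample
      counts[i, cols] <- rmultinom(1L, depth[i], wi)
    }
  }
  dimnames(counts) <- list(meta$sample_id, c(fid, bid))

  # guarantee core detection in every location: move one read if needed
  for (core in list(core_f, core_b)) {
    for (id in core) {
      j <- match(id, colnames(counts))
      kcols <- if (j <= pF) seq_len(pF) else pF + seq_len(pB)
      for (loc in unique(meta$location)) {
        rows <- which(meta$location == loc)
        if (sum(counts[rows, j]) == 0L) {
          i <- rows[which.max(rowSums(counts[rows, kcols, drop = FALSE]))]
          donor <- kcols[which.max(counts[i, kcols])]
          counts[i, donor] <- counts[i, donor] - 1L
          counts[i, j] <- 1L
        }
      }
    }
  }

  # identifiability of planted edges: realized co-presence per condition
  truth_edges <- data.frame(
    fungal_id = fid[idxF], bacterial_id = bid[idxB - pF],
    sign = ifelse(pe$rho > 0, "+", "-"), rho = pe$rho,
    condition = pe$condition,
    weakly_identifiable = rep(FALSE, nrow(pe)),
    stringsAsFactors = FALSE)
  for (e in seq_len(nrow(truth_edges))) {
    conds <- if (pe$condition[e] == "both") CONDITIONS else pe$condition[e]
    for (cc in conds) {
      rows <- meta$condition == cc
      co <- sum(counts[rows, idxF[e]] > 0L & counts[rows, idxB[e]] > 0L)
      if (co < 4L) truth_edges$weakly_identifiable[e] <- TRUE
    }
  }
  if (any(truth_edges$weakly_identifiable)) {
    warning(sum(truth_edges$weakly_identifiable),
            " planted edge(s) have < 4 co-occurrences in an active",
            " condition and are flagged weakly identifiable")
  }

  taxonomy <- rbind(
    make_taxonomy(fid, fungal_phyla, fungal_genera, config$genus_coverage),
    make_taxonomy(bid, bacterial_phyla, bacterial_genera,
                  config$genus_coverage))

  # ASVs that never materialised a read are trimmed silently: they carry
  # no occurrence information and their ids stay out of the truth
  detected <- colSums(counts) > 0L
  structure(list(
    fungi = asv_table(counts[, fid[detected[seq_len(pF)]], drop = FALSE],
                      "fungi"),
    bacteria = asv_table(counts[, bid[detected[pF + seq_len(pB)]],
                                drop = FALSE], "bacteria"),
    taxonomy = taxonomy, metadata = meta, depths = depths,
    truth = structure(list(edges = truth_edges,
                           core = list(fungi = core_f, bacteria = core_b)),
                      class = "fb_truth"),
    config = config), class = "fb_simulation")
}

#' @export
print.fb_simulation <- function(x, ...) {
  cat("<fb_simulation> ", nrow(x$metadata), " samples, ",
      ncol(x$fungi$counts), " fungal + ", ncol(x$bacteria$counts),
      " bacterial ASVs, ", nrow(x$truth$edges), " planted edges\n", sep = "")
  invisible(x)
}

#' Planted edges active in a condition
#'
#' Edges planted for `"both"` conditions appear in every condition's set.
#'
#' @param truth the `truth` element of a [simulate_communities()] result.
#' @param condition `"snow_free"` or `"snow_covered"`.
#' @return character vector of canonical edge keys (`"idA|idB"`, ids
#'   sorted), named by planted sign.
#' @export
truth_edge_set <- function(truth, condition) {
  condition <- as.character(normalize_condition(condition))
  e <- truth$edges
  e <- e[e$condition %in% c(condition, "both"), , drop = FALSE]
  setNames(edge_key(e$fungal_id, e$bacterial_id), e$sign)
}

#' Canonical key of an unordered ASV pair
#'
#' Associations are identified by the sorted id pair, so keys are
#' comparable across networks and against the planted truth.
#'
#' @param a,b character vectors of ASV ids.
#' @return character vector of `"smaller|larger"` keys.
#' @export
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Write a simulated dataset to TSV files
#'
#' Emits the same formats the readers accept: per-kingdom ASV tables,
#' taxonomy, metadata, and the planted truth
#' (`fungal_id, bacterial_id, sign, condition`).
#'
#' @param sim an `fb_simulation`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fb_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    fungi = file.path(dir, "asv_table_fungi.tsv"),
    bacteria = file.path(dir, "asv_table_bacteria.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth_edges.tsv"))
  write_asv_table(sim$fungi, files[["fungi"]])
  write_asv_table(sim$bacteria, files[["bacteria"]])
  write.table(sim$taxonomy, files[["taxonomy"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$metadata, files[["metadata"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$edges, files[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(files)
}
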