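#' Alpha diversity per sample
#'
#' Richness is the number of ASVs with count >= 1; Shannon diversity is
#' `-sum(p_i * log(p_i))` over nonzero proportions, natural log.
#'
#' @param table an [asv_table()].
#' @return `data.frame` with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  depth <- rowSums(table$counts)
  if (any(depth == 0)) {
    stop("zero-depth sample(s): ",
         paste(rownames(table$counts)[depth == 0], collapse = ", "))
  }
  data.frame(
    sample_id = sample_ids(table),
    richness = as.integer(rowSums(table$counts > 0L)),
    shannon = as.numeric(vegan::diversity(table$counts, index = "shannon")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distances between samples
#'
#' @param x matrix of counts or proportions (samples in rows), or an
#'   [asv_table()].
#' @return a `dist` object.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "asv_table")) x <- x$counts
  if (nrow(x) < 2L) stop("need at least 2 samples")
  vegan::vegdist(x, method = "bray")
}

#' Permutational analysis of variance on a distance matrix
#'
#' Single-factor PERMANOVA (the adonis2 decomposition): R2 is the
#' between-group share of the total sum of squared distances, and the
#' p-value is `(1 + #{permuted F >= observed F}) / (1 + n_perm)` under free
#' permutation of sample labels.
#'
#' @param dist a `dist` object.
#' @param labels factor of group labels, one per sample.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional seed for the permutation stream.
#' @return list with `pseudo_F`, `R2`, `p`, and `n_perm`.
#' @export
permanova <- function(dist, labels, n_perm = 999L, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("labels must have >= 2 levels")
  if (any(table(labels) < 2L)) stop("every group needs >= 2 samples")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(labels = labels)
  fit <- vegan::adonis2(dist ~ labels, data = df, permutations = n_perm)
  r2 <- fit$R2[1L]
  if (!is.finite(r2)) {
    # degenerate case: zero total sum of squares (all samples identical)
    return(list(pseudo_F = 0, R2 = 0, p = 1, n_perm = as.integer(n_perm)))
  }
  list(pseudo_F = fit$F[1L], R2 = r2, p = fit$`Pr(>F)`[1L],
       n_perm = as.integer(n_perm))
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Dunn's pairwise rank-sum z-tests (with tie correction) are only run when
#' the omnibus Kruskal-Wallis test is significant at `alpha`; pairwise
#' p-values are Holm-adjusted.
#'
#' @param values numeric vector, one value per sample.
#' @param groups factor of group labels.
#' @param alpha omnibus significance gate for the post-hoc step.
#' @return list with `omnibus_p`, `statistic`, and `dunn` (a `data.frame`
#'   of pairwise comparisons, or `NULL` when the omnibus test is not
#'   significant).
#' @export
groupwise_kruskal_dunn <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  kw <- kruskal.test(values, groups)
  dunn <- NULL
  if (is.finite(kw$p.value) && kw$p.value < alpha) dunn <- dunn_test(values, groups)
  list(omnibus_p = kw$p.value, statistic = unname(kw$statistic), dunn = dunn)
}

# Dunn (1964) z-tests on mean ranks with tie correction, Holm adjustment
dunn_test <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ], z = z,
             p = p, p_holm = p.adjust(p, "holm"),
             stringsAsFactors = FALSE)
}

#' Per-phylum ASV richness contrast between conditions
#'
#' Computes per-sample ASV richness within each phylum (unannotated ASVs are
#' grouped as `"unknown"`), reports condition medians, and tests the
#' condition difference per phylum with a Kruskal-Wallis test. Phyla whose
#' total ASV count is `<= min_asvs` are excluded.
#'
#' @param table an [asv_table()].
#' @param taxonomy taxonomy `data.frame` (`asv_id`, `phylum`, ...).
#' @param meta sample metadata.
#' @param min_asvs minimum total number of ASVs for a phylum to be reported.
#' @return `data.frame` with one row per reported phylum: `phylum`,
#'   `n_asvs`, `median_snow_free`, `median_snow_covered`, `p_kruskal`.
#' @export
phylum_richness_contrast <- function(table, taxonomy, meta, min_asvs = 10L) {
  m <- aligned_meta(table, meta)
  phy <- taxonomy$phylum[match(asv_ids(table), taxonomy$asv_id)]
  phy[is.na(phy)] <- "unknown"
  pres <- table$counts > 0L
  out <- list()
  for (ph in sort(unique(phy))) {
    cols <- phy == ph
    if (sum(cols) <= min_asvs) next
    rich <- rowSums(pres[, cols, drop = FALSE])
    sf <- rich[m$condition == "snow_free"]
    sc <- rich[m$condition == "snow_covered"]
    p <- if (length(sf) && length(sc)) {
      kruskal.test(list(sf, sc))$p.value
    } else NA_real_
    out[[ph]] <- data.frame(
      phylum = ph, n_asvs = sum(cols),
      median_snow_free = median(sf), median_snow_covered = median(sc),
      p_kruskal = p, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(phylum = character(0), n_asvs = integer(0),
                      median_snow_free = numeric(0),
                      median_snow_covered = numeric(0),
                      p_kruskal = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
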