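#' ASV count tables
#'
#' An `asv_table` holds the samples x ASVs integer count matrix for one
#' kingdom (fungi or bacteria), with unique sample and ASV identifiers as
#' dimnames. All-zero ASV columns carry no occurrence information and are
#' dropped on construction with a warning.
#'
#' @param counts non-negative integer matrix, samples in rows, ASVs in
#'   columns; both dimensions named with unique identifiers.
#' @param kingdom `"fungi"` or `"bacteria"`.
#' @return an object of class `asv_table`: a list with elements `counts`
#'   (integer matrix) and `kingdom`.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L, 5L, 0L), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), c("F001", "F002")))
#' asv_table(m, "fungi")
#' @export
asv_table <- function(counts, kingdom = c("fungi", "bacteria")) {
  kingdom <- match.arg(kingdom)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("empty ASV table (", nrow(counts), " samples x ",
         ncol(counts), " ASVs)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample row names and ASV column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and complete")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers")
  }
  storage.mode(counts) <- "integer"
  zero <- colSums(counts) == 0L
  if (any(zero)) {
    warning(sum(zero), " all-zero ASV column(s) dropped: ",
            paste(head(colnames(counts)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    counts <- counts[, !zero, drop = FALSE]
    if (ncol(counts) == 0L) stop("all ASV columns were zero")
  }
  structure(list(counts = counts, kingdom = kingdom), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("<asv_table> ", x$kingdom, ": ", nrow(x$counts), " samples x ",
      ncol(x$counts), " ASVs, ", sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

#' @rdname asv_table
#' @param x an `asv_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname asv_table
#' @export
asv_ids <- function(x) colnames(x$counts)

#' Read and write ASV tables as TSV
#'
#' The on-disk format is tab-separated with a header row of ASV ids and the
#' sample id in the first column (`orientation = "samples_rows"`), or the
#' transpose (`orientation = "asvs_rows"`). Orientation is declared, never
#' silently guessed: if the declared orientation looks implausible (far more
#' rows than a study has samples) a warning is emitted but the declaration
#' still wins.
#'
#' @param path file path.
#' @param kingdom `"fungi"` or `"bacteria"`.
#' @param orientation `"samples_rows"` (default) or `"asvs_rows"`.
#' @return `read_asv_table()` returns an [asv_table()]; `write_asv_table()`
#'   returns `path` invisibly.
#' @export
read_asv_table <- function(path, kingdom = c("fungi", "bacteria"),
                           orientation = c("samples_rows", "asvs_rows")) {
  kingdom <- match.arg(kingdom)
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ASV table must have an id column plus counts: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "asvs_rows") m <- t(m)
  if (nrow(m) > 10L * ncol(m) && nrow(m) > 1000L) {
    warning("declared orientation keeps ", nrow(m), " samples x ", ncol(m),
            " ASVs; check the 'orientation' flag")
  }
  asv_table(m, kingdom)
}

#' @rdname read_asv_table
#' @param x an `asv_table`.
#' @export
write_asv_table <- function(x, path) {
  stopifnot(inherits(x, "asv_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read taxonomy and sample metadata tables
#'
#' Taxonomy is a TSV with columns `asv_id, phylum, class, order, family,
#' genus, species` (missing ranks as empty fields or NA; stored as `NA`).
#' Metadata is a TSV with columns `sample_id, location, condition`, the
#' condition being snow-free or snow covered in any common spelling.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"asv_id" %in% names(df)) stop("taxonomy needs an 'asv_id' column")
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy")
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  for (r in setdiff(ranks, names(df))) df[[r]] <- NA_character_
  df[, c("asv_id", ranks)]
}

#' @rdname read_taxonomy
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "location", "condition")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df$condition <- normalize_condition(df$condition)
  df[, need]
}

# metadata rows aligned to the table's samples; errors on gaps
aligned_meta <- function(table, meta) {
  stopifnot(inherits(table, "asv_table"))
  miss <- setdiff(sample_ids(table), meta$sample_id)
  if (length(miss)) {
    stop("samples missing from metadata: ", paste(head(miss, 5), collapse = ", "))
  }
  meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
}

#' Core ASVs: detected in every location
#'
#' A core ASV is one detected (count >= 1) in at least one sample from every
#' location, the criterion used to call taxa typical for the habitat across
#' independent forests. No abundance floor is applied.
#'
#' @param table an [asv_table()].
#' @param meta sample metadata (`sample_id`, `location`, `condition`).
#' @return character vector of core ASV ids.
#' @export
core_asvs <- function(table, meta) {
  m <- aligned_meta(table, meta)
  locs <- unique(m$location)
  if (length(locs) < 2L) {
    stop("core ASVs are undefined with a single location")
  }
  present <- table$counts > 0L
  in_all <- rep(TRUE, ncol(present))
  for (loc in locs) {
    in_all <- in_all & colSums(present[m$location == loc, , drop = FALSE]) > 0L
  }
  asv_ids(table)[in_all]
}

#' Per-sample relative abundances
#'
#' @param table an [asv_table()].
#' @return matrix of proportions, each row summing to 1.
#' @export
relative_abundance <- function(table) {
  depth <- rowSums(table$counts)
  if (any(depth == 0)) {
    stop("zero-depth sample(s): ",
         paste(rownames(table$counts)[depth == 0], collapse = ", "))
  }
  sweep(table$counts, 1L, depth, "/")
}

#' Abundant ASVs within each sample group
#'
#' Groups are location x condition. Within each group the mean of per-sample
#' relative abundances is taken; ASVs at or above `threshold` are reported.
#'
#' @param table an [asv_table()].
#' @param meta sample metadata.
#' @param threshold proportion in (0, 1]; mean relative abundance cut-off.
#' @return named list (one element per non-empty group) of ASV id vectors.
#' @export
abundant_asvs_per_group <- function(table, meta, threshold) {
  if (!(threshold >= 0 && threshold <= 1)) {
    stop("threshold must be a proportion in [0, 1]")
  }
  m <- aligned_meta(table, meta)
  ra <- relative_abundance(table)
  groups <- interaction(m$location, m$condition, sep = ":", drop = FALSE)
  out <- list()
  for (g in levels(groups)) {
    rows <- groups == g
    if (!any(rows)) {
      warning("empty sample group skipped: ", g)
      next
    }
    mu <- colMeans(ra[rows, , drop = FALSE])
    out[[g]] <- asv_ids(table)[mu >= threshold]
  }
  out
}

#' Condition-exclusive core ASVs
#'
#' Partitions a set of core ASVs by detection pattern across conditions:
#' detected only in snow-free samples, only in snow-covered samples, or in
#' both. Exclusivity means zero counts in every sample of the other
#' condition.
#'
#' @param table an [asv_table()].
#' @param meta sample metadata.
#' @param core character vector of core ASV ids (subset of the table's ASVs).
#' @return `data.frame` with columns `asv_id`, `n_snow_free`,
#'   `n_snow_covered` (occurrence counts) and `exclusivity` in
#'   `{"snow_free_only", "snow_covered_only", "both"}`.
#' @export
condition_exclusive_core <- function(table, meta, core) {
  if (!all(core %in% asv_ids(table))) {
    stop("core contains ids not in the table")
  }
  m <- aligned_meta(table, meta)
  pres <- table$counts[, core, drop = FALSE] > 0L
  n_sf <- colSums(pres[m$condition == "snow_free", , drop = FALSE])
  n_sc <- colSums(pres[m$condition == "snow_covered", , drop = FALSE])
  excl <- ifelse(n_sf > 0 & n_sc == 0, "snow_free_only",
          ifelse(n_sc > 0 & n_sf == 0, "snow_covered_only", "both"))
  data.frame(asv_id = core, n_snow_free = as.integer(n_sf),
             n_snow_covered = as.integer(n_sc), exclusivity = excl,
             row.names = NULL, stringsAsFactors = FALSE)
}
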