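#' Per-ASV occurrence counts
#'
#' Occurrence of an ASV is the number of samples in which it is detected
#' (count >= 1). Filtering operates on occurrence, not abundance.
#'
#' @param table an [asv_table()].
#' @return named integer vector (one entry per ASV).
#' @export
occurrence <- function(table) {
  setNames(as.integer(colSums(table$counts > 0L)), asv_ids(table))
}

#' Filter a table by minimum sample occurrence
#'
#' Keeps exactly those ASVs detected in at least `threshold` samples (an ASV
#' detected in exactly `threshold` samples survives). Samples are left
#' unchanged; a sample left with zero reads only triggers a warning because
#' downstream steps decide how to handle it.
#'
#' @param table an [asv_table()].
#' @param threshold integer >= 1, minimum number of samples.
#' @return a filtered [asv_table()].
#' @export
filter_by_occurrence <- function(table, threshold) {
  if (threshold < 1L) stop("threshold must be >= 1")
  keep <- occurrence(table) >= threshold
  if (!any(keep)) {
    stop("no ", table$kingdom, " ASVs occur in >= ", threshold, " samples")
  }
  counts <- table$counts[, keep, drop = FALSE]
  if (any(rowSums(counts) == 0L)) {
    warning("filtering left ", sum(rowSums(counts) == 0L),
            " zero-depth sample(s)")
  }
  structure(list(counts = counts, kingdom = table$kingdom),
            class = "asv_table")
}

#' Build the occurrence-threshold filter grid
#'
#' Crosses a vector of fungal thresholds with a vector of bacterial
#' thresholds; each combination yields one filtered table pair. The default
#' vectors give the 5 x 5 = 25 pairs of the reference design. Ordering is
#' deterministic: fungal threshold major, both ascending.
#'
#' @param fungal,bacterial [asv_table()]s covering the same samples.
#' @param t_fungal,t_bacterial integer threshold vectors.
#' @return list of `filtered_pair` objects, each with elements `fungi`,
#'   `bacteria`, `t_fungal`, `t_bacterial`.
#' @export
build_grid <- function(fungal, bacterial,
                       t_fungal = c(5L, 7L, 9L, 11L, 19L),
                       t_bacterial = c(10L, 20L, 31L, 39L, 46L)) {
  stopifnot(length(t_fungal) >= 1L, length(t_bacterial) >= 1L)
  if (!identical(sample_ids(fungal), sample_ids(bacterial))) {
    stop("fungal and bacterial tables must cover the same samples")
  }
  t_fungal <- sort(as.integer(t_fungal))
  t_bacterial <- sort(as.integer(t_bacterial))
  # filter each kingdom once per threshold, then cross
  ftabs <- lapply(t_fungal, function(t) {
    tryCatch(filter_by_occurrence(fungal, t),
             error = function(e) stop("fungal threshold ", t, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  btabs <- lapply(t_bacterial, function(t) {
    tryCatch(filter_by_occurrence(bacterial, t),
             error = function(e) stop("bacterial threshold ", t, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  grid <- list()
  for (i in seq_along(t_fungal)) {
    for (j in seq_along(t_bacterial)) {
      grid[[length(grid) + 1L]] <- structure(
        list(fungi = ftabs[[i]], bacteria = btabs[[j]],
             t_fungal = t_fungal[i], t_bacterial = t_bacterial[j]),
        class = "filtered_pair")
    }
  }
  grid
}

#' @export
print.filtered_pair <- function(x, ...) {
  cat("<filtered_pair> t_F=", x$t_fungal, " t_B=", x$t_bacterial, ": ",
      ncol(x$fungi$counts), " fungi + ", ncol(x$bacteria$counts),
      " bacteria\n", sep = "")
  invisible(x)
}

#' Suggest occurrence thresholds from the retention curve
#'
#' Advisory "shoulder" heuristic: for each threshold t the number of ASVs
#' retained (occurrence >= t) is computed; candidate thresholds sit at the
#' k largest relative drops of this retention curve, ties broken towards
#' smaller thresholds. Grid thresholds remain explicit configuration; this
#' only suggests.
#'
#' @param occ named integer vector of occurrences (from [occurrence()]).
#' @param k number of candidates.
#' @return sorted integer vector of k candidate thresholds.
#' @export
suggest_thresholds <- function(occ, k) {
  stopifnot(k >= 1L)
  n <- max(occ)
  retained <- vapply(seq_len(n), function(t) sum(occ >= t), integer(1L))
  if (length(unique(occ)) == 1L) {
    warning("flat occurrence distribution; returning evenly spaced thresholds")
    return(unique(as.integer(round(seq(1L, n, length.out = k)))))
  }
  # relative drop moving from t-1 to t (t >= 2)
  drops <- (retained[-n] - retained[-1L]) / retained[-n]
  if (k > sum(drops > 0)) {
    warning("fewer distinct drops than k; returning all drop points")
    k <- sum(drops > 0)
  }
  ord <- order(-drops, seq_along(drops))  # ties -> smaller threshold
  sort(as.integer(ord[seq_len(k)] + 1L))
}
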