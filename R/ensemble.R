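#' Fit a paired association-network ensemble over the filter grid
#'
#' The central fitting step of the package: the two kingdoms' tables are
#' filtered at every combination of the occurrence thresholds, and for each
#' filtered pair one snow-free and one snow-covered network is inferred
#' (joint CLR, Meinshausen-Buhlmann neighborhood selection, StARS penalty
#' selection, weighted refit). The default 5 x 5 grid yields 25 + 25 = 50
#' networks.
#'
#' @param fungal,bacterial [asv_table()]s over the same samples.
#' @param meta sample metadata (`sample_id`, `location`, `condition`).
#' @param t_fungal,t_bacterial occurrence-threshold vectors (defaults
#'   5, 7, 9, 11, 19 and 10, 20, 31, 39, 46).
#' @param control a [stars_control()].
#' @param seed master seed; every network gets a derived stream.
#' @param rule edge-weight symmetrisation rule (see [refit_and_weight()]).
#' @param progress print one line per filter pair.
#' @return an object of class `network_ensemble`: list with `networks`
#'   (list with `snow_free` and `snow_covered`, each one network per filter
#'   pair, in grid order), `grid` (`data.frame` of thresholds),
#'   `properties` (one row per network, see [network_properties()]), and
#'   the call parameters.
#' @seealso [summary.network_ensemble()], [frequent_associations()]
#' @export
infer_network_ensemble <- function(fungal, bacterial, meta,
                                   t_fungal = c(5L, 7L, 9L, 11L, 19L),
                                   t_bacterial = c(10L, 20L, 31L, 39L, 46L),
                                   control = stars_control(), seed = 1L,
                                   rule = "max", progress = FALSE) {
  grid <- build_grid(fungal, bacterial, t_fungal, t_bacterial)
  nets <- list(snow_free = vector("list", length(grid)),
               snow_covered = vector("list", length(grid)))
  props <- list()
  for (i in seq_along(grid)) {
    fp <- grid[[i]]
    if (progress) {
      cat(sprintf("[%2d/%d] t_F=%d t_B=%d\n", i, length(grid),
                  fp$t_fungal, fp$t_bacterial))
    }
    pair_nets <- infer_condition_networks(fp, meta, control = control,
                                          seed = seed, rule = rule)
    for (cond in CONDITIONS) {
      nets[[cond]][[i]] <- pair_nets[[cond]]
      props[[length(props) + 1L]] <- suppressWarnings(
        network_properties(pair_nets[[cond]]))
    }
  }
  structure(list(
    networks = nets,
    grid = data.frame(
      t_fungal = vapply(grid, `[[`, integer(1L), "t_fungal"),
      t_bacterial = vapply(grid, `[[`, integer(1L), "t_bacterial")),
    properties = do.call(rbind, c(props, list(make.row.names = FALSE))),
    t_fungal = sort(as.integer(t_fungal)),
    t_bacterial = sort(as.integer(t_bacterial)),
    control = control, seed = seed, rule = rule),
    class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  n <- nrow(x$grid)
  cat("<network_ensemble> ", n, " filter pairs -> ", 2L * n,
      " networks\n", sep = "")
  cat("  fungal thresholds:    ", paste(x$t_fungal, collapse = ", "), "\n")
  cat("  bacterial thresholds: ", paste(x$t_bacterial, collapse = ", "), "\n")
  med <- tapply(x$properties$n_edges, x$properties$condition, median)
  cat("  median edges: snow-free ", med[["snow_free"]],
      ", snow covered ", med[["snow_covered"]], "\n", sep = "")
  invisible(x)
}

#' Summarise a network ensemble: paired condition comparison
#'
#' For each network property, the snow-free and snow-covered values are
#' compared across the grid with the paired signed-rank test
#' ([paired_property_test()]); properties with fewer than 3 nonzero paired
#' differences are reported with `p = NA`.
#'
#' @param object a `network_ensemble`.
#' @param properties character vector of property columns to test.
#' @param ... unused.
#' @return object of class `summary.network_ensemble`: `data.frame` with
#'   medians per condition and the paired p-value.
#' @export
summary.network_ensemble <- function(object,
                                     properties = c("n_nodes", "n_edges",
                                                    "density", "fb_density",
                                                    "n_ff", "n_fb", "n_bb",
                                                    "longest_path",
                                                    "odds_positive"),
                                     ...) {
  pr <- object$properties
  sf <- pr[pr$condition == "snow_free", , drop = FALSE]
  sc <- pr[pr$condition == "snow_covered", , drop = FALSE]
  rows <- lapply(properties, function(p) {
    x <- sf[[p]]; y <- sc[[p]]
    x[!is.finite(x)] <- NA; y[!is.finite(y)] <- NA
    p_val <- tryCatch(paired_property_test(x, y)$p, error = function(e) NA_real_)
    data.frame(property = p,
               median_snow_free = median(x, na.rm = TRUE),
               median_snow_covered = median(y, na.rm = TRUE),
               p_paired = p_val, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            n_pairs = nrow(object$grid),
            class = c("summary.network_ensemble", "data.frame"))
}

#' @export
print.summary.network_ensemble <- function(x, ...) {
  cat("Paired comparison of network properties across",
      attr(x, "n_pairs"), "filter pairs\n")
  cat("(Wilcoxon signed-rank, snow-free vs snow covered)\n\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot a network ensemble property across the grid
#'
#' Paired dot plot in the style of the grid comparison figures: one point
#' per network, snow-free and snow-covered values of the same filter pair
#' joined by a dashed segment.
#'
#' @param x a `network_ensemble`.
#' @param property property column to plot (default `"density"`).
#' @param ... passed to `plot()`.
#' @export
plot.network_ensemble <- function(x, property = "density", ...) {
  pr <- x$properties
  sf <- pr[pr$condition == "snow_free", property]
  sc <- pr[pr$condition == "snow_covered", property]
  ok <- is.finite(sf) & is.finite(sc)
  plot(c(0.75, 2.25), range(c(sf[ok], sc[ok])), type = "n", xaxt = "n",
       xlab = "", ylab = property, ...)
  axis(1, at = c(1, 2), labels = c("snow-free", "snow covered"))
  segments(1, sf[ok], 2, sc[ok], lty = 2, col = "grey60")
  points(rep(1, sum(ok)), sf[ok], pch = 19)
  points(rep(2, sum(ok)), sc[ok], pch = 19)
  invisible(x)
}

#' Serialize a network to an edge-list TSV (with JSON sidecar)
#'
#' @param net an `association_network`.
#' @param path TSV output path; a `.json` sidecar with condition,
#'   thresholds, selected penalty and the instability path is written next
#'   to it.
#' @return invisibly, the TSV path.
#' @export
write_network <- function(net, path) {
  kin <- setNames(net$nodes$kingdom, net$nodes$id)
  e <- net$edges
  out <- data.frame(id_a = e$a, id_b = e$b,
                    kingdom_a = unname(kin[e$a]), kingdom_b = unname(kin[e$b]),
                    weight = e$weight, sign = e$sign,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(condition = net$condition, t_fungal = net$t_fungal,
                  t_bacterial = net$t_bacterial, lambda = net$lambda,
                  n_input = as.list(net$n_input),
                  instability_path = net$instability_path)
  jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
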