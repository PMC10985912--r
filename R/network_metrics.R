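#' Per-network properties
#'
#' Density is `n_edges / choose(n_nodes, 2)`; fb density is the number of
#' fungal-bacterial edges over the number of possible fungal-bacterial pairs
#' among connected nodes; the longest path is reported as the unweighted
#' diameter (maximum eccentricity) of the largest connected component; the
#' odds of positive associations is `n_pos / n_neg` (infinite, with a
#' warning, when a network has no negative edge).
#'
#' @param net an `association_network`.
#' @param n_fungi_dataset,n_bacteria_dataset post-filter input sizes;
#'   default taken from the network's `n_input`.
#' @return one-row `data.frame` of properties.
#' @export
network_properties <- function(net,
                               n_fungi_dataset = net$n_input[["fungi"]],
                               n_bacteria_dataset = net$n_input[["bacteria"]]) {
  nF <- sum(net$nodes$kingdom == "fungi")
  nB <- sum(net$nodes$kingdom == "bacteria")
  nn <- nF + nB
  ne <- nrow(net$edges)
  tab <- table(factor(net$edges$type, levels = c("ff", "fb", "bb")))
  n_pos <- sum(net$edges$sign == "+")
  n_neg <- ne - n_pos
  if (ne > 0L && n_neg == 0L) {
    warning("network has no negative edges; odds_positive is Inf")
  }
  diam <- 0L
  if (ne > 0L) {
    g <- as_igraph(net)
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    diam <- igraph::diameter(sub, weights = NA)
  }
  data.frame(
    condition = net$condition, t_fungal = net$t_fungal,
    t_bacterial = net$t_bacterial,
    n_fungi_dataset = n_fungi_dataset,
    n_bacteria_dataset = n_bacteria_dataset,
    n_fungi_net = nF, n_bacteria_net = nB, n_nodes = nn, n_edges = ne,
    n_ff = as.integer(tab[["ff"]]), n_fb = as.integer(tab[["fb"]]),
    n_bb = as.integer(tab[["bb"]]),
    density = if (nn >= 2L) ne / choose(nn, 2L) else NA_real_,
    fb_density = if (nF >= 1L && nB >= 1L) {
      as.integer(tab[["fb"]]) / (nF * nB)
    } else NA_real_,
    longest_path = as.integer(diam),
    n_pos = n_pos, n_neg = n_neg,
    odds_positive = if (n_neg > 0L) n_pos / n_neg else Inf,
    stringsAsFactors = FALSE)
}

#' Partition edges by kingdom combination
#'
#' @param net an `association_network`.
#' @return named list of `data.frame`s `ff`, `fb`, `bb` (exhaustive and
#'   disjoint).
#' @export
edge_type_partition <- function(net) {
  known <- net$nodes$kingdom %in% KINGDOMS
  if (!all(known)) {
    stop("untagged node(s): ", paste(net$nodes$id[!known], collapse = ", "))
  }
  lapply(setNames(nm = c("ff", "fb", "bb")), function(t) {
    net$edges[net$edges$type == t, , drop = FALSE]
  })
}

#' Shared associations between two networks
#'
#' Edge identity is the unordered ASV-id pair (sign and weight ignored); an
#' optional strict mode additionally requires sign agreement. With
#' `fb_only`, both networks are first restricted to fungal-bacterial edges.
#'
#' @param net_a,net_b `association_network`s.
#' @param fb_only restrict to fb edges first.
#' @param require_sign_agreement also require identical signs.
#' @return list with `shared` (character vector of edge keys),
#'   `n_shared`, and `fraction_a`, `fraction_b` (shared fraction of each
#'   network's considered edges; `NaN` when a side has none).
#' @export
shared_edges <- function(net_a, net_b, fb_only = FALSE,
                         require_sign_agreement = FALSE) {
  ea <- net_a$edges; eb <- net_b$edges
  if (fb_only) {
    ea <- ea[ea$type == "fb", , drop = FALSE]
    eb <- eb[eb$type == "fb", , drop = FALSE]
  }
  ka <- edge_key(ea$a, ea$b); kb <- edge_key(eb$a, eb$b)
  if (require_sign_agreement) {
    ka <- paste(ka, ea$sign); kb <- paste(kb, eb$sign)
  }
  shared <- intersect(ka, kb)
  list(shared = shared, n_shared = length(shared),
       fraction_a = length(shared) / length(ka),
       fraction_b = length(shared) / length(kb))
}

#' Paired comparison of a network property across the filter grid
#'
#' The snow-free and snow-covered values of a property, paired within
#' filter combinations, are compared by a Wilcoxon signed-rank test (the
#' paired analogue of the rank test; zero differences are dropped by the
#' standard zero-handling). A pooled, unpaired Kruskal-Wallis variant is
#' available behind `method = "kruskal"`.
#'
#' @param snow_free,snow_covered equal-length numeric vectors, one entry
#'   per filter pair.
#' @param method `"wilcoxon"` (paired, default) or `"kruskal"` (pooled).
#' @return list with `p`, `statistic`, `method`, `n_pairs`.
#' @export
paired_property_test <- function(snow_free, snow_covered,
                                 method = c("wilcoxon", "kruskal")) {
  method <- match.arg(method)
  stopifnot(length(snow_free) == length(snow_covered))
  if (method == "kruskal") {
    kw <- kruskal.test(list(snow_free, snow_covered))
    return(list(p = kw$p.value, statistic = unname(kw$statistic),
                method = method, n_pairs = length(snow_free)))
  }
  d <- snow_free - snow_covered
  if (sum(d != 0, na.rm = TRUE) < 3L) {
    stop("fewer than 3 nonzero paired differences")
  }
  wt <- suppressWarnings(wilcox.test(snow_free, snow_covered, paired = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       method = method, n_pairs = length(snow_free))
}
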