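# pair-index encoding: unordered pairs (i < j) of n nodes are numbered
# 1..choose(n, 2) in row-major order; decode_pairs inverts the numbering
encode_pairs <- function(i, j, n) {
  (i - 1) * n - i * (i + 1) / 2 + j
}

decode_pairs <- function(k, n) {
  # i is the largest integer with (i-1)*n - i*(i+1)/2 < k
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  j <- k - ((i - 1) * n - i * (i + 1) / 2)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Uniform random network on a tagged node set
#'
#' Samples `n_edges` distinct unordered node pairs uniformly (no self
#' loops), the null used for edge-type and shared-association reference
#' distributions.
#'
#' @param nodes `data.frame` with columns `id`, `kingdom`.
#' @param n_edges number of edges, at most `choose(nrow(nodes), 2)`.
#' @param seed optional seed.
#' @return `data.frame` of edges `a`, `b`, `type`.
#' @export
random_network <- function(nodes, n_edges, seed = NULL) {
  n <- nrow(nodes)
  npairs <- choose(n, 2)
  if (n_edges > npairs) {
    stop("n_edges (", n_edges, ") exceeds possible pairs (", npairs, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- sample(npairs, n_edges)
  ij <- decode_pairs(k, n)
  ka <- nodes$kingdom[ij[, 1L]]; kb <- nodes$kingdom[ij[, 2L]]
  data.frame(a = nodes$id[ij[, 1L]], b = nodes$id[ij[, 2L]],
             type = ifelse(ka == kb, ifelse(ka == "fungi", "ff", "bb"), "fb"),
             stringsAsFactors = FALSE)
}

empirical_p <- function(replicates, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  k <- if (tail == "ge") sum(replicates >= observed) else
    sum(replicates <= observed)
  (1 + k) / (1 + length(replicates))
}

#' Edge-type frequencies of random networks
#'
#' For `R` uniform random networks matched in edge count to the inferred
#' network and drawn on the full filtered-dataset node set (not only
#' connected nodes), the fungal-fungal, fungal-bacterial and
#' bacterial-bacterial edge fractions are recorded as the reference
#' distribution. Empirical p-values use the add-one rule for both
#' enrichment (`p_ge`) and depletion (`p_le`), so they are never 0.
#'
#' @param net an `association_network`.
#' @param nodes `data.frame` (`id`, `kingdom`) of the filtered dataset the
#'   network was inferred from; defaults to the node universe recorded in
#'   the network if `NULL` (connected nodes only, a weaker null).
#' @param R number of replicates (default 999).
#' @param seed seed for the replicate stream.
#' @return `data.frame` with one row per statistic (`ff_frac`, `fb_frac`,
#'   `bb_frac`): observed value, null mean and sd, `p_ge`, `p_le`.
#' @export
edge_type_null <- function(net, nodes = NULL, R = 999L, seed = NULL) {
  stopifnot(R >= 1L)
  if (is.null(nodes)) nodes <- net$nodes
  m <- nrow(net$edges)
  if (m == 0L) stop("network has no edges")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(nodes)
  # type of every possible pair, computed once, then indexed per replicate
  is_f <- nodes$kingdom == "fungi"
  ij <- decode_pairs(seq_len(choose(n, 2)), n)
  fa <- is_f[ij[, 1L]]; fb <- is_f[ij[, 2L]]
  pair_type <- ifelse(fa & fb, "ff", ifelse(!fa & !fb, "bb", "fb"))
  reps <- matrix(0, R, 3L, dimnames = list(NULL, c("ff", "fb", "bb")))
  for (r in seq_len(R)) {
    t <- pair_type[sample.int(length(pair_type), m)]
    reps[r, ] <- c(sum(t == "ff"), sum(t == "fb"), sum(t == "bb")) / m
  }
  obs <- c(ff = sum(net$edges$type == "ff"),
           fb = sum(net$edges$type == "fb"),
           bb = sum(net$edges$type == "bb")) / m
  data.frame(
    statistic = c("ff_frac", "fb_frac", "bb_frac"),
    observed = as.numeric(obs),
    null_mean = colMeans(reps), null_sd = apply(reps, 2L, sd),
    p_ge = vapply(1:3, function(s) empirical_p(reps[, s], obs[s], "ge"),
                  numeric(1L)),
    p_le = vapply(1:3, function(s) empirical_p(reps[, s], obs[s], "le"),
                  numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Null distribution of associations shared between paired networks
#'
#' Per replicate, one random network is drawn for each condition and the
#' number of shared edges is counted. In the unrestricted variant edges are
#' drawn from all pairs of the respective node set; in the fb-restricted
#' variant only fungal-bacterial pairs among each network's connected
#' fungal and bacterial nodes are drawn, which yields stochastically larger
#' shared counts (fewer candidate pairs).
#'
#' @param nodes_a,nodes_b node `data.frame`s (`id`, `kingdom`) for the two
#'   sides.
#' @param n_edges_a,n_edges_b edge counts to match.
#' @param R replicates (default 999).
#' @param seed seed.
#' @param fb_restricted draw only fungal-bacterial pairs.
#' @param observed optional observed shared count; when given, empirical
#'   p-values are reported.
#' @return list with `replicates` (integer vector of length `R`),
#'   `null_mean`, `null_sd`, and (when `observed` is given) `observed`,
#'   `p_ge`, `p_le`.
#' @export
shared_null <- function(nodes_a, n_edges_a, nodes_b, n_edges_b,
                        R = 999L, seed = NULL, fb_restricted = FALSE,
                        observed = NULL) {
  stopifnot(R >= 1L)
  if (!is.null(seed)) set.seed(seed)
  univ <- function(nodes) {
    if (fb_restricted) {
      f <- nodes$id[nodes$kingdom == "fungi"]
      b <- nodes$id[nodes$kingdom == "bacteria"]
      if (length(f) == 0L || length(b) == 0L) return(character(0))
      as.vector(outer(f, b, edge_key))
    } else {
      n <- nrow(nodes)
      ij <- decode_pairs(seq_len(choose(n, 2)), n)
      edge_key(nodes$id[ij[, 1L]], nodes$id[ij[, 2L]])
    }
  }
  ua <- univ(nodes_a); ub <- univ(nodes_b)
  if (n_edges_a > length(ua) || n_edges_b > length(ub)) {
    stop("edge count exceeds candidate pairs")
  }
  # shared edges can only come from the common candidate pairs; index them
  common <- intersect(ua, ub)
  ia <- match(ua, common); ib <- match(ub, common)
  reps <- integer(R)
  for (r in seq_len(R)) {
    da <- ia[sample.int(length(ua), n_edges_a)]
    db <- ib[sample.int(length(ub), n_edges_b)]
    reps[r] <- length(intersect(da[!is.na(da)], db[!is.na(db)]))
  }
  out <- list(replicates = reps, null_mean = mean(reps), null_sd = sd(reps),
              fb_restricted = fb_restricted)
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_ge <- empirical_p(reps, observed, "ge")
    out$p_le <- empirical_p(reps, observed, "le")
  }
  out
}
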