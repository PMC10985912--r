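#' Joint centred log-ratio transform of paired count tables
#'
#' Each kingdom's counts (plus a pseudocount) are first normalised to
#' within-kingdom relative abundances, then the two kingdoms are
#' concatenated per sample and centred jointly:
#' `x_i = log(q_i) - mean_j log(q_j)` over the combined feature vector.
#' The per-kingdom normalisation makes the transform unbiased with respect
#' to the two libraries' sequencing depths: without it, per-sample
#' variation of the fungal/bacterial depth ratio injects a shared
#' component into every cross-kingdom pair. A per-kingdom-centred variant
#' is available for comparison.
#'
#' @param fungal,bacterial count matrices (samples x ASVs) or
#'   [asv_table()]s with identical samples in identical order.
#' @param pseudocount added before normalisation (default 1).
#' @param normalize if `FALSE`, skip the within-kingdom normalisation and
#'   transform raw pseudocounted counts
#'   (`x_i = log(c_i + 1) - mean_j log(c_j + 1)`), which leaves the
#'   depth-ratio component in.
#' @param per_kingdom if `TRUE`, centre each kingdom separately instead of
#'   jointly.
#' @return numeric matrix (samples x features) with attribute `kingdom`
#'   tagging every column `"fungi"` or `"bacteria"`; rows sum to 0 (per
#'   kingdom in the per-kingdom variant).
#' @export
joint_clr <- function(fungal, bacterial, pseudocount = 1,
                      normalize = TRUE, per_kingdom = FALSE) {
  if (inherits(fungal, "asv_table")) fungal <- fungal$counts
  if (inherits(bacterial, "asv_table")) bacterial <- bacterial$counts
  if (!identical(rownames(fungal), rownames(bacterial))) {
    stop("fungal and bacterial tables must have the same samples in the same order")
  }
  norm <- function(m) {
    m <- m + pseudocount
    if (normalize) m / rowSums(m) else m
  }
  lx <- log(cbind(norm(fungal), norm(bacterial)))
  kingdom <- rep(KINGDOMS, c(ncol(fungal), ncol(bacterial)))
  if (per_kingdom) {
    for (k in KINGDOMS) {
      cols <- kingdom == k
      lx[, cols] <- lx[, cols] - rowMeans(lx[, cols, drop = FALSE])
    }
  } else {
    lx <- lx - rowMeans(lx)
  }
  attr(lx, "kingdom") <- kingdom
  lx
}

# centre and scale columns to mean 0 / mean square 1 (population sd);
# zero-variance columns are set to 0 so they attract no coefficients
standardize_cols <- function(x) {
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu)
  s <- sqrt(colMeans(x^2))
  s[s == 0] <- Inf
  sweep(x, 2L, s, "/")
}

# descending log-spaced lambda path from lambda_max (largest absolute
# off-diagonal sample correlation) down to ratio * lambda_max
lambda_path_for <- function(xs, n_lambda = 20L, ratio = 0.01) {
  C <- crossprod(xs) / nrow(xs)
  diag(C) <- 0
  lmax <- max(abs(C))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
}

#' Meinshausen-Buhlmann neighborhood fit at one penalty
#'
#' Column `j` of the returned matrix holds the coefficients of the
#' L1-penalised linear regression of feature `j` on all other features
#' (columns standardised, no intercept after centring); the diagonal is
#' zero. The lasso solutions are computed by coordinate descent in C++
#' with warm starts down a path ending at `lambda`.
#'
#' @param clr a matrix from [joint_clr()] (or any samples x features
#'   matrix).
#' @param lambda penalty, `>= 0`.
#' @return p x p coefficient matrix `B` with `B[k, j]` the coefficient of
#'   predictor `k` in the regression of target `j`.
#' @export
mb_fit <- function(clr, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (nrow(clr) < 3L) stop("need >= 3 samples")
  xs <- standardize_cols(clr)
  path <- lambda_path_for(xs)
  path <- c(path[path > lambda], lambda)
  B <- mb_lasso_path_cpp(xs, path)
  out <- B[, , length(path)]
  dimnames(out) <- list(colnames(clr), colnames(clr))
  out
}

#' StARS control settings
#'
#' @param n_lambda,lambda_min_ratio the penalty path: `n_lambda` log-spaced
#'   values from the largest absolute feature-feature correlation
#'   `lambda_max` down to `lambda_min_ratio * lambda_max`.
#' @param n_subsamples number of random subsamples.
#' @param subsample_ratio fraction of samples per subsample (used when
#'   `subsample_size` is `NULL`): `b = min(floor(10*sqrt(n)),
#'   floor(subsample_ratio * n))`.
#' @param subsample_size explicit rows per subsample, overriding the ratio.
#' @param beta_threshold StARS instability bound (default 0.05).
#' @return list of class `stars_control`.
#' @export
stars_control <- function(n_lambda = 20L, lambda_min_ratio = 0.01,
                          n_subsamples = 20L, subsample_ratio = 0.8,
                          subsample_size = NULL,
                          beta_threshold = 0.05) {
  stopifnot(n_lambda >= 2L, n_subsamples >= 2L, beta_threshold > 0,
            subsample_ratio > 0, subsample_ratio < 1)
  structure(list(n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_ratio = subsample_ratio,
                 subsample_size = subsample_size,
                 beta_threshold = beta_threshold),
            class = "stars_control")
}

#' Stability selection of the lasso penalty (StARS)
#'
#' For every penalty on a descending path, neighborhood graphs are fit on
#' random subsamples (without replacement); an edge is counted when either
#' direction's coefficient is nonzero. With selection frequency
#' `theta_hat`, per-pair instability is `2 * theta_hat * (1 - theta_hat)`
#' and the path instability is its mean over all feature pairs. The
#' instability curve is monotonised by a running supremum from the sparse
#' (large-lambda) end, and the smallest penalty whose monotonised
#' instability stays below `beta_threshold` is selected; when even the
#' sparsest graph exceeds the bound, `lambda_max` is returned with a
#' warning.
#'
#' @param clr matrix from [joint_clr()].
#' @param control a [stars_control()].
#' @param seed seed for the subsampling stream.
#' @return list with `lambda` (selected penalty), `instability_path`
#'   (`data.frame` of lambda, instability, monotone instability), and
#'   `merge` (feature x feature edge selection frequencies at the selected
#'   penalty).
#' @export
stars_select <- function(clr, control = stars_control(), seed = NULL) {
  n <- nrow(clr); p <- ncol(clr)
  if (n < 4L) stop("need >= 4 samples for subsampling")
  b <- control$subsample_size %||%
    min(floor(10 * sqrt(n)), floor((control$subsample_ratio %||% 0.8) * n))
  b <- max(3L, min(n - 1L, as.integer(b)))
  if (!is.null(seed)) set.seed(seed)
  lambdas <- {
    xs_full <- standardize_cols(clr)
    lambda_path_for(xs_full, control$n_lambda, control$lambda_min_ratio)
  }
  L <- length(lambdas)
  S <- control$n_subsamples
  subsamples <- lapply(seq_len(S), function(s) sample.int(n, b))
  npairs <- p * (p - 1) / 2

  # Everything denser than the first crossing of the instability bound can
  # never be selected, so the path is evaluated on doubling prefixes with
  # an early stop at the crossing; the sparse end is cheap to fit.
  instability_for <- function(k) {
    counts <- array(0L, c(p, p, k))
    for (s in seq_len(S)) {
      xs <- standardize_cols(clr[subsamples[[s]], , drop = FALSE])
      B <- mb_lasso_path_cpp(xs, lambdas[seq_len(k)])
      nz <- B != 0
      counts <- counts + (nz | aperm(nz, c(2L, 1L, 3L)))
    }
    theta <- counts / S
    instab <- vapply(seq_len(k), function(l) {
      th <- theta[, , l]
      sum(2 * th * (1 - th)) / 2 / npairs   # each pair counted once
    }, numeric(1L))
    list(instab = instab, theta = theta)
  }

  k <- min(6L, L)
  repeat {
    fit <- instability_for(k)
    mono <- cummax(fit$instab)
    crossed <- mono > control$beta_threshold
    if (any(crossed) || k == L) break
    k <- min(2L * k, L)
  }
  ok <- mono <= control$beta_threshold
  if (!any(ok)) {
    warning("instability above threshold on the whole path; selecting lambda_max")
    sel <- 1L
  } else {
    sel <- max(which(ok))   # smallest lambda still within the bound
  }
  merge <- fit$theta[, , sel]
  dimnames(merge) <- list(colnames(clr), colnames(clr))
  list(lambda = lambdas[sel],
       instability_path = data.frame(lambda = lambdas[seq_len(k)],
                                     instability = fit$instab,
                                     monotone = mono),
       merge = merge)
}

#' Refit at the selected penalty and derive signed edge weights
#'
#' The neighborhood fit at the selected penalty is symmetrised with the OR
#' rule (an edge exists when either direction's coefficient is nonzero) and
#' the symmetrised beta coefficient is multiplied onto the refitted network
#' structure: for each retained edge, the weight is the larger-magnitude
#' member of the two directed coefficients (`rule = "max"`), or their mean
#' (`rule = "mean"`). Orphan nodes (no incident edge) are removed.
#'
#' @param clr matrix from [joint_clr()].
#' @param lambda selected penalty (from [stars_select()]).
#' @param rule symmetrisation rule, `"max"` (default) or `"mean"`.
#' @param condition,t_fungal,t_bacterial,n_input optional provenance fields
#'   stored on the network.
#' @param instability_path optional StARS path to store.
#' @return an object of class `association_network`: list with `nodes`
#'   (`data.frame` of `id`, `kingdom`), `edges` (`data.frame` of `a`, `b`,
#'   `weight`, `sign`, `type` in `{"ff","fb","bb"}`), `lambda`, provenance
#'   fields, and `n_input` (post-filter feature counts per kingdom).
#' @export
refit_and_weight <- function(clr, lambda, rule = c("max", "mean"),
                             condition = NA_character_,
                             t_fungal = NA_integer_, t_bacterial = NA_integer_,
                             n_input = NULL, instability_path = NULL) {
  rule <- match.arg(rule)
  kingdom <- attr(clr, "kingdom")
  if (is.null(kingdom)) stop("clr matrix lacks kingdom tags")
  B <- mb_fit(clr, lambda)
  A <- (B != 0) | t(B != 0)
  diag(A) <- FALSE
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  ids <- colnames(clr)
  if (nrow(idx)) {
    b_ij <- B[idx]
    b_ji <- B[idx[, c(2L, 1L), drop = FALSE]]
    w <- if (rule == "max") {
      ifelse(abs(b_ij) >= abs(b_ji), b_ij, b_ji)
    } else {
      (b_ij + b_ji) / 2
    }
    keep <- w != 0
    idx <- idx[keep, , drop = FALSE]
    w <- w[keep]
  } else {
    w <- numeric(0)
  }
  ka <- kingdom[idx[, 1L]]; kb <- kingdom[idx[, 2L]]
  type <- ifelse(ka == "fungi" & kb == "fungi", "ff",
          ifelse(ka == "bacteria" & kb == "bacteria", "bb", "fb"))
  edges <- data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]],
                      weight = w, sign = ifelse(w > 0, "+", "-"),
                      type = type, stringsAsFactors = FALSE)
  connected <- unique(c(edges$a, edges$b))
  nodes <- data.frame(id = ids, kingdom = kingdom,
                      stringsAsFactors = FALSE)
  nodes <- nodes[nodes$id %in% connected, , drop = FALSE]
  rownames(nodes) <- NULL
  if (is.null(n_input)) {
    n_input <- c(fungi = sum(kingdom == "fungi"),
                 bacteria = sum(kingdom == "bacteria"))
  }
  structure(list(condition = condition, t_fungal = t_fungal,
                 t_bacterial = t_bacterial, nodes = nodes, edges = edges,
                 lambda = lambda, instability_path = instability_path,
                 n_input = n_input),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("<association_network>",
      if (!is.na(x$condition)) paste0(" ", x$condition), " t_F=", x$t_fungal,
      " t_B=", x$t_bacterial, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (",
      sum(x$edges$type == "fb"), " fb), lambda=",
      signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

#' Plot an association network
#'
#' Thin wrapper around igraph plotting: fungal nodes as squares, bacterial
#' nodes as circles, solid edges positive, dashed negative.
#'
#' @param x an `association_network`.
#' @param ... passed to `plot.igraph`.
#' @export
plot.association_network <- function(x, ...) {
  g <- as_igraph(x)
  if (igraph::vcount(g) == 0L) {
    warning("empty network; nothing to plot")
    return(invisible(NULL))
  }
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(igraph::V(g)$kingdom == "fungi", "square", "circle"),
    vertex.size = 5, vertex.label = NA,
    edge.lty = ifelse(igraph::E(g)$sign == "+", 1L, 2L), ...)
  invisible(x)
}

# association_network -> igraph
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("a", "b", "weight", "sign")],
    directed = FALSE, vertices = net$nodes)
}

#' Infer the paired condition networks for one filtered table pair
#'
#' Splits samples by condition and, per condition, drops ASVs with zero
#' occurrence in that subset, applies the joint CLR, selects the penalty by
#' StARS and refits the weighted network.
#'
#' @param filtered a `filtered_pair` from [build_grid()].
#' @param meta sample metadata.
#' @param control a [stars_control()].
#' @param seed master seed; per-condition streams are derived from it.
#' @param rule symmetrisation rule passed to [refit_and_weight()].
#' @return named list with one `association_network` per condition.
#' @export
infer_condition_networks <- function(filtered, meta,
                                     control = stars_control(),
                                     seed = 1L, rule = "max") {
  stopifnot(inherits(filtered, "filtered_pair"))
  m <- aligned_meta(filtered$fungi, meta)
  out <- list()
  for (cond in CONDITIONS) {
    rows <- which(m$condition == cond)
    if (length(rows) == 0L) stop("condition absent from metadata: ", cond)
    if (length(rows) < 4L) stop("need >= 4 samples per condition (", cond, ")")
    fc <- filtered$fungi$counts[rows, , drop = FALSE]
    bc <- filtered$bacteria$counts[rows, , drop = FALSE]
    fdrop <- colSums(fc > 0L) == 0L
    bdrop <- colSums(bc > 0L) == 0L
    if (any(fdrop) || any(bdrop)) {
      message(sum(fdrop), " fungal / ", sum(bdrop), " bacterial ASVs have",
              " zero occurrence in ", cond, " samples and are dropped")
      fc <- fc[, !fdrop, drop = FALSE]
      bc <- bc[, !bdrop, drop = FALSE]
    }
    clr <- joint_clr(fc, bc)
    tag <- paste("stars", cond, filtered$t_fungal, filtered$t_bacterial,
                 sep = "/")
    sel <- stars_select(clr, control, seed = derive_seed(seed, tag))
    out[[cond]] <- refit_and_weight(
      clr, sel$lambda, rule = rule, condition = cond,
      t_fungal = filtered$t_fungal, t_bacterial = filtered$t_bacterial,
      n_input = c(fungi = ncol(fc), bacteria = ncol(bc)),
      instability_path = sel$instability_path)
  }
  out
}
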