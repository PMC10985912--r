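# small in-code fixtures shared across test files

toy_counts <- function(m, prefix = "A", samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- sprintf("%s%03d", prefix, seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(n, locations = c("L1", "L2", "L3"),
                     conditions = c("snow_free", "snow_covered")) {
  data.frame(sample_id = paste0("S", seq_len(n)),
             location = rep_len(locations, n),
             condition = rep_len(conditions, n),
             stringsAsFactors = FALSE)
}

# a small simulation config that keeps network tests fast
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    groups = data.frame(
      location = rep(c("L1", "L2", "L3"), each = 2L),
      condition = rep(c("snow_free", "snow_covered"), 3L),
      n = c(7L, 7L, 7L, 7L, 6L, 6L)),
    n_fungi = 40L, n_bacteria = 80L,
    depth_mean = c(fungi = 2000, bacteria = 6000),
    depth_sd = c(fungi = 400, bacteria = 1200),
    n_core = c(fungi = 4L, bacteria = 8L),
    planted_edges = data.frame(
      fungus = 1:4, bacterium = 1:4, rho = c(0.8, -0.8, 0.8, -0.8),
      condition = c("both", "both", "snow_free", "snow_covered")),
    seed = seed, ...)
}

# hand-built association network (no inference involved)
toy_network <- function(edges, nodes = NULL, condition = "snow_free",
                        t_fungal = 5L, t_bacterial = 10L) {
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$a, edges$b)))
    nodes <- data.frame(
      id = ids,
      kingdom = ifelse(startsWith(ids, "F"), "fungi", "bacteria"),
      stringsAsFactors = FALSE)
  }
  kin <- stats::setNames(nodes$kingdom, nodes$id)
  ka <- kin[edges$a]; kb <- kin[edges$b]
  edges$type <- ifelse(ka == "fungi" & kb == "fungi", "ff",
                ifelse(ka == "bacteria" & kb == "bacteria", "bb", "fb"))
  if (is.null(edges$weight)) edges$weight <- 0.3
  if (is.null(edges$sign)) edges$sign <- ifelse(edges$weight > 0, "+", "-")
  structure(list(condition = condition, t_fungal = t_fungal,
                 t_bacterial = t_bacterial, nodes = nodes, edges = edges,
                 lambda = 0.1, instability_path = NULL,
                 n_input = c(fungi = sum(nodes$kingdom == "fungi"),
                             bacteria = sum(nodes$kingdom == "bacteria"))),
            class = "association_network")
}

edge_df <- function(a, b, weight = 0.3, sign = NULL) {
  d <- data.frame(a = a, b = b, weight = weight, stringsAsFactors = FALSE)
  d$sign <- sign %||% ifelse(d$weight > 0, "+", "-")
  d
}
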