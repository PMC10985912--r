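# networks: a list(snow_free = ..., snow_covered = ...) of toy networks
grid_networks <- function(sf_edges, sc_edges) {
  list(snow_free = lapply(sf_edges, toy_network, condition = "snow_free"),
       snow_covered = lapply(sc_edges, toy_network,
                             condition = "snow_covered"))
}

test_that("frequent_associations applies the more-than-five rule exactly", {
  e <- edge_df("F01", "B01")
  other <- edge_df("F02", "B02")
  # edge in 6 of 8 snow-free networks, 0 snow-covered
  sf <- c(replicate(6, e, simplify = FALSE),
          replicate(2, other, simplify = FALSE))
  sc <- replicate(8, other, simplify = FALSE)
  rec <- frequent_associations(grid_networks(sf, sc), min_networks = 6L)
  k <- edge_key(rec$a, rec$b)
  expect_true(edge_key("F01", "B01") %in% k)
  row <- rec[k == edge_key("F01", "B01"), ]
  expect_equal(row$n_snow_free, 6L)
  expect_true(row$frequent_snow_free)
  expect_false(row$frequent_snow_covered)

  # 5 of 25 is excluded under the default rule
  sf5 <- c(replicate(5, e, simplify = FALSE),
           replicate(20, other, simplify = FALSE))
  rec5 <- frequent_associations(grid_networks(sf5, sc), min_networks = 6L)
  expect_false(edge_key("F01", "B01") %in% edge_key(rec5$a, rec5$b))
})

test_that("min_networks = 1 reproduces the brute-force union of edges", {
  set.seed(71)
  mk <- function() {
    n <- sample(2:5, 1)
    edge_df(sprintf("F%02d", sample(5, n, TRUE)),
            sprintf("B%02d", sample(9, n, TRUE)))
  }
  sf <- replicate(4, mk(), simplify = FALSE)
  sc <- replicate(4, mk(), simplify = FALSE)
  nets <- grid_networks(sf, sc)
  rec <- frequent_associations(nets, min_networks = 1L)
  oracle <- unique(unlist(lapply(c(nets$snow_free, nets$snow_covered),
                                 function(n) edge_key(n$edges$a, n$edges$b))))
  expect_setequal(edge_key(rec$a, rec$b), oracle)

  # monotone decreasing in min_networks
  for (m in 2:4) {
    recm <- frequent_associations(nets, min_networks = m)
    expect_true(all(edge_key(recm$a, recm$b) %in% edge_key(rec$a, rec$b)))
  }
})

test_that("consensus sign is the majority with ties reported mixed", {
  pos <- edge_df("F01", "B01", weight = 0.5)
  neg <- edge_df("F01", "B01", weight = -0.5)
  nets <- grid_networks(list(pos, pos, neg), list(pos))
  rec <- frequent_associations(nets, min_networks = 3L)
  expect_equal(rec$consensus_sign, "+")
  expect_equal(rec$fraction_positive, 3 / 4)

  tie <- grid_networks(list(pos, neg), list(pos, neg))
  rec2 <- frequent_associations(tie, min_networks = 2L)
  expect_equal(rec2$consensus_sign, "mixed")
})

test_that("condition specificity partitions frequent records", {
  both <- edge_df("F01", "B01")
  sf_only <- edge_df("F02", "B02")
  sc_only <- edge_df("F03", "B03")
  sf <- replicate(8, rbind(both, sf_only), simplify = FALSE)
  sc <- replicate(7, rbind(both, sc_only), simplify = FALSE)
  rec <- condition_specificity(frequent_associations(grid_networks(sf, sc)))
  spec <- setNames(rec$specificity, edge_key(rec$a, rec$b))
  expect_equal(unname(spec[edge_key("F01", "B01")]), "both")
  expect_equal(unname(spec[edge_key("F02", "B02")]), "snow_free_only")
  expect_equal(unname(spec[edge_key("F03", "B03")]), "snow_covered_only")
})

test_that("genus_summary applies annotation and support rules", {
  tax <- data.frame(
    asv_id = c("F01", "F02", "F03", "F04", "B01", "B02", "B03", "B04"),
    phylum = "P",
    genus = c("GenusX", "GenusX", NA, "GenusZ",
              "GenusY", "GenusY", "GenusY", "GenusW"),
    stringsAsFactors = FALSE)
  # three GenusX-GenusY records with signs (+, +, -); one unannotated;
  # one single-support pair GenusZ-GenusW
  e1 <- edge_df("F01", "B01", weight = 0.4)
  e2 <- edge_df("F02", "B02", weight = 0.4)
  e3 <- edge_df("F01", "B03", weight = -0.4)
  e4 <- edge_df("F03", "B01", weight = 0.4)   # fungal genus missing
  e5 <- edge_df("F04", "B04", weight = 0.4)   # support 1
  sf <- replicate(6, rbind(e1, e2, e3, e4, e5), simplify = FALSE)
  rec <- frequent_associations(grid_networks(sf, list()), min_networks = 6L)
  gs <- genus_summary(rec, tax, "snow_free", min_pair_support = 2L)
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$fungal_genus, "GenusX")
  expect_equal(gs$bacterial_genus, "GenusY")
  expect_equal(gs$n_supporting, 3L)
  expect_equal(gs$consensus_sign, "+")
  expect_equal(gs$n_positive / (gs$n_positive + gs$n_negative), 2 / 3)

  # output count never exceeds the fb frequent-record count
  expect_lte(nrow(gs), sum(rec$type == "fb"))
})

test_that("recovery_score handles perfect, empty and missing detections", {
  truth <- structure(list(edges = data.frame(
    fungal_id = c("F01", "F02"), bacterial_id = c("B01", "B02"),
    sign = c("+", "-"), condition = c("both", "both"),
    stringsAsFactors = FALSE)), class = "fb_truth")
  hit <- rbind(edge_df("F01", "B01", weight = 0.4),
               edge_df("F02", "B02", weight = -0.4))
  nets <- grid_networks(replicate(6, hit, simplify = FALSE),
                        replicate(6, hit, simplify = FALSE))
  rec <- frequent_associations(nets)
  sc <- recovery_score(rec, truth)
  expect_equal(sc$recall, c(1, 1))
  expect_equal(sc$precision, c(1, 1))
  expect_equal(sc$sign_accuracy, c(1, 1))

  none <- frequent_associations(grid_networks(list(), list()))
  sc0 <- recovery_score(none, truth)
  expect_equal(sc0$recall, c(0, 0))
  expect_true(all(is.na(sc0$precision)))

  expect_error(recovery_score(rec, structure(list(edges = truth$edges[0, ]),
                                             class = "fb_truth")),
               "empty truth")
})
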