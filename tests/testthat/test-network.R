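test_that("network construction enforces the structural invariants", {
  expect_error(
    signed_network(3, data.frame(source = 1, target = 1, weight = 1)),
    class = "socnet_invalid_config"
  )
  expect_error(
    signed_network(3, data.frame(source = c(1, 1), target = c(2, 2), weight = c(1, -1))),
    class = "socnet_invalid_config"
  )
  expect_error(
    signed_network(3, data.frame(source = 1, target = 2, weight = 2)),
    class = "socnet_invalid_config"
  )
  net <- signed_network(3, data.frame(source = c(1, 3), target = c(2, 2), weight = c(1, -1)))
  expect_equal(n_links(net), 2L)
  expect_equal(avg_connectivity(net), 2 / 3)
  expect_equal(activating_ratio(net), 0.5)
  expect_true(is.na(activating_ratio(signed_network(4))))
})

test_that("random initialisation hits the requested connectivity and sign ratio", {
  expect_equal(n_links(make_random_network(10, 0, 0.5, seed = 1)), 0L)

  net <- make_random_network(100, 3, p_activating = 1, seed = 7)
  expect_equal(n_links(net), 300L)
  expect_equal(activating_ratio(net), 1)
  expect_true(all(diag(net$W) == 0L))
  # in-links come from distinct sources by construction: each row holds
  # deg_i distinct nonzero entries
  expect_equal(sum(rowSums(net$W != 0L)), 300L)

  # sign frequency: 2000 Bernoulli(0.5) draws stay within 0.5 +/- 0.05
  # (±0.05 is > 4 binomial SD = 4 * sqrt(0.25 / 2000) = 0.045)
  net2 <- make_random_network(1000, 2, p_activating = 0.5, seed = 3)
  expect_equal(n_links(net2), 2000L)
  expect_lt(abs(activating_ratio(net2) - 0.5), 0.05)

  expect_error(make_random_network(10, 10), class = "socnet_invalid_config")
})

test_that("link insertion and removal are exact inverses via their descriptors", {
  net <- make_random_network(12, 2, seed = 5)
  k0 <- avg_connectivity(net)

  res <- add_in_link(net, 4, p_activating = 0.5, seed = 9)
  expect_equal(avg_connectivity(res$network), k0 + 1 / 12)
  expect_equal(res$link$action, "insert")
  expect_identical(revert_link(res$network, res$link)$W, net$W)

  res2 <- remove_in_link(net, 4, seed = 9)
  expect_equal(avg_connectivity(res2$network), k0 - 1 / 12)
  expect_identical(revert_link(res2$network, res2$link)$W, net$W)
  # removal descriptor preserves the original weight
  expect_equal(
    res2$network$W[res2$link$target, res2$link$source] + res2$link$weight,
    net$W[res2$link$target, res2$link$source]
  )
})

test_that("seeded link choices are reproducible and degenerate cases error", {
  net <- signed_network(3)
  r1 <- add_in_link(net, 1, seed = 4)
  r2 <- add_in_link(net, 1, seed = 4)
  expect_identical(r1$link, r2$link)
  expect_equal(avg_connectivity(r1$network), 1 / 3)
  expect_true(r1$link$source %in% c(2L, 3L))

  # saturated target: in-links from all other nodes already present
  full <- signed_network(3, data.frame(source = c(2, 3), target = c(1, 1), weight = 1))
  expect_error(add_in_link(full, 1), class = "socnet_no_candidate")
  expect_error(remove_in_link(net, 1), class = "socnet_no_link")
})

test_that("sign rebalancing reaches the nearest achievable ratio and only flips signs", {
  mk <- function(n_pos, n_neg) {
    n <- n_pos + n_neg + 1L
    signed_network(n, data.frame(
      source = seq_len(n_pos + n_neg),
      target = n,
      weight = c(rep(1L, n_pos), rep(-1L, n_neg))
    ))
  }
  # 10 links, 5 positive, target 0.8 -> exactly 8 positive
  net <- rebalance_link_signs(mk(5, 5), 0.8, seed = 1)
  expect_equal(sum(net$W > 0), 8L)
  expect_equal(n_links(net), 10L)

  # 7 links, target 0.8 -> 6 positive (6/7 is closer to 0.8 than 5/7)
  net7 <- rebalance_link_signs(mk(3, 4), 0.8, seed = 1)
  expect_equal(sum(net7$W > 0), 6L)

  # already at target: untouched
  net8 <- mk(8, 2)
  expect_identical(rebalance_link_signs(net8, 0.8, seed = 1)$W, net8$W)

  # endpoints conserved
  before <- mk(2, 8)
  after <- rebalance_link_signs(before, 0.8, seed = 2)
  expect_identical(abs(after$W), abs(before$W))
})

test_that("snapshot TSV round-trips bit-exactly and GraphML preserves structure", {
  net <- make_random_network(20, 1.5, theta = c(rep(0L, 10), rep(1L, 10)), seed = 2)
  net$meta$epoch <- 123
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_network_tsv(net, f1)
  back <- read_network_tsv(f1)
  expect_identical(back$W, net$W)
  expect_identical(back$theta, net$theta)
  expect_equal(back$meta$epoch, 123)
  write_network_tsv(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  g <- tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  back2 <- read_network_graphml(g)
  expect_identical(back2$W, net$W)
  expect_identical(back2$theta, net$theta)
})

test_that("the edge view is a canonical tibble", {
  net <- signed_network(4, data.frame(
    source = c(3, 1, 2), target = c(2, 2, 4), weight = c(-1, 1, 1)
  ))
  ed <- network_edges(net)
  expect_s3_class(ed, "tbl_df")
  expect_equal(ed$target, c(2L, 2L, 4L))
  expect_equal(ed$source, c(1L, 3L, 2L))
  expect_equal(ed$weight, c(1L, -1L, 1L))
})
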