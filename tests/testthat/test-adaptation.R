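test_that("lagged correlations handle perfect, frozen, and anticorrelated series", {
  # source alternates; target is its one-step-delayed copy
  tw <- 20
  traj <- matrix(0L, 2, tw)
  traj[1, ] <- rep_len(c(1L, 0L), tw)
  traj[2, ] <- c(0L, traj[1, 1:(tw - 1)])
  expect_equal(lagged_pearson(traj, target = 2, source = 1), 1)

  # frozen target: Pearson undefined, convention 0
  traj2 <- traj
  traj2[2, ] <- 1L
  expect_equal(lagged_pearson(traj2, 2, 1), 0)

  # perfect anticorrelation: n_i(t + 1) = 1 - n_j(t)
  traj3 <- traj
  traj3[2, ] <- c(0L, 1L - traj[1, 1:(tw - 1)])
  expect_equal(lagged_pearson(traj3, 2, 1), -1)

  # general case agrees with stats::cor on the shifted series
  set.seed(5)
  traj4 <- matrix(sample(0:1, 60, replace = TRUE), 2, 30)
  expect_equal(
    lagged_pearson(traj4, 1, 2),
    cor(traj4[1, 2:30], traj4[2, 1:29])
  )
})

test_that("average input correlation follows the link structure", {
  net <- signed_network(3, data.frame(
    source = c(1, 2), target = 3, weight = c(1, -1)
  ))
  tw <- 16
  traj <- matrix(0L, 3, tw)
  traj[1, ] <- rep_len(c(1L, 0L), tw)
  traj[2, ] <- rep_len(c(1L, 0L), tw)
  traj[3, ] <- c(0L, traj[1, 1:(tw - 1)]) # follows source 1 exactly

  # node with no in-links: 0 by convention
  expect_equal(avg_input_correlation(net, traj, 1), 0)
  # single-input mean is that input's correlation
  one <- signed_network(3, data.frame(source = 1, target = 3, weight = 1))
  expect_equal(avg_input_correlation(one, traj, 3), 1)
  # +1 and -1 correlated inputs cancel in the mean
  expect_equal(avg_input_correlation(net, traj, 3), mean(c(1, 1)))
  traj[2, ] <- 1L - traj[1, ] # in antiphase with source 1: C = -1
  two <- signed_network(3, data.frame(
    source = c(1, 2), target = 3, weight = c(1, 1)
  ))
  expect_equal(avg_input_correlation(two, traj, 3), 0)
})

test_that("the branching parameter matches hand-computed damage counts", {
  toys <- toy_networks()
  expect_equal(branching_parameter(toys$isolated, rep(0, 5)), 0)
  # 2-node net 1 -> 2 (+1), both off: flipping 1 changes 2, flipping 2 nothing
  net2 <- signed_network(2, data.frame(source = 1, target = 2, weight = 1))
  expect_equal(branching_parameter(net2, c(0, 0)), 0.5)
  # complete +1 digraph on 3 nodes, all off: each flip activates the other two
  expect_equal(branching_parameter(toys$complete3, c(0, 0, 0)), 2)
})

test_that("the branching parameter equals the brute-force damage oracle", {
  set.seed(44)
  for (rep in 1:60) {
    n <- sample(3:20, 1)
    net <- make_random_network(n, runif(1, 0, 2.5),
      p_activating = runif(1),
      theta = sample(0:1, 1)
    )
    s <- sample(0:1, n, replace = TRUE)
    expect_equal(branching_parameter(net, s), brute_force_branching(net, s))
  }
})

test_that("adaptation configs are validated and unknown YAML keys rejected", {
  expect_error(adaptation_config(t_corr = 1), class = "socnet_invalid_config")
  expect_error(adaptation_config(beta = -1), class = "socnet_invalid_config")
  expect_error(adaptation_config(eps = 1.2), class = "socnet_invalid_config")
  expect_error(adaptation_config(fixed_ratio = 0), class = "socnet_invalid_config")

  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_epochs: 10", "t_corr: 20", "typo_key: 3"), f)
  expect_error(read_adaptation_config(f), class = "socnet_invalid_config")
  writeLines(c("n_epochs: 10", "t_corr: 20", "seed: 1"), f)
  cfg <- read_adaptation_config(f)
  expect_s3_class(cfg, "adaptation_config")
  expect_equal(cfg$n_epochs, 10L)

  # noisy-dynamics guideline: warn when idle activation is not rare
  expect_warning(
    evolve(
      make_random_network(8, 0),
      adaptation_config(n_epochs = 1, t_corr = 2, t_trans = 1, beta = 1, seed = 1)
    ),
    class = "socnet_noise_warning"
  )
})

test_that("evolve keeps the trace consistent with the accepted actions", {
  net <- make_random_network(16, 1, seed = 2)
  cfg <- adaptation_config(
    n_epochs = 40, t_corr = 20, t_trans = 10, seed = 11,
    snapshot_band = 0.1
  )
  ev <- evolve(net, cfg)
  tr <- ev$trace
  expect_equal(nrow(tr), 40L)
  # connectivity bookkeeping: each accepted insert adds 1/N, each accepted
  # removal subtracts 1/N, rejections leave K unchanged
  delta <- ifelse(tr$accepted, ifelse(tr$action == "insert", 1, -1), 0) / 16
  expect_equal(tr$K, avg_connectivity(net) + cumsum(delta))
  expect_equal(n_links(ev$network), round(tail(tr$K, 1) * 16))
  expect_true(all(tr$action %in% c("insert", "remove")))
  expect_true(all(tr$lambda >= 0))
  # snapshots carry their epoch and a near-critical lambda
  for (s in ev$snapshots) {
    expect_lte(abs(s$meta$lambda - 1), 0.1)
    expect_true(s$meta$epoch %in% tr$epoch)
  }
  # identical seeds give bit-identical runs
  ev2 <- evolve(net, cfg)
  expect_identical(ev$trace, ev2$trace)
  expect_identical(ev$network$W, ev2$network$W)
})

test_that("the acceptance rule is a strict increase of the input correlation", {
  net <- make_random_network(16, 1, seed = 2)
  cfg <- adaptation_config(n_epochs = 60, t_corr = 20, t_trans = 10, seed = 12)
  tr <- evolve(net, cfg)$trace
  expect_true(all(tr$accepted == (tr$c_after > tr$c_before)))
})

test_that("stimulant experiments switch thresholds mid-run and stitch the trace", {
  net <- make_random_network(24, 2, seed = 6)
  cfg <- adaptation_config(n_epochs = 12, t_corr = 10, t_trans = 5, beta = 1.25, seed = 3)
  sx <- suppressWarnings(
    stimulant_experiment(net, cfg, switch_epoch = 5, theta_before = 1L, theta_after = 0L)
  )
  expect_equal(nrow(sx$trace), 12L)
  expect_equal(sx$trace$epoch, 1:12)
  expect_equal(sx$trace$phase, rep(c("pre", "post"), c(5, 7)))
  expect_true(all(thresholds(sx$pre$network) == 1L))
  expect_true(all(thresholds(sx$post$network) == 0L))
  expect_error(
    stimulant_experiment(net, cfg, switch_epoch = 12),
    class = "socnet_invalid_config"
  )
})
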