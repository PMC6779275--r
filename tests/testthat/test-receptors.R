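# receptor_engagement: rapid-equilibrium binding and cluster assignment

test_that("rapid-equilibrium binding obeys its limits", {
  expect_equal(bound_receptor_count(905, 0, 1), 0)
  expect_equal(bound_receptor_count(905, 1, 1), 452.5)   # L = Kd
  expect_equal(bound_receptor_count(905, 1e9, 1), 905, tolerance = 1e-6)
  expect_error(bound_receptor_count(905, 1, 0), "kd")
  # monotone nondecreasing in ligand
  l <- seq(0, 20, by = 0.5)
  rl <- bound_receptor_count(905, l, 1.3)
  expect_true(all(diff(rl) >= 0))
  expect_true(all(rl >= 0 & rl <= 905))
})

test_that("equilibrium expression is the fixed point of the binding ODE", {
  # kon [R][L] = koff [RL] with Kd = koff/kon, [R] = Rtot - [RL]
  set.seed(1)
  for (i in 1:20) {
    rtot <- runif(1, 100, 2000)
    l <- runif(1, 0.01, 30)
    kon <- runif(1, 0.01, 1)
    koff <- runif(1, 0.01, 5)
    kd <- koff / kon
    rl <- bound_receptor_count(rtot, l, kd)
    expect_equal(kon * (rtot - rl) * l, koff * rl, tolerance = 1e-9)
  }
})

test_that("trimer counting floors the bound pool", {
  expect_identical(trimer_count(0), 0L)
  expect_identical(trimer_count(452.5), 150L)
  expect_identical(trimer_count(905), 301L)
  expect_error(trimer_count(-1), ">= 0")
})

test_that("receptor panel pools per-species trimers", {
  cfg <- default_cfg()
  pan <- receptor_panel(cfg, 5)
  expect_equal(pan$n_trimers, sum(trimer_count(pan$rl)))
  expect_gt(receptor_panel(cfg, 50)$n_trimers, pan$n_trimers)
  expect_equal(receptor_panel(cfg, 0)$n_trimers, 0L)
})

test_that("cluster assignment conserves trimers in every draw", {
  cfg <- default_cfg()
  set.seed(7)
  for (n in c(0L, 1L, 13L, 172L)) {
    cl <- assign_clusters(n, cfg$clustering$size_trimers,
                          cfg$clustering$probability, TRUE)
    expect_equal(sum(cl$sizes), n)
    expect_equal(length(cl$cluster_id), n)
    if (n > 0) {
      expect_true(all(table(cl$cluster_id) == cl$sizes))
    }
  }
})

test_that("disrupted clustering yields singletons only", {
  cfg <- default_cfg()
  cl <- assign_clusters(150L, cfg$clustering$size_trimers,
                        cfg$clustering$probability, FALSE)
  expect_equal(cl$sizes, rep(1L, 150))
  expect_equal(assign_clusters(0L, 1L, 1, FALSE)$sizes, integer(0))
})

test_that("sampled cluster sizes reproduce the configured distribution", {
  # large-sample oracle: complete clusters are i.i.d. draws from the
  # configured mass function (the final truncated cluster is dropped)
  cfg <- default_cfg()
  set.seed(11)
  cl <- assign_clusters(10000L, cfg$clustering$size_trimers,
                        cfg$clustering$probability, TRUE)
  sizes <- cl$sizes[-length(cl$sizes)]
  obs <- table(factor(sizes, levels = cfg$clustering$size_trimers))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$clustering$probability))
  expect_gt(gof$p.value, 0.01)
})

test_that("invalid cluster distributions are rejected", {
  expect_error(validate_cluster_distribution(c(1, 2), c(0.6, 0.6)),
               class = "riposim_bad_value")
  expect_error(validate_cluster_distribution(c(0, 2), c(0.5, 0.5)),
               class = "riposim_bad_value")
  expect_error(assign_clusters(-1, 1L, 1), class = "riposim_bad_value")
})

test_that("shipped cluster-size table loads and matches the defaults", {
  path <- system.file("extdata", "cluster_sizes.csv", package = "riposim")
  tab <- read_cluster_distribution(path)
  cfg <- default_cfg()
  expect_equal(tab$size_trimers, cfg$clustering$size_trimers)
  expect_equal(tab$probability, cfg$clustering$probability)
})
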