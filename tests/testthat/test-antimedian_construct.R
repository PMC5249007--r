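test_that("sample_stage honors theta, maximality, and infeasibility", {
  set.seed(8)
  n <- 100L
  g <- random_genome(n)
  empty <- partial_assembly(n)

  st0 <- sample_stage(empty, g, theta = 0)
  expect_equal(st0$n_added, 0L)
  expect_equal(nrow(st0$assembly$adj), 0L)

  # from an empty assembly every adjacency has two free ends
  stmax <- sample_stage(empty, g, maximal = TRUE)
  expect_equal(stmax$n_candidates, n)
  expect_equal(genome_id(random_completion(stmax$assembly)), genome_id(g))

  # asking beyond the achievable maximum fails loudly, reporting it
  full <- stmax$assembly
  h <- random_genome(n)
  expect_error(sample_stage(full, h, theta = 0.5), "achievable maximum")
})

test_that("random completion preserves the assembly and pairs all ends", {
  set.seed(12)
  n <- 50L
  g <- random_genome(n)
  asm <- sample_stage(partial_assembly(n), g, maximal = TRUE)$assembly
  expect_identical(genome_id(random_completion(asm)), genome_id(g))

  # two free ends: the single forced adjacency
  asm2 <- partial_assembly(2L, rbind(c(gene_tail(1), gene_head(1))))
  expect_equal(free_ends(asm2), c(gene_tail(2), gene_head(2)))
  done <- random_completion(asm2)
  expect_setequal(adj_set(done), c("1h-1t", "2h-2t"))
})

test_that("two-free-end candidate fraction follows the (1-theta)^2 law", {
  trio <- random_trio(10000, seed = 31)
  set.seed(32)
  st1 <- sample_stage(partial_assembly(10000L), trio$g1, theta = 0.15)
  st2 <- sample_stage(st1$assembly, trio$g2, theta = 0)
  expect_lt(abs(st2$n_candidates / 10000 - (1 - 0.15)^2), 0.02)
})

test_that("construction conserves adjacency counts and realizes thetas", {
  trio <- random_trio(2000, psi = 0.1, omega12 = 0.04, omega13 = 0.06,
                      omega23 = 0.02, seed = 41)
  n <- 2000L
  set.seed(42)
  for (th in list(c(0.1, 0.1), c(0.2, 0.05), c(0, 0.3))) {
    res <- construct_antimedian(trio$g1, trio$g2, trio$g3, th[1], th[2])
    expect_s3_class(validate_genome(res$genome$adj, n), "genome")
    # explicit stages hit their requests exactly
    expect_equal(res$realized_theta[["theta1"]], th[1])
    expect_equal(res$realized_theta[["theta2"]], th[2])
    # conservation: sampled + overlap + completed = n
    shared_n <- n * (res$overlaps$psi + res$overlaps$omega12 +
                       res$overlaps$omega13 + res$overlaps$omega23)
    expect_equal(n * sum(res$realized_theta) + shared_n +
                   res$n_random_completed, n)
    # the reported score is the recomputed score of the genome
    expect_equal(res$score, score(res$genome, trio$g1, trio$g2, trio$g3))
  }
})

test_that("a fully shared trio forces the anti-median onto the inputs", {
  trio <- random_trio(100, psi = 1, seed = 5)
  set.seed(6)
  res <- construct_antimedian(trio$g1, trio$g2, trio$g3, 0, 0)
  expect_equal(genome_id(res$genome), genome_id(trio$g1))
  expect_equal(res$score, 0)
  expect_equal(res$n_random_completed, 0L)
})

test_that("nothing sampled means a near-random genome with score near 3", {
  trio <- random_trio(10000, seed = 51)
  set.seed(52)
  res <- construct_antimedian(trio$g1, trio$g2, trio$g3, 0, 0, theta3 = 0)
  expect_equal(res$n_random_completed, 10000L)
  expect_lt(abs(res$score - 3), 0.01)
})

test_that("maximal third proportion is monotone in theta1 and theta2", {
  trio <- random_trio(4000, seed = 61)
  grid <- seq(0, 0.3, by = 0.1)  # keeps every (theta1, theta2) pair feasible
  set.seed(62)
  t3 <- matrix(NA_real_, length(grid), length(grid))
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    t3[i, j] <- construct_antimedian(trio$g1, trio$g2, trio$g3,
                                     grid[i], grid[j])$realized_theta[["theta3"]]
  }
  # non-increasing along rows and columns (small slack for sampling noise)
  expect_true(all(diff(t3) <= 0.01))
  expect_true(all(apply(t3, 1L, diff) <= 0.01))
})

test_that("empirical maximal theta3 matches the closed forms", {
  trio <- random_trio(10000, seed = 71)
  set.seed(72)
  # nothing sampled first: all of g3 fits
  emp0 <- empirical_max_theta3(trio$g1, trio$g2, trio$g3, 0, 0,
                               replicates = 2)
  expect_lt(abs(emp0$mean - 1), 0.01)

  emp <- empirical_max_theta3(trio$g1, trio$g2, trio$g3, 0.35, 0.35,
                              replicates = 3)
  expect_lt(abs(emp$mean - 0.09), 0.02)
})

test_that("general-overlap simulations are reported against both closed forms", {
  # the model leaves open whether the maximal third proportion at general
  # overlap is the stationary square or the square conditioned on the third
  # genome's own shared ends; the simulation is the arbiter and must lie
  # near at least one of them, between them up to noise
  trio <- random_trio(10000, psi = 0.1, omega12 = 0.05, omega13 = 0.05,
                      omega23 = 0.05, seed = 81)
  set.seed(82)
  emp <- empirical_max_theta3(trio$g1, trio$g2, trio$g3, 0.1, 0.1,
                              replicates = 3)
  stat <- max_theta3(0.1, 0.1, 0.1, 0.05, 0.05, 0.05)
  cond <- max_theta3(0.1, 0.1, 0.1, 0.05, 0.05, 0.05, model = "conditional")
  dev <- c(stationary = abs(emp$mean - stat), conditional = abs(emp$mean - cond))
  expect_lt(min(dev), 0.02)
  expect_gte(emp$mean, min(stat, cond) - 0.02)
  expect_lte(emp$mean, max(stat, cond) + 0.02)
})

test_that("random completion contributes almost no shared adjacencies", {
  trio <- random_trio(10000, seed = 91)
  set.seed(92)
  res <- construct_antimedian(trio$g1, trio$g2, trio$g3, 0.15, 0.15)
  # every shared adjacency beyond the sampled ones comes from completion
  extra <- shared_adjacency_count(res$genome, trio$g1) -
    res$realized_theta[["theta1"]] * 10000
  expect_lt(extra / 10000, 0.01)
})
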