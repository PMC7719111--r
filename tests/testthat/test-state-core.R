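test_that("KL divergence follows the zero and infinity conventions", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_gte(kl_divergence(c(0.2, 0.8), c(0.6, 0.4)), 0)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.25, 0.25)), "same index set")
  expect_error(kl_divergence(c(0.9, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("joint distribution is the elementwise product and marginalises back", {
  sys <- bin_sys(1)
  mu <- as_input_dist(c(0.5, 0.5), sys)
  ident <- as_markov_kernel(diag(2), sys)
  p <- joint_distribution(mu, ident)
  expect_equal(p$prob, diag(2) / 2)
  for (seed in 1:5) {
    sys2 <- rand_small_sys(seed)
    mu2 <- rand_mu(seed, sys2)
    kap <- gen_random_kernel(seed + 100, sys2)
    p2 <- joint_distribution(mu2, kap)
    # elementwise product oracle
    expect_equal(p2$prob, mu2$p * kap$prob)
    expect_equal(input_marginal(p2)$p, mu2$p)
  }
})

test_that("exclusion dependence matches the brute-force double sum", {
  sys <- bin_sys(2)
  for (seed in 1:10) {
    mu <- rand_mu(seed, sys, sparse = (seed %% 2 == 0))
    kap <- gen_random_kernel(seed + 10, sys)
    kj <- gen_random_kernel(seed + 20, sys, "x1")
    expect_equal(exclusion_dependence(mu, kap, kj),
                 oracle_exclusion_dependence(mu, kap, kj),
                 tolerance = 1e-12)
  }
})

test_that("exclusion dependence vanishes exactly when the kernel ignores the removed nodes", {
  sys <- bin_sys(2)
  mu <- rand_mu(1, sys)
  # kernel that depends only on x1
  rows <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  kap <- as_markov_kernel(rows[knockoutr:::project_index(sys, sys$input_names, "x1"), ], sys)
  kj <- as_markov_kernel(rows, sys, inputs = "x1")
  expect_equal(exclusion_dependence(mu, kap, kj), 0)
  # and is strictly positive for a generic kernel
  kap2 <- gen_random_kernel(5, sys)
  expect_gt(exclusion_dependence(mu, kap2, kj), 0)
  # infinite when the post-knockout kernel forbids an observed output
  kz <- as_markov_kernel(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE), sys, inputs = "x1")
  expect_identical(exclusion_dependence(mu, kap2, kz), Inf)
})

test_that("conditional mutual information agrees with independent oracles", {
  # hand value: Y = X1, uniform binary input, no conditioning
  sys <- bin_sys(1)
  mu <- as_input_dist(c(0.5, 0.5), sys)
  p <- joint_distribution(mu, as_markov_kernel(diag(2), sys))
  expect_equal(conditional_mutual_information(p, "x1"), log(2))
  # output independent of the inputs
  sys2 <- bin_sys(2)
  mu2 <- rand_mu(3, sys2)
  const <- as_markov_kernel(matrix(c(0.4, 0.6), 4, 2, byrow = TRUE), sys2)
  p2 <- joint_distribution(mu2, const)
  expect_equal(conditional_mutual_information(p2, c("x1", "x2")), 0)
  expect_equal(conditional_mutual_information(p2, "x2", "x1"), 0)
  # random joints vs entropy-combination and triple-loop oracles
  for (seed in 1:10) {
    sysr <- rand_small_sys(seed)
    mur <- rand_mu(seed + 1, sysr, sparse = (seed %% 3 == 0))
    kapr <- gen_random_kernel(seed + 2, sysr)
    pr <- joint_distribution(mur, kapr)
    n <- length(sysr$input_names)
    K <- sysr$input_names[seq_len(if (seed %% 2 == 0) 1 else n)]
    J <- setdiff(sysr$input_names, K)
    got <- conditional_mutual_information(pr, K, J)
    expect_equal(got, oracle_cmi_entropy(pr, K, J), tolerance = 1e-10)
    expect_equal(got, oracle_cmi_triple_loop(pr, K, J), tolerance = 1e-10)
    expect_gte(got, 0)
  }
  expect_error(conditional_mutual_information(p2, "x1", "x1"), "disjoint")
})

test_that("the optimal post-knockout kernel attains the CMI bound and beats random kernels", {
  for (seed in 1:8) {
    sys <- rand_small_sys(seed)
    mu <- rand_mu(seed + 50, sys)
    kap <- gen_random_kernel(seed + 60, sys)
    n <- length(sys$input_names)
    J <- sys$input_names[seq_len(max(0, n - 1))]
    K <- setdiff(sys$input_names, J)
    star <- optimal_postknockout(mu, kap, J)
    d_star <- exclusion_dependence(mu, kap, star)
    cmi <- conditional_mutual_information(joint_distribution(mu, kap), K, J)
    expect_equal(d_star, cmi, tolerance = 1e-9)
    for (s2 in 1:25) {
      rival <- gen_random_kernel(seed * 1000 + s2, sys, J)
      expect_gte(exclusion_dependence(mu, kap, rival), d_star - 1e-9)
    }
  }
  # restriction to the support: kappa*_I equals kappa on S
  sys <- bin_sys(2)
  mu <- rand_mu(9, sys, sparse = TRUE)
  kap <- gen_random_kernel(91, sys)
  star <- optimal_postknockout(mu, kap, sys$input_names)
  on_s <- which(mu$p > 0)
  expect_equal(star$prob[on_s, ], kap$prob[on_s, ], tolerance = 1e-12)
  # rows with zero marginal are uniform
  off_s <- which(mu$p == 0)
  if (length(off_s) > 0)
    expect_true(all(star$prob[off_s, ] == 0.5))
})

test_that("k-exclusion independence verdicts identify the worst knockout set", {
  sys <- bin_sys(3)
  mu <- rand_mu(2, sys)
  # k = 0 is vacuous
  expect_true(k_exclusion_independent(mu, gen_random_kernel(1, sys), 0)$independent)
  # generic kernels fail at k = 1 with CMI bounded away from zero
  v <- k_exclusion_independent(mu, gen_random_kernel(1, sys), 1)
  expect_false(v$independent)
  expect_gt(v$worst$cmi, 1e-4)
  expect_equal(nrow(v$table), 3)
  # constant kernels pass at every k
  const <- as_markov_kernel(matrix(c(0.3, 0.7), 8, 2, byrow = TRUE), sys)
  v2 <- k_exclusion_independent(mu, const, 3)
  expect_true(v2$independent)
  expect_equal(nrow(v2$table), 7)
})

test_that("mutation neutrality is implied by exclusion independence and fails generically", {
  sys <- bin_sys(3)
  mu <- rand_mu(4, sys)
  const <- as_markov_kernel(matrix(c(0.2, 0.8), 8, 2, byrow = TRUE), sys)
  expect_true(mutation_neutrality(mu, const, 3)$neutral)
  # generic interaction system on two nodes is not neutral at k = 1
  g <- gen_random_system(7, n = 2, hyperedges = list(c("x1", "x2")))
  mu2 <- as_input_dist(rep(0.25, 4), g$system)
  kap2 <- knockout(g$interactions, character(0))
  v <- mutation_neutrality(mu2, kap2, 1)
  expect_false(v$neutral)
  expect_false(is.null(v$witness))
  # the witness pair really differs
  expect_gt(v$witness$sup_diff, 1e-6)
})

test_that("the exclusion-dependence chain holds on seeded random systems", {
  for (seed in 1:25) {
    sys <- rand_small_sys(seed)
    mu <- rand_mu(seed + 200, sys, sparse = (seed %% 4 == 0))
    kap <- gen_random_kernel(seed + 300, sys)
    n <- length(sys$input_names)
    J <- sys$input_names[setdiff(seq_len(n), (seed %% n) + 1)]
    K <- setdiff(sys$input_names, J)
    kj <- gen_random_kernel(seed + 400, sys, J)
    d <- exclusion_dependence(mu, kap, kj)
    star <- optimal_postknockout(mu, kap, J)
    d_star <- exclusion_dependence(mu, kap, star)
    cmi <- conditional_mutual_information(joint_distribution(mu, kap), K, J)
    expect_gte(d, d_star - 1e-9)
    expect_equal(d_star, cmi, tolerance = 1e-9)
    expect_gte(cmi, -1e-12)
  }
})

test_that("k-exclusion independence implies mutation neutrality at the same level", {
  for (seed in 1:6) {
    fam <- robust_family(seed, n = 3, k = 1, support_density = 0.4)
    v_ci <- k_exclusion_independent(fam$mu, fam$kappa, 1)
    expect_true(v_ci$independent)
    expect_true(mutation_neutrality(fam$mu, fam$kappa, 1)$neutral)
  }
})
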