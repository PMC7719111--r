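test_that("Hamming components cover the basic connectivity cases", {
  sys <- bin_sys(3)
  # the full hypercube is connected at k = 1
  all_conf <- configurations(sys)
  part <- hamming_components(all_conf, 1, system = sys)
  expect_length(part$components, 1)
  # two antipodal points are separate at k = 1, joined at k = 2
  sys2 <- bin_sys(2)
  S <- data.frame(x1 = c("0", "1"), x2 = c("0", "1"))
  expect_length(hamming_components(S, 1, system = sys2)$components, 2)
  expect_length(hamming_components(S, 2, system = sys2)$components, 1)
  # k = 0: every configuration is a singleton
  part0 <- hamming_components(all_conf, 0, system = sys)
  expect_length(part0$components, 8)
  expect_error(hamming_components(all_conf[0, ], 1, system = sys), "empty")
})

test_that("components agree with a BFS oracle on random ternary supports", {
  sys <- state_system(
    stats::setNames(rep(list(c("0", "1", "2")), 4), paste0("x", 1:4)),
    c("0", "1"))
  grid <- configurations(sys)
  for (seed in 1:25) {
    S <- withr::with_seed(seed, {
      keep <- runif(nrow(grid)) < 0.15
      if (!any(keep)) keep[1] <- TRUE
      grid[keep, , drop = FALSE]
    })
    codes <- as.matrix(as.data.frame(lapply(sys$input_names, function(nm)
      match(S[[nm]], sys$input_alphabets[[nm]]))))
    for (k in 1:2) {
      part <- hamming_components(S, k, system = sys)
      oracle <- oracle_components_bfs(codes, k)
      # same partition: membership vectors agree up to relabelling
      expect_equal(length(part$components), length(unique(oracle)))
      expect_true(all(tapply(part$membership, oracle,
                             function(v) length(unique(v)) == 1)))
    }
  }
})

test_that("components at k + 1 coarsen the components at k", {
  sys <- bin_sys(4)
  grid <- configurations(sys)
  for (seed in 1:10) {
    S <- withr::with_seed(seed, grid[runif(16) < 0.4, , drop = FALSE])
    if (nrow(S) == 0) next
    parts <- lapply(0:3, function(k) hamming_components(S, k, system = sys))
    for (k in 1:3) {
      fine <- parts[[k]]$membership
      coarse <- parts[[k + 1]]$membership
      # each fine component maps into exactly one coarse component
      expect_true(all(tapply(coarse, fine, function(v) length(unique(v)) == 1)))
    }
  }
})

test_that("custom adjacency relations are honoured", {
  sys2 <- bin_sys(2)
  S <- configurations(sys2)
  # adjacency that links nothing: all singletons even with labels equal
  part <- hamming_components(S, 1, system = sys2,
                             adjacency = function(a, b) FALSE)
  expect_length(part$components, 4)
})

test_that("neutral kernels pass the exclusion-independence check they are built for", {
  g <- gen_grid_support(11, 3)
  lam <- list(c(1, 0), c(0, 1), c(0.5, 0.5))
  names(lam) <- names(g$partition$components)
  kap <- neutral_kernel(g$mu, 1, lam)
  expect_true(k_exclusion_independent(g$mu, kap, 1)$independent)
  expect_true(mutation_neutrality(g$mu, kap, 1)$neutral)
  # off-support rows are uniform
  off <- which(g$mu$p == 0)
  expect_true(all(kap$prob[off, ] == 0.5))
  # single component with a point mass output: constant over the support
  g1 <- gen_grid_support(12, 1)
  kap1 <- neutral_kernel(g1$mu, 1, c(1, 0))
  on_s <- which(g1$mu$p > 0)
  expect_true(all(kap1$prob[on_s, 1] == 1))
  expect_error(neutral_kernel(g$mu, 1, lam[1:2]), "missing output distribution")
})

test_that("mixture joints have the advertised structure and marginals", {
  fam <- robust_family(31, n = 3, k = 1, support_density = 0.35)
  part <- fam$partition
  nc <- length(part$components)
  alpha <- seq_len(nc); alpha <- alpha / sum(alpha)
  mu_n <- lapply(part$components, function(ix) rep(1 / length(ix), length(ix)))
  lam <- rand_lambdas(99, part)
  mix <- neutral_mixture(part, alpha, mu_n, lam)
  p <- mixture_joint(mix)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
  # x-marginal is the alpha-mixture of the component input distributions
  marg <- input_marginal(p)
  expect_gte(min(marg$p[knockoutr:::config_index(
    p$system, part$support, p$system$input_names)]), 1e-12)
  # single component reduces to a product distribution
  if (nc == 1) {
    expect_equal(p$prob, outer(marg$p, lam[[1]]), tolerance = 1e-12)
  }
  # CI check at the partition level
  v <- k_exclusion_independent(marg, conditional_kernel(p), part$k)
  expect_true(v$independent)
})

test_that("robust joints decompose and round-trip; non-neutral joints are rejected with a witness", {
  for (seed in 1:20) {
    fam <- robust_family(seed, n = 3, k = 1, support_density = 0.4)
    p <- joint_distribution(fam$mu, fam$kappa)
    dec <- decompose_robust_joint(p, 1)
    expect_true(dec$accepted)
    expect_equal(mixture_joint(dec$mixture)$prob, p$prob, tolerance = 1e-12)
    # component weights recover the support masses
    expect_equal(sum(dec$mixture$alpha), 1, tolerance = 1e-12)
  }
  # product distribution: single component, alpha = 1
  sys <- bin_sys(2)
  mu <- as_input_dist(rep(0.25, 4), sys)
  lam <- c(0.3, 0.7)
  p_prod <- as_joint_dist(outer(mu$p, lam), sys)
  dec_prod <- decompose_robust_joint(p_prod, 1)
  expect_true(dec_prod$accepted)
  expect_equal(unname(dec_prod$mixture$alpha), 1)
  # generic non-neutral kernel: rejected with a concrete witness pair
  kap_bad <- gen_random_kernel(77, sys)
  dec_bad <- decompose_robust_joint(joint_distribution(mu, kap_bad), 1)
  expect_false(dec_bad$accepted)
  expect_false(is.null(dec_bad$witness))
  expect_gt(dec_bad$witness$sup_diff, 1e-6)
})

test_that("decomposition accepts exactly the joints passing the CI check", {
  # accept family: constructed mixtures; reject family: perturbed kernels
  for (seed in 1:10) {
    fam <- robust_family(seed + 500, n = 3, k = 1, support_density = 0.45)
    p <- joint_distribution(fam$mu, fam$kappa)
    ci <- k_exclusion_independent(input_marginal(p), conditional_kernel(p), 1)
    dec <- decompose_robust_joint(p, 1)
    expect_true(ci$independent)
    expect_true(dec$accepted)
    # perturb one support row towards a different output distribution
    bad <- fam$kappa
    on_s <- which(fam$mu$p > 0)
    target <- on_s[1]
    bad$prob[target, ] <- rev(bad$prob[target, ]) * 0.5 + c(0.49, 0.01)
    bad$prob[target, ] <- bad$prob[target, ] / sum(bad$prob[target, ])
    p_bad <- joint_distribution(fam$mu, bad)
    ci_bad <- k_exclusion_independent(input_marginal(p_bad),
                                      conditional_kernel(p_bad), 1)
    dec_bad <- decompose_robust_joint(p_bad, 1)
    # a perturbation inside a multi-member component breaks both or neither
    expect_equal(ci_bad$independent, dec_bad$accepted)
  }
})
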