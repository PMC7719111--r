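six_node_experiment <- function(g, remove) {
  J <- setdiff(g$system$input_names, remove)
  knockout_experiment(J, knockout(g$interactions, remove))
}

test_that("both worked-example protocols recover the three interaction terms exactly", {
  g <- gen_six_node(19)
  hyp <- list(c("x1", "x2", "x3"), c("x3", "x4"), c("x5", "x6"))
  truth <- gauge_normalize(g$interactions)
  # protocol A: knockouts {3}, {4,5}, {1,5}
  pA <- knockout_protocol(list(six_node_experiment(g, "x3"),
                               six_node_experiment(g, c("x4", "x5")),
                               six_node_experiment(g, c("x1", "x5"))), hyp)
  # protocol B: single-node knockouts of 1, 4, 5
  pB <- knockout_protocol(list(six_node_experiment(g, "x1"),
                               six_node_experiment(g, "x4"),
                               six_node_experiment(g, "x5")), hyp)
  for (proto in list(pA, pB)) {
    res <- solve_protocol(proto)
    expect_true(all(res$verdicts$identifiable))
    expect_false(res$misfit)
    expect_lt(res$residual, 1e-9)
    for (key in names(truth$terms)) {
      if (output_dependence(truth$terms[[key]]) == 0) next
      expect_equal(res$recovered$terms[[key]], truth$terms[[key]],
                   tolerance = 1e-9)
    }
  }
  # pooling both protocols is consistent and yields the same solution
  pooled <- knockout_protocol(c(pA$experiments, pB$experiments), hyp)
  res_pool <- solve_protocol(pooled)
  expect_false(res_pool$misfit)
  for (key in c("x1,x2,x3", "x3,x4", "x5,x6"))
    expect_equal(res_pool$recovered$terms[[key]], truth$terms[[key]],
                 tolerance = 1e-9)
})

test_that("uncovered and confounded hypothesis sets are flagged, not solved", {
  g <- gen_six_node(3)
  hyp <- list(c("x1", "x2", "x3"), c("x3", "x4"), c("x5", "x6"))
  # no experiment's surviving set contains {x5, x6}
  p <- knockout_protocol(list(six_node_experiment(g, c("x5", "x6"))), hyp)
  res <- solve_protocol(p)
  v <- res$verdicts
  expect_false(v$covered[v$set == "x5,x6"])
  expect_false(v$identifiable[v$set == "x5,x6"])
  # the single experiment covers the two overlapping terms but cannot
  # separate their shared dependence on x3
  expect_true(all(v$covered[v$set != "x5,x6"]))
  expect_false(any(v$identifiable[v$set != "x5,x6"]))
  expect_null(res$recovered$terms[["x5,x6"]])
})

test_that("design reports are consistent with solving and with the lattice limits", {
  g <- gen_six_node(3)
  sys <- g$system
  hyp <- list(c("x1", "x2", "x3"), c("x3", "x4"), c("x5", "x6"))
  # no experiments: nothing identifiable
  rep0 <- design_report(hyp, list(), sys)
  expect_false(any(rep0$covered))
  expect_false(any(rep0$identifiable))
  # full lattice: everything identifiable
  full <- knockoutr:::all_subsets(sys$input_names)
  rep_full <- design_report(hyp, full, sys)
  expect_true(all(rep_full$identifiable))
  # structural report matches the solver verdicts on the worked protocols
  pA <- list(six_node_experiment(g, "x3"),
             six_node_experiment(g, c("x4", "x5")),
             six_node_experiment(g, c("x1", "x5")))
  repA <- design_report(hyp, pA)
  resA <- solve_protocol(knockout_protocol(pA, hyp))
  expect_equal(repA$identifiable, resA$verdicts$identifiable)
})

test_that("full identification equals Mobius inversion plus gauge normalisation", {
  for (seed in c(4, 8)) {
    g <- gen_random_system(seed, n = 3, density = 0.5)
    mod <- modalities_from_interactions(g$interactions)
    expect_equal(full_identification(mod)$terms,
                 gauge_normalize(mobius_invert(mod))$terms)
  }
  # exactly the generating supports carry output dependence in the
  # six-node system
  g6 <- gen_six_node(57)
  td <- tidy(full_identification(g6$modalities))
  active <- td$set[td$output_dependence > 1e-8]
  expect_setequal(active, c("x1,x2,x3", "x3,x4", "x5,x6"))
})

test_that("the full-lattice protocol solves to the Mobius answer", {
  g <- gen_random_system(12, n = 3, density = 0.6)
  sys <- g$system
  mod <- modalities_from_interactions(g$interactions)
  subsets <- knockoutr:::all_subsets(sys$input_names)
  exps <- lapply(subsets, function(J)
    knockout_experiment(J, mod$kernels[[knockoutr:::set_key(J)]]))
  proto <- knockout_protocol(exps, subsets)
  res <- solve_protocol(proto)
  expect_true(all(res$verdicts$identifiable))
  expect_false(res$misfit)
  expect_lt(max_term_diff(res$recovered, full_identification(mod)), 1e-9)
})

test_that("robustness hides structure: small knockouts of a robust system identify nothing of high order", {
  fam <- robust_family(6, n = 4, k = 1, support_density = 0.3)
  sys <- fam$system
  # experiments limited to knockouts of size <= k measure kernels equal to
  # the unperturbed conditional on S, so any term of order > r needs
  # information that no such experiment carries; structurally, no
  # experiment with |J| >= n - k ever separates order-n terms from the
  # full-input kernel alone
  hyp <- list(sys$input_names)   # the order-4 term
  exps <- lapply(sys$input_names, function(v) setdiff(sys$input_names, v))
  rep1 <- design_report(hyp, exps, sys)
  expect_true(all(rep1$covered == FALSE))
  expect_false(any(rep1$identifiable))
  # and the measured post-knockout kernels coincide with the original on S
  for (v in sys$input_names) {
    J <- setdiff(sys$input_names, v)
    kJ <- fam$modalities$kernels[[knockoutr:::set_key(J)]]
    kI <- fam$modalities$kernels[[knockoutr:::set_key(sys$input_names)]]
    pr <- knockoutr:::project_index(sys, sys$input_names, J)
    on_s <- which(fam$mu$p > 0)
    expect_equal(kJ$prob[pr[on_s], ], kI$prob[on_s, ], tolerance = 1e-9)
  }
})

test_that("identification on noise-free synthetic systems is exact for identifiable terms", {
  for (seed in 1:6) {
    hyper <- list(c("x1", "x2"), c("x2", "x3"), "x3")
    g <- gen_random_system(seed + 70, n = 3, hyperedges = hyper)
    mod <- modalities_from_interactions(g$interactions)
    # experiments: all two-node survivor sets plus the full set
    sets <- list(c("x1", "x2"), c("x2", "x3"), c("x1", "x3"),
                 c("x1", "x2", "x3"))
    exps <- lapply(sets, function(J)
      knockout_experiment(J, mod$kernels[[knockoutr:::set_key(J)]]))
    res <- solve_protocol(knockout_protocol(exps, hyper))
    truth <- gauge_normalize(g$interactions)
    for (i in seq_along(hyper)) {
      if (!res$verdicts$identifiable[i]) next
      key <- knockoutr:::set_key(hyper[[i]])
      expect_equal(res$recovered$terms[[key]], truth$terms[[key]],
                   tolerance = 1e-9)
    }
    expect_false(res$misfit)
  }
})
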