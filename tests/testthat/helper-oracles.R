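# Builders and independent oracles used across the suite. Oracles are
# deliberately written as naive enumerations, separate from the package's
# vectorised implementations.

bin_sys <- function(n, ny = 2) {
  state_system(
    stats::setNames(rep(list(c("0", "1")), n), paste0("x", seq_len(n))),
    as.character(0:(ny - 1)))
}

# a random small system: n in 1..nmax, alphabet sizes 2..amax, outputs 2..ymax
rand_small_sys <- function(seed, nmax = 4, amax = 3, ymax = 3) {
  withr::with_seed(seed, {
    n <- sample.int(nmax, 1)
    sizes <- sample(2:amax, n, replace = TRUE)
    ny <- sample(2:ymax, 1)
    state_system(
      stats::setNames(lapply(sizes, function(s) as.character(0:(s - 1))),
                      paste0("x", seq_len(n))),
      as.character(0:(ny - 1)))
  })
}

rand_mu <- function(seed, sys, sparse = FALSE) {
  withr::with_seed(seed, {
    m <- n_configs(sys)
    w <- stats::rexp(m)
    if (sparse) {
      keep <- stats::runif(m) < 0.5
      if (!any(keep)) keep[sample.int(m, 1)] <- TRUE
      w[!keep] <- 0
    }
    as_input_dist(w / sum(w), sys)
  })
}

# exclusion dependence by a literal double sum over table rows
oracle_exclusion_dependence <- function(mu, kappa, kappa_j) {
  mu_tab <- as_tibble(mu)
  k_tab <- as_tibble(kappa)
  kj_tab <- as_tibble(kappa_j)
  sysn <- mu$system$input_names
  total <- 0
  for (i in seq_len(nrow(mu_tab))) {
    if (mu_tab$p[i] == 0) next
    for (y in mu$system$output_alphabet) {
      krow <- k_tab
      for (nm in sysn) krow <- krow[krow[[nm]] == mu_tab[[nm]][i], ]
      kv <- krow$p[krow$y == y]
      if (kv == 0) next
      kjrow <- kj_tab
      for (nm in kappa_j$inputs) kjrow <- kjrow[kjrow[[nm]] == mu_tab[[nm]][i], ]
      kjv <- kjrow$p[kjrow$y == y]
      if (kjv == 0) return(Inf)
      total <- total + mu_tab$p[i] * kv * log(kv / kjv)
    }
  }
  total
}

# CMI via the entropy combination H(Y|X_J) - H(Y|X_J, X_K)
oracle_cmi_entropy <- function(p, K, J) {
  tab <- dplyr::filter(as_tibble(p), .data$p > 0)
  ent <- function(groups) {
    agg <- dplyr::summarise(dplyr::group_by(tab, dplyr::across(dplyr::all_of(groups))),
                            m = sum(.data$p), .groups = "drop")
    -sum(agg$m * log(agg$m))
  }
  sysn <- p$system$input_names
  h_jy <- ent(c(J, "y")) - if (length(J) > 0) ent(J) else 0
  h_xy <- ent(c(sysn, "y")) - ent(sysn)
  h_jy - h_xy
}

# CMI by the literal triple loop over (x_J, x_K, y)
oracle_cmi_triple_loop <- function(p, K, J) {
  tab <- as_tibble(p)
  sysn <- p$system$input_names
  gJ <- if (length(J) > 0) do.call(paste, tab[J]) else rep("(all)", nrow(tab))
  gX <- do.call(paste, tab[sysn])
  pj <- tapply(tab$p, gJ, sum)
  pjy <- tapply(tab$p, paste(gJ, tab$y), sum)
  px <- tapply(tab$p, gX, sum)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    pxy <- tab$p[i]
    if (pxy == 0) next
    num <- pxy / px[[gX[i]]]
    den <- pjy[[paste(gJ[i], tab$y[i])]] / pj[[gJ[i]]]
    total <- total + pxy * log(num / den)
  }
  total
}

# connected components by breadth-first search on an explicit edge list
oracle_components_bfs <- function(codes, k) {
  m <- nrow(codes)
  adj <- lapply(seq_len(m), function(i) {
    d <- rowSums(codes != matrix(codes[i, ], m, ncol(codes), byrow = TRUE))
    setdiff(which(d <= k), i)
  })
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# random output distributions, one per component of a partition
rand_lambdas <- function(seed, partition) {
  ny <- length(partition$system$output_alphabet)
  withr::with_seed(seed, {
    lam <- lapply(partition$components, function(ix) {
      v <- stats::rexp(ny)
      v / sum(v)
    })
    lam
  })
}

# a complete strictly positive modality family that is k-exclusion
# independent on the support of mu: optimal conditionals of a neutral
# kernel, mixed with uniform at weight eps (same eps for every kernel, so
# the family equalities survive exactly)
robust_family <- function(seed, n = 4, k = 1, eps = 1e-6, support_density = 0.25) {
  g <- gen_random_system(seed, n, support_density = support_density)
  part <- hamming_components(g$mu, k)
  lam <- rand_lambdas(seed + 1, part)
  kap <- neutral_kernel(g$mu, k, lam)
  kers <- list()
  for (J in knockoutr:::all_subsets(g$system$input_names)) {
    kers[[knockoutr:::set_key(J)]] <-
      smooth_kernel(optimal_postknockout(g$mu, kap, J), eps)
  }
  list(system = g$system, mu = g$mu, kappa = kap, partition = part,
       modalities = functional_modalities(g$system, kers), eps = eps)
}

max_kernel_diff <- function(a, b) max(abs(a$prob - b$prob))

# largest entrywise difference between two modality families
max_family_diff <- function(a, b) {
  max(vapply(names(a$kernels), function(key)
    max_kernel_diff(a$kernels[[key]], b$kernels[[key]]), numeric(1)))
}

# largest entrywise difference between two gauge-normalised families
max_term_diff <- function(a, b) {
  keys <- union(names(a$terms), names(b$terms))
  zero_like <- function(fam, key) {
    t <- fam$terms[[key]]
    if (is.null(t)) 0 else max(abs(t))
  }
  max(vapply(keys, function(key) {
    ta <- a$terms[[key]]; tb <- b$terms[[key]]
    if (is.null(ta)) return(zero_like(b, key))
    if (is.null(tb)) return(zero_like(a, key))
    max(abs(ta - tb))
  }, numeric(1)))
}
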