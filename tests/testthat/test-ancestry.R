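test_that("admixture log-likelihood matches its closed forms", {
  map <- small_map(S = 200, n_chrom = 2, total_cm = 300)
  panel <- small_panel(K = 2, S = 200, seed = 1)

  # all sites missing: l = S log(1/3) for every q
  gl_u <- manual_gl(list(matrix(1 / 3, 200, 3)), map)
  l1 <- admixture_loglik(c(0.2, 0.8), gl_u, panel, id = "X")
  l2 <- admixture_loglik(c(0.9, 0.1), gl_u, panel, id = "X")
  expect_equal(l1, 200 * log(1 / 3), tolerance = 1e-9)
  expect_equal(l1, l2, tolerance = 1e-12)

  # K = 1: h(s) = f_1(s), value independent of the (scalar) q
  pan1 <- small_panel(K = 1, S = 200, seed = 2)
  gl <- manual_gl(list(cbind(rep(0.8, 200), 0.15, 0.05)), map)
  ll <- admixture_loglik(1, gl, pan1, id = "X")
  f <- pan1$freqs[, 1]
  manual <- sum(log(0.8 * (1 - f)^2 + 0.15 * 2 * f * (1 - f) +
                      0.05 * f^2))
  expect_equal(ll, manual, tolerance = 1e-9)

  expect_error(admixture_loglik(c(0.7, 0.7), gl_u, panel, id = "X"),
               "simplex")
})

test_that("EM iterations never decrease the log-likelihood", {
  set.seed(99)
  for (rep in 1:5) {
    S <- 300; K <- 3
    freqs <- matrix(runif(S * K, 0.05, 0.95), S, K)
    gl <- matrix(rgamma(S * 3, 1), S, 3)
    gl <- gl / rowSums(gl)
    q <- rep(1 / K, K)
    ll_prev <- -Inf
    for (it in 1:40) {
      step <- paleocomm:::em_admixture_cpp(gl, freqs, q, -1, 1)
      ll_now <- paleocomm:::admixture_loglik_cpp(gl, freqs, q)
      expect_gte(ll_now, ll_prev - 1e-8)
      ll_prev <- ll_now
      q <- step$q
    }
  }
})

test_that("admixture estimates recover known mixing proportions", {
  # pure individual at good depth
  panel <- small_panel(K = 2, S = 10000, seed = 11)
  ped <- data.frame(id = "P", father = NA, mother = NA)
  co <- simulate_pedigree_genotypes(panel, ped,
                                    matrix(c(1, 0), 1,
                                           dimnames = list("P")),
                                    seed = 12)
  gl <- emit_genotype_likelihoods(co, depth = 5, seed = 13)
  fit <- estimate_admixture(gl, panel, restarts = 5, seed = 14, id = "P")
  expect_gte(coef(fit)["POP1"], 0.95)
  expect_on_simplex(coef(fit))

  # admixed individual at 1x on a larger panel
  panel2 <- simulate_reference_panel(2, 100000, 0.1, seed = 15)
  co2 <- simulate_pedigree_genotypes(panel2,
                                     data.frame(id = "Q", father = NA,
                                                mother = NA),
                                     matrix(c(0.7, 0.3), 1,
                                            dimnames = list("Q")),
                                     seed = 16)
  gl2 <- emit_genotype_likelihoods(co2, depth = 1, seed = 17)
  fit2 <- estimate_admixture(gl2, panel2, restarts = 5, seed = 18,
                             id = "Q")
  expect_lt(max(abs(coef(fit2) - c(0.7, 0.3))), 0.05)

  expect_error(
    estimate_admixture(manual_gl(list(matrix(1 / 3, 100, 3)),
                                 small_map(100, 2, 100)),
                       small_panel(2, 100, seed = 1), id = "X"),
    "informative")
})

test_that("best-of-restarts matches a 0.01 simplex grid search", {
  for (seed in c(31, 32)) {
    panel <- small_panel(K = 2, S = 1500, seed = seed)
    co <- simulate_pedigree_genotypes(
      panel, data.frame(id = "Z", father = NA, mother = NA),
      matrix(c(0.6, 0.4), 1, dimnames = list("Z")), seed = seed + 1)
    gl <- emit_genotype_likelihoods(co, depth = 2, seed = seed + 2)
    fit <- estimate_admixture(gl, panel, restarts = 10, seed = seed + 3,
                              id = "Z")
    qs <- seq(0, 1, by = 0.01)
    lls <- vapply(qs, function(q1)
      admixture_loglik(c(q1, 1 - q1), gl, panel, id = "Z"), 0)
    q_grid <- qs[which.max(lls)]
    expect_lt(abs(coef(fit)["POP1"] - q_grid), 0.02)
  }
})

test_that("block bootstrap quantifies sampling variation correctly", {
  # four identical, strongly informative blocks: no between-block
  # variation, so component SDs collapse to ~0
  S <- 400
  map <- data.frame(chrom = "chr1",
                    pos_bp = (seq_len(S) - 1L) * 1e5 + 1,
                    pos_cm = seq_len(S) * 0.1)
  map <- validate_genetic_map(map)   # 40 Mb -> 4 aligned 10 Mb blocks
  panel <- small_panel(K = 2, S = S, seed = 41)
  block <- cbind(rep(c(0.9, 0.05), 50), 0.05, rep(c(0.05, 0.9), 50))
  gl <- manual_gl(list(do.call(rbind, rep(list(block), 4))[1:S, ]), map)
  # make every block carry the same data: frequencies repeat too
  panel$freqs <- do.call(rbind, rep(list(panel$freqs[1:100, ]), 4))
  bb <- block_bootstrap(gl, panel, block_bp = 1e7, B = 20, seed = 42,
                        id = "X")
  expect_lt(max(bb$sd), 0.01)
  expect_true(all(abs(rowSums(bb$replicates) - 1) < 1e-6))

  # reproducible under a fixed seed
  bb2 <- block_bootstrap(gl, panel, block_bp = 1e7, B = 20, seed = 42,
                         id = "X")
  expect_identical(bb$replicates, bb2$replicates)

  expect_error(block_bootstrap(gl, panel, block_bp = 1e9, B = 10,
                               id = "X"), "fewer than 2 blocks")
  expect_error(block_bootstrap(gl, panel, B = 1, id = "X"), "at least 2")
})

test_that("pooling weakly differentiated components narrows intervals", {
  # panel with two near-identical populations (F_ST ~ 0.002) plus one
  # distinct population: ancestry swaps between the close pair inflate
  # their individual SDs, pooling removes the label switching
  S <- 4000
  base <- simulate_reference_panel(2, S, 0.1, seed = 51)
  fA <- base$freqs[, 1]
  eps <- 0.035                       # perturbation -> F_ST ~ 0.002
  fB <- paleocomm:::clamp_freq(fA + rnorm(S, 0, eps) * sqrt(fA * (1 - fA)))
  panel <- structure(list(pops = c("A", "B", "C"),
                          freqs = cbind(A = fA, B = fB,
                                        C = base$freqs[, 2]),
                          anc_freq = base$anc_freq, map = base$map),
                     class = "ref_panel")
  co <- simulate_pedigree_genotypes(
    panel, data.frame(id = "M", father = NA, mother = NA),
    matrix(c(0.25, 0.25, 0.5), 1, dimnames = list("M")), seed = 52)
  gl <- emit_genotype_likelihoods(co, depth = 1, seed = 53)
  bb <- block_bootstrap(gl, panel, block_bp = 1e7, B = 30, seed = 54,
                        restarts = 3, id = "M")
  pooled <- pool_components(bb, list(AB = c("A", "B")))
  expect_lt(pooled$sd, bb$sd["A"])
  expect_lt(pooled$sd, bb$sd["B"])
  # pooled point estimate is the sum of the member estimates
  expect_equal(pooled$estimate, sum(bb$point$q[c("A", "B")]),
               tolerance = 1e-12)
  # subadditivity of the SD of a sum
  expect_lte(pooled$sd, bb$sd["A"] + bb$sd["B"] + 1e-12)

  # pooling both components of a K=2 fit gives the constant 1
  panel2 <- small_panel(K = 2, S = 800, seed = 55)
  co2 <- simulate_pedigree_genotypes(
    panel2, data.frame(id = "N", father = NA, mother = NA),
    matrix(c(0.5, 0.5), 1, dimnames = list("N")), seed = 56)
  gl2 <- emit_genotype_likelihoods(co2, depth = 2, seed = 57)
  bb2 <- block_bootstrap(gl2, panel2, block_bp = 1e7, B = 10, seed = 58,
                         restarts = 2, id = "N")
  both <- pool_components(bb2, list(c("POP1", "POP2")))
  expect_equal(both$estimate, 1, tolerance = 1e-9)
  expect_lt(both$sd, 1e-9)

  expect_error(pool_components(bb2, list(c("POP1", "NOPE"))), "unknown")
})

test_that("congruence correlation behaves at its limits", {
  set.seed(61)
  qa <- matrix(runif(40), 20, 2, dimnames = list(paste0("i", 1:20)))
  qa <- qa / rowSums(qa)
  colnames(qa) <- c("N", "S")
  expect_equal(congruence_correlation(qa, qa, "N"), 1)

  qb <- qa[, c(2, 1)]; colnames(qb) <- c("N", "S")
  expect_equal(congruence_correlation(qa, qb, "N"), -1)

  # independent vectors: null correlation near zero
  a <- matrix(runif(1000), 1000, 1, dimnames = list(NULL, "N"))
  b <- matrix(runif(1000), 1000, 1, dimnames = list(NULL, "N"))
  expect_lt(abs(congruence_correlation(a, b, "N")), 0.1)

  expect_error(congruence_correlation(qa[1:2, ], qa[1:2, ], "N"),
               "at least 3")
  const <- matrix(0.5, 10, 1, dimnames = list(NULL, "N"))
  expect_error(congruence_correlation(const, const, "N"),
               "zero variance")
})
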