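# brute-force conditional genotype-pair table: shared alleles drawn
# once, non-shared alleles drawn independently from frequency p
oracle_pair_table <- function(m, p) {
  tab <- matrix(0, 3, 3)
  bern <- function(a) ifelse(a == 1, p, 1 - p)
  if (m == 0) {
    for (a in 0:2) for (b in 0:2)
      tab[a + 1, b + 1] <- dbinom(a, 2, p) * dbinom(b, 2, p)
  } else if (m == 1) {
    for (A in 0:1) for (x in 0:1) for (y in 0:1)
      tab[A + x + 1, A + y + 1] <- tab[A + x + 1, A + y + 1] +
        bern(A) * bern(x) * bern(y)
  } else {
    for (a in 0:2) tab[a + 1, a + 1] <- dbinom(a, 2, p)
  }
  tab
}

test_that("conditional site likelihoods match brute-force enumeration", {
  set.seed(1)
  for (rep in 1:5) {
    p <- runif(1, 0.1, 0.9)
    gi <- rgamma(3, 1); gi <- gi / sum(gi)
    gj <- rgamma(3, 1); gj <- gj / sum(gj)
    L <- kin_site_likelihoods(matrix(gi, 1), matrix(gj, 1), p)
    for (m in 0:2) {
      oracle <- sum(outer(gi, gj) * oracle_pair_table(m, p))
      expect_equal(as.numeric(L[1, m + 1]), oracle, tolerance = 1e-12)
    }
  }
})

test_that("relatedness ML recovers duplicates, parent-offspring and unrelated", {
  map <- place_sites(default_genome(22, 3540), 20000)
  panel <- simulate_reference_panel(1, 20000, 0.1, map = map, seed = 2)
  ped <- data.frame(id = c("P1", "P2", "C"),
                    father = c(NA, NA, "P1"), mother = c(NA, NA, "P2"))
  co <- simulate_pedigree_genotypes(panel, ped, c(1), seed = 3)
  f <- panel$freqs[, 1]

  # duplicate: same genotypes emitted twice at high depth
  dup_geno <- co$geno[, c("P1", "P1")]
  colnames(dup_geno) <- c("D1", "D2")
  gl_dup <- emit_genotype_likelihoods(dup_geno, depth = 4, map = map,
                                      seed = 4)
  rd <- estimate_relatedness(gl_dup, "D1", "D2", f, grid_step = 0.05)
  expect_gte(rd$k2, 0.9)
  expect_gte(rd$pihat, 0.9)

  gl <- emit_genotype_likelihoods(co, depth = 1, seed = 5)
  ru <- estimate_relatedness(gl, "P1", "P2", f, grid_step = 0.05)
  expect_gte(ru$k0, 0.9)
  rpo <- estimate_relatedness(gl, "P1", "C", f, grid_step = 0.05)
  expect_gte(rpo$k1, 0.8)
  expect_lte(rpo$k0, 0.1)
  # k on the simplex, pi-hat consistent
  for (r in list(rd, ru, rpo)) {
    expect_on_simplex(c(r$k0, r$k1, r$k2))
    expect_equal(r$pihat, r$k1 / 2 + r$k2, tolerance = 1e-9)
  }
})

test_that("ML estimate agrees with an exhaustive 0.01-grid oracle", {
  res <- relative_cohort(S = 2000, depth = 2, seed = 11)
  for (pair in list(c("A", "C"), c("C", "D"), c("A", "E"))) {
    r <- estimate_relatedness(res$gl, pair[1], pair[2], res$freqs)
    # independent oracle: direct log-likelihood scan at 0.01 resolution
    shared <- !res$gl$missing[, pair[1]] & !res$gl$missing[, pair[2]]
    L <- kin_site_likelihoods(res$gl$gl[shared, , pair[1]],
                              res$gl$gl[shared, , pair[2]],
                              res$freqs[shared])
    pts <- expand.grid(k0 = 0:100, k1 = 0:100)
    pts <- as.matrix(pts[pts$k0 + pts$k1 <= 100, ]) / 100
    grid <- cbind(pts, k2 = 1 - rowSums(pts))
    ll <- colSums(log(L %*% t(grid) + 1e-300))
    best <- grid[which.max(ll), ]
    expect_lt(max(abs(c(r$k0, r$k1, r$k2) - best)), 0.03)
  }
})

test_that("overlap filter applies the 10,000-SNP rule exactly", {
  pairs <- data.frame(id1 = c("a", "b", "c"), id2 = c("x", "y", "z"),
                      n_snps = c(9999, 10000, 25000))
  kept <- filter_by_overlap(pairs)
  expect_equal(kept$id1, c("b", "c"))
  expect_equal(attr(kept, "removed")$n_snps, 9999)
  empty <- filter_by_overlap(pairs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("degree bins follow the power-of-two convention on pi-hat", {
  df <- data.frame(
    pihat = c(0.98, 0.5, 0.5, 0.25, 0.125, 0.01),
    k0 = c(0.01, 0.02, 0.25, 0.5, 0.75, 0.98))
  expect_equal(classify_degree(df),
               c("duplicate", "parent-offspring", "sibling", "2nd",
                 "3rd", "unrelated"))
  # truth k-values of the canonical relationships map to their degree
  truth <- data.frame(
    pihat = c(1, 0.5, 0.5, 0.25, 0.125),
    k0 = c(0, 0, 0.25, 0.5, 0.75))
  expect_equal(classify_degree(truth),
               c("duplicate", "parent-offspring", "sibling", "2nd",
                 "3rd"))
})

test_that("estimator reconciliation follows the majority rule", {
  mk <- function(degrees, estimators) {
    data.frame(id1 = "a", id2 = "b", estimator = estimators,
               degree = degrees)
  }
  # full agreement: accepted, no flag
  r <- reconcile(mk(rep("parent-offspring", 3),
                    c("ml", "read", "kin")))
  expect_equal(r$degree, "parent-offspring")
  expect_equal(r$flag, "")
  # primary 2nd, both secondaries unrelated: discordant but kept
  r2 <- reconcile(mk(c("2nd", "unrelated", "unrelated"),
                     c("ml", "read", "kin")))
  expect_equal(r2$degree, "2nd")
  expect_equal(r2$flag, "discordant")
  # 3rd with one secondary at 2nd: within one level, supported
  r3 <- reconcile(mk(c("3rd", "2nd"), c("ml", "read")))
  expect_equal(r3$flag, "")
  # only the primary available
  r4 <- reconcile(mk("sibling", "ml"))
  expect_equal(r4$flag, "single-source")
})

test_that("pedigree assembly builds components, depths and orientations", {
  trio <- data.frame(id1 = c("dad", "mom"), id2 = c("kid", "kid"),
                     degree = "parent-offspring")
  meta <- data.frame(id = c("dad", "mom", "kid"),
                     age_class = c("adult", "adult", "nonadult"))
  pg <- assemble_pedigrees(trio, meta)
  expect_equal(nrow(pg$components), 1)
  expect_equal(pg$components$size, 3)
  expect_equal(pg$components$generation_depth, 2)

  # chain of four oriented parent-offspring edges spans five generations
  chain <- data.frame(id1 = c("g1", "g2", "g3", "g4"),
                      id2 = c("g2", "g3", "g4", "g5"),
                      degree = "parent-offspring")
  ori <- data.frame(parent = c("g1", "g2", "g3", "g4"),
                    child = c("g2", "g3", "g4", "g5"))
  pg2 <- assemble_pedigrees(chain, orientation = ori)
  expect_equal(pg2$components$generation_depth, 5)

  # individuals tied only by distant evidence are listed separately
  far <- rbind(chain,
               data.frame(id1 = "g1", id2 = "loner",
                          degree = "unrelated"))
  pg3 <- assemble_pedigrees(far, orientation = ori)
  expect_equal(pg3$distant, "loner")

  # order independence: permuting the input rows changes nothing
  set.seed(3)
  shuffled <- far[sample.int(nrow(far)), ]
  pg4 <- assemble_pedigrees(shuffled, orientation = ori)
  expect_identical(pg3$components, pg4$components)
})

test_that("a five-generation pedigree is recovered from low-coverage data", {
  # 24-member pedigree plus a separate unrelated family, homogeneous
  # ancestry so the estimator's frequency assumption holds
  map <- place_sites(default_genome(22, 3540), 12000)
  panel <- simulate_reference_panel(1, 12000, 0.1, map = map, seed = 21)
  dp <- demo_pedigree()
  fam2 <- data.frame(id = c("z1", "z2", "z3", "z4"),
                     father = c(NA, NA, "z1", "z1"),
                     mother = c(NA, NA, "z2", "z2"))
  ped <- rbind(dp$ped, fam2)
  co <- simulate_pedigree_genotypes(panel, ped, c(1), seed = 22)
  gl <- emit_genotype_likelihoods(co, depth = 1, seed = 23)
  pairs <- estimate_relatedness_all(gl, panel$freqs[, 1],
                                    grid_step = 0.05)
  pairs <- filter_by_overlap(pairs, min_snps = 3000)
  pairs$degree <- classify_degree(pairs)
  cons <- reconcile(data.frame(id1 = pairs$id1, id2 = pairs$id2,
                               estimator = "ml", degree = pairs$degree))
  pg <- assemble_pedigrees(cons)
  comp1 <- strsplit(pg$components$members[1], ";")[[1]]
  expect_gte(mean(dp$ped$id %in% comp1), 0.9)
  # the unrelated family must not merge into the big pedigree
  expect_false(any(fam2$id %in% comp1))
})
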