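test_that("reference panel follows the Balding-Nichols model", {
  expect_error(simulate_reference_panel(0, 10, 0.1), "positive")
  expect_error(simulate_reference_panel(2, 10, 1.2), "F must lie")

  p <- simulate_reference_panel(3, 3000, 0.1, seed = 1)
  expect_true(all(p$freqs > 0 & p$freqs < 1))

  # F -> 0: population frequencies collapse onto the ancestral frequency
  p0 <- simulate_reference_panel(2, 3000, 1e-4, seed = 2)
  expect_lt(mean(abs(p0$freqs - p0$anc_freq)), 0.01)

  # Hudson F_ST oracle on the simulated population frequencies: under
  # the model E[(p1-p2)^2] / E[p1(1-p2) + p2(1-p1)] = F
  ph <- simulate_reference_panel(2, 10000, 0.1, seed = 3)
  p1 <- ph$freqs[, 1]; p2 <- ph$freqs[, 2]
  fst <- sum((p1 - p2)^2 - 0) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(fst, 0.1, tolerance = 0.02 / 0.1)
})

test_that("pedigree transmission obeys Mendelian and crossover limits", {
  expect_error(validate_pedigree(
    data.frame(id = c("A", "B"), father = c(NA, "Z"),
               mother = c(NA, "A"))), "unknown parent")
  expect_error(validate_pedigree(
    data.frame(id = c("A", "B"), father = c("B", "A"),
               mother = c("B", "A"))), "cycle")

  co <- relative_cohort(S = 1500, depth = 2, seed = 5,
                        n_chrom = 4, total_cm = 800)$cohort
  # parent-offspring: the child shares at least one allele everywhere
  gA <- co$geno[, "A"]; gC <- co$geno[, "C"]
  incompatible <- (gA == 0 & gC == 2) | (gA == 2 & gC == 0)
  expect_false(any(incompatible))

  # zero-crossover limit: a vanishing map means each child haplotype is
  # one unbroken parental haplotype
  map0 <- place_sites(default_genome(n_chrom = 2, total_cm = 0.02), 50)
  pan0 <- simulate_reference_panel(1, 50, 0.1, map = map0, seed = 6)
  ped <- data.frame(id = c("P", "Q", "K"), father = c(NA, NA, "P"),
                    mother = c(NA, NA, "Q"))
  co0 <- simulate_pedigree_genotypes(pan0, ped, c(1), seed = 7)
  for (h in 1:2)
    for (ch in names(co0$chrom_cm))
      expect_equal(nrow(co0$haps[["K"]][[h]][[ch]]), 1)
})

test_that("realized sibling IBD matches expectation on a 3,500 cM genome", {
  res <- relative_cohort(S = 800, depth = 1, seed = 11)
  tk <- truth_kinship(res$cohort,
                      data.frame(id1 = "C", id2 = "D"))
  expect_equal(tk$k0, 0.25, tolerance = 0.1 / 0.25)
  expect_equal(tk$k1, 0.50, tolerance = 0.1 / 0.50)
  expect_equal(tk$k2, 0.25, tolerance = 0.1 / 0.25)
})

test_that("truth k-coefficients and truth IBD segments are consistent", {
  res <- relative_cohort(S = 500, depth = 1, seed = 21,
                         n_chrom = 5, total_cm = 900)
  co <- res$cohort
  tk <- truth_kinship(co)
  seg <- truth_ibd_segments(co, by_status = TRUE)
  tot <- sum(unlist(co$chrom_cm))
  for (i in seq_len(nrow(tk))) {
    s <- seg[seg$id1 == tk$id1[i] & seg$id2 == tk$id2[i], ]
    rhs <- (sum(s$length_cm[s$ibd == 1]) / 2 +
              sum(s$length_cm[s$ibd == 2])) / tot
    expect_equal(tk$k1[i] / 2 + tk$k2[i], rhs, tolerance = 1e-9)
    expect_equal(tk$k0[i] + tk$k1[i] + tk$k2[i], 1, tolerance = 1e-9)
  }
})

test_that("genotype likelihood emission follows the read model", {
  expect_error(read_emission_likelihood(1, 1, 0.6), "0.5")
  # one derived read at error 0.01: unnormalized (0.01, 0.5, 0.99)
  lik <- read_emission_likelihood(1L, 1L, 0.01)
  expect_equal(as.numeric(lik), c(0.01, 0.5, 0.99))

  res <- relative_cohort(S = 800, depth = 1, seed = 31,
                         n_chrom = 4, total_cm = 700)
  sums <- apply(res$gl$gl, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # depth 0: everything missing and uniform
  gl0 <- emit_genotype_likelihoods(res$cohort, depth = 0, seed = 32)
  expect_true(all(gl0$missing))
  expect_true(all(abs(gl0$gl - 1 / 3) < 1e-12))

  # error 0, very high depth: mass concentrates on the true genotype
  gl_hi <- emit_genotype_likelihoods(res$cohort, depth = 60, error = 0,
                                     seed = 33)
  called <- apply(gl_hi$gl[, , "A"], 1, which.max) - 1L
  covered <- !gl_hi$missing[, "A"]
  expect_gt(mean(called[covered] == res$cohort$geno[covered, "A"]), 0.999)
  expect_gt(mean(apply(gl_hi$gl[covered, , "A"], 1, max) > 0.999), 0.99)
})

test_that("regenerating with the same seed is byte-identical", {
  a <- relative_cohort(S = 400, depth = 1, seed = 41,
                       n_chrom = 3, total_cm = 500)
  b <- relative_cohort(S = 400, depth = 1, seed = 41,
                       n_chrom = 3, total_cm = 500)
  expect_identical(a$panel$freqs, b$panel$freqs)
  expect_identical(a$cohort$geno, b$cohort$geno)
  expect_identical(a$gl$gl, b$gl$gl)

  m <- data.frame(id = c("i1", "i2"), locality = c("local", "nonlocal"))
  i1 <- simulate_isotopes(m, seed = 42)
  i2 <- simulate_isotopes(m, seed = 42)
  expect_identical(i1$records, i2$records)
})

test_that("isotope simulation plants recoverable truth", {
  expect_error(simulate_isotopes(data.frame()[0, ]), "empty")

  pars <- isotope_sim_params()
  n <- 400
  m <- data.frame(id = sprintf("i%03d", 1:n),
                  locality = rep(c("local", "nonlocal"), c(n - 20, 20)))
  iso <- simulate_isotopes(m, pars, seed = 43)
  loc <- iso$records$sr_ratio[iso$truth$locality == "local"]
  nl <- iso$records$sr_ratio[iso$truth$locality == "nonlocal"]
  band <- mean(loc) + c(-2, 2) * sd(loc)
  # nonlocals offset by 10 local SDs all fall outside the 2 SD band
  expect_true(all(nl < band[1] | nl > band[2]))

  # planted QC-failure fraction is recovered binomially
  pars$qc_fail_fraction <- 0.2
  iso2 <- simulate_isotopes(
    data.frame(id = sprintf("j%03d", 1:500)), pars, seed = 44)
  qc <- collagen_qc(iso2$records)
  expect_equal(mean(!qc$pass), 0.2, tolerance = 0.05 / 0.2)
  # truth labels and realized QC agree almost everywhere
  expect_gt(mean(qc$pass == !iso2$truth$qc_fail), 0.95)
})
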