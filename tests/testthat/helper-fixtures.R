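# Shared fixtures: all synthetic, generated in code at test time.

# small genome so pedigree simulations stay fast but keep several
# chromosomes' worth of recombination
small_map <- function(S = 2000, n_chrom = 6, total_cm = 1200) {
  place_sites(default_genome(n_chrom = n_chrom, total_cm = total_cm), S)
}

small_panel <- function(K = 2, S = 2000, F = 0.1, seed = 1, ...) {
  simulate_reference_panel(K, S, F, seed = seed, ...)
}

# three-generation family with marrying-in founders covering degrees
# 1-3: parent-offspring, siblings, grandparent, avuncular, half-sibling,
# first cousins.  `truth_degrees()` lists the pedigree degree per pair.
relative_pedigree <- function(prefix = "") {
  p <- function(x) paste0(prefix, x)
  ped <- rbind(
    data.frame(id = p(c("A", "B", "E", "E2", "W")),
               father = NA_character_, mother = NA_character_),
    data.frame(id = p(c("C", "D")), father = p("A"), mother = p("B")),
    data.frame(id = p("Hs"), father = p("A"), mother = p("W")),
    data.frame(id = p(c("F", "G")), father = p("C"), mother = p("E")),
    data.frame(id = p("H"), father = p("D"), mother = p("E2")))
  ped
}

relative_truth_degrees <- function(prefix = "") {
  p <- function(x) paste0(prefix, x)
  rbind(
    data.frame(id1 = p(c("A", "B", "A", "B", "C", "C", "D", "E", "E",
                         "E2", "A", "W")),
               id2 = p(c("C", "C", "D", "D", "F", "G", "H", "F", "G",
                         "H", "Hs", "Hs")),
               degree = "parent-offspring"),
    data.frame(id1 = p(c("C", "F")), id2 = p(c("D", "G")),
               degree = "sibling"),
    data.frame(id1 = p(c("A", "A", "B", "B", "A", "B", "D", "D", "C",
                         "C", "D")),
               id2 = p(c("F", "G", "F", "G", "H", "H", "F", "G", "H",
                         "Hs", "Hs")),
               degree = "2nd"),
    data.frame(id1 = p(c("F", "G", "F", "G")),
               id2 = p(c("H", "H", "Hs", "Hs")),
               degree = "3rd"))
}

# homogeneous-ancestry cohort over the relative pedigree: the true site
# frequencies equal the single panel column, matching the kinship
# estimator's assumption
relative_cohort <- function(S = 2000, depth = 2, seed = 1, n_chrom = 22,
                            total_cm = 3540, prefix = "") {
  map <- place_sites(default_genome(n_chrom, total_cm), S)
  panel <- simulate_reference_panel(1, S, 0.1, map = map, seed = seed)
  cohort <- simulate_pedigree_genotypes(panel, relative_pedigree(prefix),
                                        c(1), seed = seed + 1)
  gl <- emit_genotype_likelihoods(cohort, depth, 0.01, seed = seed + 2)
  list(panel = panel, cohort = cohort, gl = gl,
       freqs = panel$freqs[, 1])
}

# gl_matrix built directly from explicit likelihood triples
manual_gl <- function(triples, map, ids = "X") {
  S <- nrow(map)
  gl <- array(NA_real_, c(S, 3, length(ids)),
              dimnames = list(NULL, c("g0", "g1", "g2"), ids))
  missing <- matrix(FALSE, S, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    tri <- triples[[j]]
    tri <- tri / rowSums(tri)
    gl[, , j] <- tri
    missing[, j] <- apply(abs(tri - 1 / 3) < 1e-9, 1, all)
  }
  structure(list(ids = ids, map = map, gl = gl, missing = missing),
            class = "gl_matrix")
}

expect_on_simplex <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = 1e-6)
}
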