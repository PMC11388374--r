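#' Simulate a reference allele-frequency panel
#'
#' Draws per-population derived-allele frequencies under the
#' Balding--Nichols model: an ancestral frequency \eqn{p} uniform on
#' [0.05, 0.95] per site, and population frequencies
#' \eqn{f_k \sim Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)} so that
#' \eqn{E[f_k] = p} and the differentiation from the ancestral pool is
#' \eqn{F_k}.  Frequencies are clamped to [1e-5, 1 - 1e-5] so that no
#' site is fixed in any population.
#'
#' @param K number of reference populations.
#' @param S number of sites.
#' @param F_vector differentiation parameter per population, each in
#'   (0, 1); recycled to length \code{K}.
#' @param map optional \code{genetic_map} with \code{S} rows; by default
#'   sites are placed on \code{default_genome()}.
#' @param pops population names (default \code{POP1..POPK}).
#' @param seed integer seed.
#' @return a \code{ref_panel}: list with \code{pops}, \code{freqs}
#'   (S x K matrix), \code{anc_freq}, \code{map}.
#' @export
simulate_reference_panel <- function(K, S, F_vector, map = NULL,
                                     pops = NULL, seed = NULL) {
  if (K < 1 || S < 1) stop("K and S must be positive")
  F_vector <- rep_len(F_vector, K)
  if (any(F_vector <= 0 | F_vector >= 1)) stop("F must lie in (0, 1)")
  if (is.null(map)) map <- place_sites(default_genome(), S)
  if (nrow(map) != S) stop("map must have S rows")
  pops <- pops %||% paste0("POP", seq_len(K))
  with_seed(seed, {
    p <- runif(S, 0.05, 0.95)
    freqs <- vapply(seq_len(K), function(k) {
      F <- F_vector[k]
      rbeta(S, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }, numeric(S))
    freqs <- clamp_freq(matrix(freqs, nrow = S))
    colnames(freqs) <- pops
    structure(list(pops = pops, freqs = freqs, anc_freq = p, map = map),
              class = "ref_panel")
  })
}

clamp_freq <- function(f, eps = 1e-5) pmin(pmax(f, eps), 1 - eps)

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel:", length(x$pops), "populations x",
      nrow(x$freqs), "sites\n")
  cat("  populations:", paste(x$pops, collapse = ", "), "\n")
  invisible(x)
}

# ---- pedigree machinery -----------------------------------------------

#' Validate a pedigree specification
#'
#' A pedigree is a data frame with columns \code{id}, \code{father},
#' \code{mother}; founders have both parents \code{NA}.  Checks reject
#' duplicate ids, children referencing unknown parents, half-specified
#' parentage and cycles.
#'
#' @param ped data frame with \code{id}, \code{father}, \code{mother}.
#' @return the pedigree, rows re-ordered so parents precede children.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  founder <- is.na(ped$father) & is.na(ped$mother)
  if (any(xor(is.na(ped$father), is.na(ped$mother))))
    stop("individuals must have both parents specified or neither")
  unknown <- setdiff(c(ped$father, ped$mother), c(ped$id, NA))
  if (length(unknown))
    stop("child references unknown parent: ", paste(unknown, collapse = ", "))
  # topological sort; failure to make progress means a cycle
  placed <- ped$id[founder]
  order <- which(founder)
  todo <- which(!founder)
  while (length(todo)) {
    ready <- todo[ped$father[todo] %in% placed & ped$mother[todo] %in% placed]
    if (!length(ready)) stop("pedigree contains a cycle")
    order <- c(order, ready)
    placed <- c(placed, ped$id[ready])
    todo <- setdiff(todo, ready)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# splice two parental haplotypes (segment frames over [0, L]) at the
# given crossover positions, starting from haplotype `first`
splice_hap <- function(a, b, breaks, first, L) {
  if (length(breaks) == 0L) return(if (first == 1L) a else b)
  cuts <- c(0, breaks, L)
  src <- rep_len(c(first, 3L - first), length(cuts) - 1L)
  pieces <- vector("list", length(src))
  for (i in seq_along(src)) {
    h <- if (src[i] == 1L) a else b
    lo <- cuts[i]; hi <- cuts[i + 1L]
    keep <- which(h$end > lo & h$start < hi)
    if (length(keep)) {
      seg <- h[keep, , drop = FALSE]
      seg$start[1L] <- max(seg$start[1L], lo)
      seg$end[nrow(seg)] <- min(seg$end[nrow(seg)], hi)
      pieces[[i]] <- seg
    }
  }
  merge_adjacent(do.call(rbind, pieces))
}

merge_adjacent <- function(s) {
  n <- nrow(s)
  if (is.null(n) || n <= 1L) return(s)
  new <- c(TRUE, s$anc[-1L] != s$anc[-n])
  data.frame(start = s$start[new],
             end = s$end[c(which(new)[-1L] - 1L, n)],
             anc = s$anc[new])
}

# one gamete: Poisson(L/100) crossovers per chromosome, positions
# uniform in genetic distance (Haldane, no interference)
meiosis <- function(hap_pair, chrom_cm) {
  out <- vector("list", length(chrom_cm))
  names(out) <- names(chrom_cm)
  for (ch in names(chrom_cm)) {
    L <- chrom_cm[[ch]]
    nx <- rpois(1L, L / 100)
    breaks <- sort(runif(nx, 0, L))
    first <- sample.int(2L, 1L)
    out[[ch]] <- splice_hap(hap_pair[[1L]][[ch]], hap_pair[[2L]][[ch]],
                            breaks, first, L)
  }
  out
}

whole_hap <- function(anc_id, chrom_cm) {
  out <- lapply(chrom_cm, function(L)
    data.frame(start = 0, end = L, anc = anc_id))
  names(out) <- names(chrom_cm)
  out
}

chrom_lengths_cm <- function(map) {
  len <- attr(map, "chrom_cm")
  if (!is.null(len)) return(len)
  tab <- tapply(map$pos_cm, map$chrom, max)
  len <- as.list(tab * (1 + 1 / (2 * max(table(map$chrom)))))
  len[unique(map$chrom)]
}

#' Simulate genotypes through a pedigree with IBD truth
#'
#' Founder haplotypes are drawn per site as Bernoulli(\eqn{h}),
#' \eqn{h(s) = \sum_k q_k f_k(s)}, from each founder's admixture vector
#' \eqn{q}.  Children are formed by meiosis: per chromosome the crossover
#' count is Poisson in the map length (Morgans), crossover positions are
#' uniform in genetic distance, and the transmitted founder-haplotype
#' mosaic is recorded.  Those mosaics yield exact per-pair IBD segments
#' and realized (k0, k1, k2) via \code{\link{truth_kinship}} and
#' \code{\link{truth_ibd_segments}}.
#'
#' @param panel a \code{ref_panel}.
#' @param pedigree data frame (\code{id}, \code{father}, \code{mother});
#'   founders have \code{NA} parents.
#' @param founder_q matrix of admixture vectors, one row per founder
#'   (rownames = founder ids), columns matching \code{panel$pops}.  A
#'   single vector is recycled for all founders.
#' @param seed integer seed.
#' @return a \code{sim_cohort}: ids, map, genotype matrix (sites x
#'   individuals, 0/1/2 derived copies), haplotype mosaics, expected
#'   admixture truth, and the pedigree.
#' @export
simulate_pedigree_genotypes <- function(panel, pedigree, founder_q,
                                        seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  ped <- validate_pedigree(pedigree)
  map <- panel$map
  chrom_cm <- chrom_lengths_cm(map)
  founders <- ped$id[is.na(ped$father)]
  K <- length(panel$pops)
  if (is.null(dim(founder_q)))
    founder_q <- matrix(rep(founder_q, length(founders)),
                        ncol = K, byrow = TRUE,
                        dimnames = list(founders, panel$pops))
  if (!all(founders %in% rownames(founder_q)))
    stop("founder_q must carry a row for every founder")
  qs <- founder_q[founders, , drop = FALSE]
  if (any(qs < -1e-9) || any(abs(rowSums(qs) - 1) > 1e-6))
    stop("founder admixture vectors must lie on the simplex")

  with_seed(seed, {
    S <- nrow(map)
    n_f <- length(founders)
    # founder haplotype alleles: row per founder haplotype
    fh_alleles <- matrix(0L, nrow = 2L * n_f, ncol = S)
    for (i in seq_len(n_f)) {
      h <- as.vector(panel$freqs %*% qs[i, ])
      fh_alleles[2L * i - 1L, ] <- rbinom(S, 1L, h)
      fh_alleles[2L * i, ]      <- rbinom(S, 1L, h)
    }
    haps <- vector("list", nrow(ped))
    names(haps) <- ped$id
    q_truth <- matrix(NA_real_, nrow(ped), K,
                      dimnames = list(ped$id, panel$pops))
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (is.na(ped$father[i])) {
        fi <- match(id, founders)
        haps[[id]] <- list(whole_hap(2L * fi - 1L, chrom_cm),
                           whole_hap(2L * fi, chrom_cm))
        q_truth[id, ] <- qs[fi, ]
      } else {
        haps[[id]] <- list(meiosis(haps[[ped$father[i]]], chrom_cm),
                           meiosis(haps[[ped$mother[i]]], chrom_cm))
        q_truth[id, ] <- (q_truth[ped$father[i], ] +
                          q_truth[ped$mother[i], ]) / 2
      }
    }
    geno <- hap_genotypes(haps, map, fh_alleles)
    structure(list(ids = ped$id, map = map, chrom_cm = chrom_cm,
                   geno = geno, haps = haps, founder_alleles = fh_alleles,
                   q_truth = q_truth, pedigree = ped),
              class = "sim_cohort")
  })
}

# sites x individuals genotype matrix from haplotype mosaics
hap_genotypes <- function(haps, map, fh_alleles) {
  S <- nrow(map)
  geno <- matrix(0L, S, length(haps), dimnames = list(NULL, names(haps)))
  idx_by_chrom <- split(seq_len(S), map$chrom)
  for (id in names(haps)) {
    g <- integer(S)
    for (h in 1:2) {
      for (ch in names(idx_by_chrom)) {
        idx <- idx_by_chrom[[ch]]
        seg <- haps[[id]][[h]][[ch]]
        anc <- seg$anc[findInterval(map$pos_cm[idx], seg$start)]
        g[idx] <- g[idx] + fh_alleles[cbind(anc, idx)]
      }
    }
    geno[, id] <- g
  }
  geno
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$ids), "individuals,",
      nrow(x$map), "sites,",
      length(x$chrom_cm), "chromosomes (",
      round(sum(unlist(x$chrom_cm))), "cM )\n")
  invisible(x)
}

# ---- IBD truth --------------------------------------------------------

# piecewise IBD state (0/1/2 alleles shared) between two individuals
pair_ibd_intervals <- function(cohort, id1, id2) {
  h1 <- cohort$haps[[id1]]; h2 <- cohort$haps[[id2]]
  if (is.null(h1) || is.null(h2)) stop("unknown individual id")
  out <- vector("list", length(cohort$chrom_cm))
  for (ci in seq_along(cohort$chrom_cm)) {
    ch <- names(cohort$chrom_cm)[ci]
    segs <- list(h1[[1]][[ch]], h1[[2]][[ch]], h2[[1]][[ch]], h2[[2]][[ch]])
    cuts <- sort(unique(c(0, unlist(lapply(segs, `[[`, "start")),
                          cohort$chrom_cm[[ch]])))
    lo <- cuts[-length(cuts)]; hi <- cuts[-1]
    anc <- matrix(vapply(segs, function(s) s$anc[findInterval(lo, s$start)],
                         numeric(length(lo))), ncol = 4L)
    a1 <- anc[, 1]; a2 <- anc[, 2]; b1 <- anc[, 3]; b2 <- anc[, 4]
    m <- ifelse((a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1), 2L,
         ifelse(a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2, 1L, 0L))
    d <- data.frame(chrom = ch, start = lo, end = hi, ibd = m)
    # merge runs of equal state
    n <- nrow(d)
    new <- c(TRUE, d$ibd[-1] != d$ibd[-n])
    out[[ci]] <- data.frame(chrom = ch, start = d$start[new],
                            end = d$end[c(which(new)[-1] - 1L, n)],
                            ibd = d$ibd[new])
  }
  do.call(rbind, out)
}

#' Realized kinship coefficients from simulation truth
#'
#' For each pair, the realized genome fractions in IBD state 0/1/2 are
#' computed from the recorded transmission mosaics; \eqn{\hat\pi} is
#' \eqn{k_1/2 + k_2}.
#'
#' @param cohort a \code{sim_cohort}.
#' @param pairs optional 2-column matrix/data frame of id pairs; default
#'   all pairs.
#' @return data frame \code{id1, id2, k0, k1, k2, pihat}.
#' @export
truth_kinship <- function(cohort, pairs = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(cohort$ids, 2)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }
  total <- sum(unlist(cohort$chrom_cm))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    iv <- pair_ibd_intervals(cohort, pairs[[1]][i], pairs[[2]][i])
    len <- iv$end - iv$start
    k <- vapply(0:2, function(m) sum(len[iv$ibd == m]) / total, 0)
    data.frame(id1 = pairs[[1]][i], id2 = pairs[[2]][i],
               k0 = k[1], k1 = k[2], k2 = k[3],
               pihat = k[2] / 2 + k[3])
  })
  do.call(rbind, out)
}

#' True IBD segments from simulation truth
#'
#' @param cohort a \code{sim_cohort}.
#' @param pairs optional id pairs (default all).
#' @param by_status if \code{TRUE}, segments are split by IBD state with
#'   an \code{ibd} column (1 or 2); if \code{FALSE} (default) segments
#'   with at least one shared allele are merged, mirroring callers that
#'   cannot separate IBD2 from IBD1.
#' @return data frame \code{id1, id2, chrom, start_cm, end_cm, length_cm}
#'   (plus \code{ibd} when \code{by_status}).
#' @export
truth_ibd_segments <- function(cohort, pairs = NULL, by_status = FALSE) {
  if (is.null(pairs)) {
    cmb <- utils::combn(cohort$ids, 2)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    iv <- pair_ibd_intervals(cohort, pairs[[1]][i], pairs[[2]][i])
    if (!by_status) {
      iv$ibd <- as.integer(iv$ibd >= 1L)
      # re-merge adjacent shared runs within chromosome
      parts <- lapply(split(iv, iv$chrom), function(d) {
        n <- nrow(d)
        new <- c(TRUE, d$ibd[-1] != d$ibd[-n])
        data.frame(chrom = d$chrom[new], start = d$start[new],
                   end = d$end[c(which(new)[-1] - 1L, n)],
                   ibd = d$ibd[new])
      })
      iv <- do.call(rbind, parts)
    }
    iv <- iv[iv$ibd >= 1L, , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    d <- data.frame(id1 = pairs[[1]][i], id2 = pairs[[2]][i],
                    chrom = iv$chrom, start_cm = iv$start,
                    end_cm = iv$end, length_cm = iv$end - iv$start)
    if (by_status) d$ibd <- iv$ibd
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id1 = character(), id2 = character(),
                      chrom = character(), start_cm = numeric(),
                      end_cm = numeric(), length_cm = numeric())
  rownames(out) <- NULL
  out
}

# ---- genotype likelihoods --------------------------------------------

#' Read-emission genotype likelihoods
#'
#' Probability of observing \code{n_derived} derived-allele reads out of
#' \code{n_reads} at a site, for each diploid genotype g = 0, 1, 2: a
#' read reports the derived allele with probability
#' \eqn{g/2\,(1-\epsilon) + (1-g/2)\,\epsilon}.
#'
#' @param n_reads,n_derived integer vectors (recycled).
#' @param error per-base error rate in [0, 0.5).
#' @return matrix with 3 columns (g = 0, 1, 2) of unnormalized
#'   likelihoods.
#' @export
read_emission_likelihood <- function(n_reads, n_derived, error) {
  if (error < 0 || error >= 0.5) stop("error must lie in [0, 0.5)")
  p <- c(error, 0.5, 1 - error)
  vapply(1:3, function(g) dbinom(n_derived, n_reads, p[g]),
         numeric(length(n_reads)))
}

#' Emit genotype likelihoods from simulated genotypes
#'
#' Per-site read counts are Poisson(\code{depth}); derived-allele read
#' counts are binomial under the read-emission model with base error
#' \code{error}.  Likelihood triples are normalized to sum to one;
#' zero-read sites are flagged missing and carry the uninformative
#' triple (1/3, 1/3, 1/3).
#'
#' @param cohort a \code{sim_cohort}, or a sites x individuals genotype
#'   matrix (0/1/2) with column names.
#' @param depth mean sequencing depth (x), >= 0.
#' @param error base error rate in [0, 0.5).
#' @param map genetic map (taken from the cohort when omitted).
#' @param seed integer seed.
#' @return a \code{gl_matrix}: list with \code{ids}, \code{map},
#'   \code{gl} (sites x 3 x individuals array), \code{missing}
#'   (sites x individuals logical).
#' @export
emit_genotype_likelihoods <- function(cohort, depth, error = 0.01,
                                      map = NULL, seed = NULL) {
  if (inherits(cohort, "sim_cohort")) {
    geno <- cohort$geno
    map <- map %||% cohort$map
  } else {
    geno <- cohort
    if (is.null(map)) stop("map required when passing a genotype matrix")
  }
  if (depth < 0) stop("depth must be nonnegative")
  if (error < 0 || error >= 0.5) stop("error must lie in [0, 0.5)")
  S <- nrow(geno); ids <- colnames(geno)
  with_seed(seed, {
    gl <- array(NA_real_, c(S, 3, length(ids)),
                dimnames = list(NULL, c("g0", "g1", "g2"), ids))
    missing <- matrix(FALSE, S, length(ids), dimnames = list(NULL, ids))
    p_emit <- c(error, 0.5, 1 - error)
    for (j in seq_along(ids)) {
      n <- rpois(S, depth)
      d <- rbinom(S, n, p_emit[geno[, j] + 1L])
      lik <- read_emission_likelihood(n, d, error)
      lik <- lik / rowSums(lik)
      zero <- n == 0L
      lik[zero, ] <- 1 / 3
      gl[, , j] <- lik
      missing[, j] <- zero
    }
    structure(list(ids = ids, map = map, gl = gl, missing = missing),
              class = "gl_matrix")
  })
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("Genotype likelihoods:", length(x$ids), "individuals x",
      nrow(x$map), "sites;",
      sprintf("%.1f%% sites missing on average\n", 100 * mean(x$missing)))
  invisible(x)
}

# ---- isotopes ---------------------------------------------------------

#' Default isotope simulation parameters
#'
#' Local \eqn{^{87}Sr/^{86}Sr} baseline (mean 0.7090, SD 0.0004, a
#' plausible bioavailable range for a single alluvial locality);
#' nonlocals offset by \code{nonlocal_offset_sd} local SDs.  Collagen of
#' well-preserved samples: \%C ~ N(43, 2) with atomic C/N ~ N(3.2, 0.1)
#' and \%N derived from the two (so preserved samples sit inside the
#' 2.9--3.6 acceptance window); QC failures are degraded to
#' \%C ~ N(8, 2), \%N ~ N(2, 0.8).  Diet groups are named lists of
#' d13C/d15N means (per mil).
#'
#' @return list of parameters accepted by \code{\link{simulate_isotopes}}.
#' @export
isotope_sim_params <- function() {
  list(sr_local_mean = 0.7090, sr_local_sd = 0.0004,
       nonlocal_offset_sd = 10,
       d13C_sd = 0.5, d15N_sd = 0.8,
       diet = list(base = list(d13C = -19.0, d15N = 9.0)),
       pctC_mean = 43, pctC_sd = 2, cn_mean = 3.2, cn_sd = 0.1,
       qc_fail_fraction = 0)
}

#' Simulate isotope records with known truth
#'
#' @param members data frame with \code{id} and optional \code{age_class}
#'   (\code{adult}/\code{nonadult}), \code{sex}, \code{diet_group}
#'   (name into \code{params$diet}), \code{locality}
#'   (\code{local}/\code{nonlocal}).
#' @param params list as \code{\link{isotope_sim_params}}.
#' @param seed integer seed.
#' @return list with \code{records} (isotope CSV-shaped data frame) and
#'   \code{truth} (locality class, diet group, planted QC failure).
#' @export
simulate_isotopes <- function(members, params = isotope_sim_params(),
                              seed = NULL) {
  if (is.null(members) || nrow(members) == 0) stop("empty member list")
  n <- nrow(members)
  age <- members$age_class %||% rep("adult", n)
  sex <- members$sex %||% rep(NA_character_, n)
  group <- members$diet_group %||% rep(names(params$diet)[1], n)
  local <- members$locality %||% rep("local", n)
  if (!all(group %in% names(params$diet)))
    stop("diet_group not found in params$diet")
  with_seed(seed, {
    sr <- rnorm(n, params$sr_local_mean, params$sr_local_sd)
    off <- params$nonlocal_offset_sd * params$sr_local_sd
    nl <- local == "nonlocal"
    sr[nl] <- sr[nl] + sample(c(-1, 1), sum(nl), replace = TRUE) * off
    mus <- do.call(rbind, lapply(params$diet[group], function(g)
      c(g$d13C, g$d15N)))
    d13C <- rnorm(n, mus[, 1], params$d13C_sd)
    d15N <- rnorm(n, mus[, 2], params$d15N_sd)
    fail <- runif(n) < params$qc_fail_fraction
    cn <- rnorm(n, params$cn_mean, params$cn_sd)
    good_c <- pmax(rnorm(n, params$pctC_mean, params$pctC_sd), 1)
    pctC <- ifelse(fail, pmax(rnorm(n, 8, 2), 0.5), good_c)
    pctN <- ifelse(fail, pmax(rnorm(n, 2, 0.8), 0.1),
                   good_c / 12.011 * 14.007 / cn)
    list(records = data.frame(id = members$id, sr_ratio = sr,
                              d13C = d13C, d15N = d15N,
                              pctC = pctC, pctN = pctN,
                              age_class = age, sex = sex,
                              stringsAsFactors = FALSE),
         truth = data.frame(id = members$id, locality = local,
                            diet_group = group, qc_fail = fail,
                            stringsAsFactors = FALSE))
  })
}
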