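#' Per-site likelihoods conditional on IBD state
#'
#' For each site, the probability of the pair's genotype likelihoods
#' given m = 0, 1, 2 alleles shared identical by descent, under
#' Hardy--Weinberg genotype frequencies at derived-allele frequency p:
#' IBD0 factorizes over the two individuals, IBD2 forces equal
#' genotypes, and IBD1 draws one shared allele plus one independent
#' allele each.
#'
#' @param gl_i,gl_j sites x 3 genotype-likelihood matrices.
#' @param p derived-allele frequency per site (clamped to (0, 1)).
#' @return sites x 3 matrix with columns \code{L0}, \code{L1}, \code{L2}.
#' @export
kin_site_likelihoods <- function(gl_i, gl_j, p) {
  p <- clamp_freq(p)
  q <- 1 - p
  hw0 <- q * q; hw1 <- 2 * p * q; hw2 <- p * p
  mi <- gl_i[, 1] * hw0 + gl_i[, 2] * hw1 + gl_i[, 3] * hw2
  mj <- gl_j[, 1] * hw0 + gl_j[, 2] * hw1 + gl_j[, 3] * hw2
  L0 <- mi * mj
  L1 <- q * (gl_i[, 1] * q + gl_i[, 2] * p) * (gl_j[, 1] * q + gl_j[, 2] * p) +
        p * (gl_i[, 2] * q + gl_i[, 3] * p) * (gl_j[, 2] * q + gl_j[, 3] * p)
  L2 <- gl_i[, 1] * gl_j[, 1] * hw0 + gl_i[, 2] * gl_j[, 2] * hw1 +
        gl_i[, 3] * gl_j[, 3] * hw2
  cbind(L0 = L0, L1 = L1, L2 = L2)
}

# all (k0, k1, k2) on the simplex at the given grid step
simplex_grid <- function(step) {
  n <- round(1 / step)
  pts <- expand.grid(i = 0:n, j = 0:n)
  pts <- pts[pts$i + pts$j <= n, ]
  cbind(k0 = pts$i / n, k1 = pts$j / n, k2 = 1 - (pts$i + pts$j) / n)
}

# log-likelihood of each simplex grid row, chunked over sites
kin_grid_loglik <- function(L, grid, chunk = 20000L) {
  ll <- numeric(nrow(grid))
  tg <- t(grid)
  for (i in seq(1L, nrow(L), by = chunk)) {
    idx <- i:min(i + chunk - 1L, nrow(L))
    ll <- ll + colSums(log(L[idx, , drop = FALSE] %*% tg + 1e-300))
  }
  ll
}

# EM refinement on the 3-component site mixture; the log-likelihood is
# concave in k, so this converges to the global maximum from any
# interior start
kin_em <- function(L, k0, tol = 1e-8, maxit = 1000) {
  k <- pmax(k0, 1e-6); k <- k / sum(k)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    w <- sweep(L, 2, k, `*`)
    rs <- rowSums(w) + 1e-300
    ll <- sum(log(rs))
    k <- colSums(w / rs) / nrow(L)
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  list(k = k, loglik = ll)
}

#' Maximum-likelihood pairwise relatedness from genotype likelihoods
#'
#' Maximizes \deqn{L(k) = \prod_s \sum_m k_m L_m(s)} over the
#' (k0, k1, k2) simplex, where \eqn{L_m(s)} integrates both individuals'
#' genotype likelihoods against the conditional genotype-pair
#' distribution given m alleles IBD.  A coarse simplex grid (step
#' \code{grid_step}) is scanned and the best point is refined by EM.
#' Only sites where both individuals carry reads (non-missing genotype
#' likelihoods) inform the fit; their count is reported as
#' \code{n_snps}.
#'
#' @param gl a \code{gl_matrix} holding both individuals, or a sites x 3
#'   matrix for individual i (then pass \code{gl_j}).
#' @param id_i,id_j individual ids within \code{gl}.
#' @param freqs derived-allele frequency vector (one per site), e.g. a
#'   pooled reference-panel column.
#' @param gl_j sites x 3 matrix for individual j when \code{gl} is a
#'   plain matrix.
#' @param missing_i,missing_j optional logical missing masks when plain
#'   matrices are supplied (default: uniform triples count as missing).
#' @param grid_step coarse grid resolution on the simplex.
#' @return a \code{kin_pair}: \code{id1}, \code{id2}, \code{k0},
#'   \code{k1}, \code{k2}, \code{pihat} (= k1/2 + k2), \code{n_snps},
#'   \code{loglik}, \code{estimator}.
#' @export
estimate_relatedness <- function(gl, id_i = NULL, id_j = NULL, freqs,
                                 gl_j = NULL, missing_i = NULL,
                                 missing_j = NULL, grid_step = 0.02) {
  if (inherits(gl, "gl_matrix")) {
    gi <- individual_gl(gl, id_i); gj <- individual_gl(gl, id_j)
    mi <- gl$missing[, id_i]; mj <- gl$missing[, id_j]
  } else {
    gi <- gl; gj <- gl_j
    if (is.null(gj)) stop("supply gl_j when gl is a plain matrix")
    mi <- missing_i %||% (rowSums(abs(gi - 1 / 3) > 1e-12) == 0)
    mj <- missing_j %||% (rowSums(abs(gj - 1 / 3) > 1e-12) == 0)
    id_i <- id_i %||% "i"; id_j <- id_j %||% "j"
  }
  shared <- !mi & !mj
  n_snps <- sum(shared)
  if (n_snps == 0) stop("no shared sites between ", id_i, " and ", id_j)
  L <- kin_site_likelihoods(gi[shared, , drop = FALSE],
                            gj[shared, , drop = FALSE], freqs[shared])
  grid <- simplex_grid(grid_step)
  ll <- kin_grid_loglik(L, grid)
  best <- grid[which.max(ll), ]
  ref <- kin_em(L, 0.99 * best + 0.01 / 3)
  k <- ref$k
  structure(list(id1 = id_i, id2 = id_j,
                 k0 = k[1], k1 = k[2], k2 = k[3],
                 pihat = k[2] / 2 + k[3],
                 n_snps = n_snps, loglik = ref$loglik,
                 estimator = "ml"),
            class = "kin_pair")
}

#' @export
print.kin_pair <- function(x, digits = 3, ...) {
  cat(sprintf("%s -- %s: k = (%.*f, %.*f, %.*f), pi-hat = %.*f, %d SNPs\n",
              x$id1, x$id2, digits, x$k0, digits, x$k1, digits, x$k2,
              digits, x$pihat, x$n_snps))
  invisible(x)
}

as_kin_row <- function(x) {
  data.frame(id1 = x$id1, id2 = x$id2, k0 = x$k0, k1 = x$k1, k2 = x$k2,
             pihat = x$pihat, n_snps = x$n_snps, loglik = x$loglik,
             estimator = x$estimator, stringsAsFactors = FALSE)
}

#' Relatedness for many pairs
#'
#' @param gl a \code{gl_matrix}.
#' @param freqs per-site derived-allele frequencies.
#' @param pairs optional 2-column data frame of id pairs (default: all).
#' @param ... passed to \code{\link{estimate_relatedness}}.
#' @return data frame, one row per pair.
#' @export
estimate_relatedness_all <- function(gl, freqs, pairs = NULL, ...) {
  stopifnot(inherits(gl, "gl_matrix"))
  if (is.null(pairs)) {
    cmb <- utils::combn(gl$ids, 2)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    as_kin_row(estimate_relatedness(gl, pairs[[1]][i], pairs[[2]][i],
                                    freqs, ...)))
  do.call(rbind, rows)
}

#' Drop pairs with too few co-covered SNPs
#'
#' Relatedness estimates from pairs sharing fewer than \code{min_snps}
#' co-covered sites are likely spurious and are disregarded.
#'
#' @param pairs data frame with an \code{n_snps} column.
#' @param min_snps minimum shared-SNP count to retain (default 10,000);
#'   pairs with exactly \code{min_snps} are kept.
#' @return the retained rows; removed rows are attached as
#'   \code{attr(, "removed")}.
#' @export
filter_by_overlap <- function(pairs, min_snps = 10000) {
  keep <- pairs$n_snps >= min_snps
  out <- pairs[keep, , drop = FALSE]
  attr(out, "removed") <- pairs[!keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify relatedness degree from kinship coefficients
#'
#' Power-of-two bins in the KING convention, expressed on the
#' \eqn{\hat\pi = k_1/2 + k_2} scale where the expectation halves per
#' degree (1, 0.5, 0.25, 0.125, ... for duplicate, 1st, 2nd, 3rd):
#' \eqn{\hat\pi > 2^{-1/2}} duplicate/twin; \eqn{(2^{-3/2}, 2^{-1/2}]}
#' first degree, split into parent--offspring (k0 < 0.1) versus sibling
#' (k0 >= 0.1); \eqn{(2^{-5/2}, 2^{-3/2}]} second;
#' \eqn{(2^{-7/2}, 2^{-5/2}]} third; below that unrelated (beyond third
#' degree).  Each cut is the geometric midpoint of adjacent expected
#' values.
#'
#' @param rel a \code{kin_pair}, or a data frame with \code{pihat} and
#'   \code{k0} columns.
#' @return character vector of degree classes.
#' @export
classify_degree <- function(rel) {
  if (inherits(rel, "kin_pair")) rel <- as_kin_row(rel)
  cut1 <- 2^-0.5; cut2 <- 2^-1.5; cut3 <- 2^-2.5; cut4 <- 2^-3.5
  ifelse(rel$pihat > cut1, "duplicate",
  ifelse(rel$pihat > cut2, ifelse(rel$k0 < 0.1, "parent-offspring",
                                  "sibling"),
  ifelse(rel$pihat > cut3, "2nd",
  ifelse(rel$pihat > cut4, "3rd", "unrelated"))))
}

degree_level <- function(degree) {
  lv <- c(duplicate = 0, `parent-offspring` = 1, sibling = 1, `1st` = 1,
          `2nd` = 2, `3rd` = 3, unrelated = 4)
  unname(lv[degree])
}

#' Reconcile relatedness calls across estimators
#'
#' The primary (likelihood-based) call is accepted when at least half of
#' the available secondary estimators agree on the degree -- exactly for
#' first-degree calls, within one level for second/third -- and is
#' otherwise emitted with a discordance flag.  A pair with only the
#' primary call is flagged \code{single-source}.
#'
#' @param calls data frame with \code{id1}, \code{id2},
#'   \code{estimator}, \code{degree} (classes as in
#'   \code{\link{classify_degree}}, or \code{1st}).
#' @param primary name of the primary estimator (default \code{"ml"}).
#' @return data frame of consensus relationships: \code{id1}, \code{id2},
#'   \code{degree}, \code{n_support}, \code{n_secondary}, \code{flag}.
#' @export
reconcile <- function(calls, primary = "ml") {
  stopifnot(all(c("id1", "id2", "estimator", "degree") %in% names(calls)))
  key <- paste(pmin(calls$id1, calls$id2), pmax(calls$id1, calls$id2),
               sep = "\r")
  out <- lapply(split(calls, key), function(d) {
    if (length(unique(paste(pmin(d$id1, d$id2),
                            pmax(d$id1, d$id2)))) != 1)
      stop("conflicting ids within a pair record")
    pri <- d[d$estimator == primary, , drop = FALSE]
    if (nrow(pri) == 0) return(NULL)       # no primary call: not assigned
    sec <- d[d$estimator != primary, , drop = FALSE]
    lv <- degree_level(pri$degree[1])
    flag <- ""
    if (nrow(sec) == 0) {
      flag <- "single-source"
      n_sup <- 0L
    } else {
      slack <- if (lv <= 1) 0 else 1
      n_sup <- sum(abs(degree_level(sec$degree) - lv) <= slack)
      if (n_sup < nrow(sec) / 2) flag <- "discordant"
    }
    data.frame(id1 = pri$id1[1], id2 = pri$id2[1],
               degree = pri$degree[1], n_support = n_sup,
               n_secondary = nrow(sec), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- pedigree assembly ------------------------------------------------

#' Assemble pedigree components from consensus relationships
#'
#' Builds a relationship graph over pairs called third degree or closer;
#' connected components (reported largest first) are the pedigrees.
#' Parent--offspring edges are oriented older to younger when the two
#' age classes differ (adult vs nonadult) and left unoriented otherwise;
#' the generation depth of a component is one plus the longest directed
#' parent--offspring path.  Individuals whose only evidence is beyond
#' third degree are listed separately as distant connections.
#'
#' @param consensus data frame as returned by \code{\link{reconcile}}
#'   (columns \code{id1}, \code{id2}, \code{degree}).
#' @param metadata optional data frame with \code{id}, \code{age_class}
#'   (\code{adult}/\code{nonadult}/\code{unknown}), \code{sex}.
#' @param orientation optional data frame with \code{parent},
#'   \code{child} columns for parent--offspring edges whose direction is
#'   known from external evidence; age-class orientation is added on
#'   top.  An edge oriented both ways is reported and left unoriented.
#' @return a \code{pedigree_graph}: \code{components} summary (id, size,
#'   generation depth, members), \code{edges}, \code{graph} (igraph),
#'   \code{distant} (ids attached only by distant evidence).
#' @export
assemble_pedigrees <- function(consensus, metadata = NULL,
                               orientation = NULL) {
  close_deg <- c("duplicate", "parent-offspring", "sibling", "1st",
                 "2nd", "3rd")
  edges <- consensus[consensus$degree %in% close_deg, , drop = FALSE]
  far <- consensus[!consensus$degree %in% close_deg, , drop = FALSE]
  close_ids <- unique(c(edges$id1, edges$id2))
  distant <- setdiff(unique(c(far$id1, far$id2)), close_ids)

  if (nrow(edges) == 0)
    return(structure(list(components = data.frame(), edges = edges,
                          graph = igraph::make_empty_graph(directed = FALSE),
                          distant = distant),
                     class = "pedigree_graph"))

  # deterministic vertex order regardless of input row order
  verts <- sort(close_ids)
  g <- igraph::graph_from_data_frame(
    edges[order(pmin(edges$id1, edges$id2), pmax(edges$id1, edges$id2)),
          c("id1", "id2", "degree")],
    directed = FALSE, vertices = verts)

  # orient parent-offspring edges by age class
  age <- rep("unknown", length(verts)); names(age) <- verts
  if (!is.null(metadata) && "age_class" %in% names(metadata))
    age[intersect(metadata$id, verts)] <-
      metadata$age_class[match(intersect(metadata$id, verts), metadata$id)]
  po <- edges[edges$degree == "parent-offspring", , drop = FALSE]
  oriented <- orientation
  if (nrow(po)) {
    a1 <- age[po$id1]; a2 <- age[po$id2]
    dir1 <- a1 == "adult" & a2 == "nonadult"
    dir2 <- a1 == "nonadult" & a2 == "adult"
    oriented <- rbind(
      oriented,
      data.frame(parent = po$id1[dir1], child = po$id2[dir1]),
      data.frame(parent = po$id2[dir2], child = po$id1[dir2]))
  }
  if (!is.null(oriented) && nrow(oriented)) {
    key <- paste(oriented$parent, oriented$child, sep = "\r")
    oriented <- oriented[!duplicated(key), , drop = FALSE]
    rev_key <- paste(oriented$child, oriented$parent, sep = "\r")
    both <- paste(oriented$parent, oriented$child, sep = "\r") %in% rev_key
    if (any(both)) {
      warning("orientation contradiction for ",
              sum(both) / 2, " edge(s); left unoriented")
      oriented <- oriented[!both, , drop = FALSE]
    }
  }

  comp <- igraph::components(g)
  member_of <- comp$membership
  cids <- seq_len(comp$no)
  min_member <- vapply(cids, function(cid)
    min(names(member_of)[member_of == cid]), "")
  ord <- cids[order(-comp$csize, min_member)]
  comps <- lapply(seq_along(ord), function(rank) {
    cid <- ord[rank]
    members <- sort(names(member_of)[member_of == cid])
    depth <- component_generation_depth(members, oriented)
    data.frame(component = rank, size = length(members),
               generation_depth = depth,
               members = paste(members, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  structure(list(components = do.call(rbind, comps), edges = edges,
                 oriented = oriented, graph = g, distant = distant),
            class = "pedigree_graph")
}

# 1 + longest directed parent->child path among the component's members
component_generation_depth <- function(members, oriented) {
  if (is.null(oriented) || nrow(oriented) == 0) return(1L)
  o <- oriented[oriented$parent %in% members &
                  oriented$child %in% members, , drop = FALSE]
  if (nrow(o) == 0) return(1L)
  dg <- igraph::graph_from_data_frame(o, directed = TRUE)
  if (!igraph::is_dag(dg)) {
    warning("orientation contradiction: parent-offspring cycle; ",
            "depth computed on the acyclic part")
    return(1L)
  }
  ord <- igraph::topo_sort(dg, mode = "out")
  depth <- stats::setNames(rep(1L, igraph::vcount(dg)),
                           igraph::V(dg)$name)
  for (v in ord$name) {
    kids <- igraph::neighbors(dg, v, mode = "out")$name
    for (k in kids) depth[k] <- max(depth[k], depth[v] + 1L)
  }
  max(depth)
}

#' @export
print.pedigree_graph <- function(x, ...) {
  cat("Pedigree graph:", nrow(x$components), "component(s),",
      nrow(x$edges), "close-degree edge(s)\n")
  if (nrow(x$components))
    print(x$components[, c("component", "size", "generation_depth")],
          row.names = FALSE)
  if (length(x$distant))
    cat("distant-only connections:", paste(x$distant, collapse = ", "),
        "\n")
  invisible(x)
}
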