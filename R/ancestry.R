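#' Supervised admixture log-likelihood
#'
#' \deqn{\ell(q) = \sum_s \log \sum_{g=0}^{2} GL(s,g)\,
#'   \mathrm{Binom}(g; 2, h(s)), \quad h(s) = \sum_k q_k f_k(s)}
#' Missing sites carry uniform likelihood triples and contribute a
#' constant, so they never move the optimum.
#'
#' @param q admixture vector on the simplex (length K).
#' @param gl sites x 3 matrix of normalized genotype likelihoods for one
#'   individual, or a \code{gl_matrix} together with \code{id}.
#' @param panel a \code{ref_panel} or a sites x K frequency matrix.
#' @param id individual id when \code{gl} is a \code{gl_matrix}.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(q, gl, panel, id = NULL) {
  gl <- individual_gl(gl, id)
  freqs <- panel_freqs(panel)
  if (nrow(gl) != nrow(freqs))
    stop("gl and panel must cover the same sites")
  if (length(q) != ncol(freqs))
    stop("q length must match the number of panel populations")
  if (any(q < -1e-9) || abs(sum(q) - 1) > 1e-6)
    stop("q must lie on the simplex")
  q <- pmax(q, 0); q <- q / sum(q)
  admixture_loglik_cpp(gl, freqs, q)
}

individual_gl <- function(gl, id = NULL) {
  if (inherits(gl, "gl_matrix")) {
    if (is.null(id)) {
      if (length(gl$ids) != 1L)
        stop("supply `id` to pick an individual from a gl_matrix")
      id <- gl$ids
    }
    if (!id %in% gl$ids) stop("unknown individual id: ", id)
    return(gl$gl[, , id])
  }
  stopifnot(is.matrix(gl), ncol(gl) == 3)
  gl
}

panel_freqs <- function(panel) {
  f <- if (inherits(panel, "ref_panel")) panel$freqs else panel
  stopifnot(is.matrix(f))
  clamp_freq(f)
}

rdirichlet1 <- function(K) {
  g <- rgamma(K, 1)
  g / sum(g)
}

#' Estimate admixture proportions by maximum likelihood
#'
#' EM with multiple independent restarts: each restart starts from a
#' Dirichlet(1, ..., 1) draw, iterates the allele-allocation EM update
#' until the log-likelihood gain falls below \code{tol} (or
#' \code{maxit}), and the highest-likelihood run is returned.  The
#' default of 50 restarts guards against multimodality when panel
#' populations are weakly differentiated.
#'
#' @inheritParams admixture_loglik
#' @param restarts number of independent EM initializations.
#' @param seed integer seed for the restart draws.
#' @param tol log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations per restart.
#' @param init optional list of starting vectors prepended to the random
#'   restarts (used for warm starts).
#' @return an \code{admix_fit}: admixture vector \code{q}, \code{loglik},
#'   \code{restarts}, \code{converged}, \code{n_sites} (informative).
#' @export
estimate_admixture <- function(gl, panel, restarts = 50, seed = NULL,
                               tol = 1e-6, maxit = 2000, id = NULL,
                               init = NULL) {
  glm1 <- individual_gl(gl, id)
  freqs <- panel_freqs(panel)
  if (nrow(glm1) != nrow(freqs))
    stop("gl and panel must cover the same sites")
  K <- ncol(freqs)
  informative <- rowSums(abs(glm1 - 1 / 3) > 1e-12) > 0
  if (!any(informative)) stop("no informative sites")
  with_seed(seed, {
    starts <- c(init, lapply(seq_len(max(restarts - length(init), 0L)),
                             function(i) rdirichlet1(K)))
    best <- NULL
    for (q0 in starts) {
      fit <- em_admixture_cpp(glm1, freqs, q0, tol, maxit)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    q <- pmax(best$q, 0); q <- q / sum(q)
    names(q) <- colnames(freqs) %||% paste0("POP", seq_len(K))
    structure(list(q = q, loglik = best$loglik,
                   restarts = length(starts),
                   converged = isTRUE(best$converged),
                   iters = best$iters,
                   n_sites = sum(informative)),
              class = "admix_fit")
  })
}

#' @export
print.admix_fit <- function(x, digits = 3, ...) {
  cat("Supervised admixture fit (", x$restarts, " restarts, ",
      x$n_sites, " informative sites)\n", sep = "")
  print(round(x$q, digits))
  cat("log-likelihood:", format(x$loglik), "| converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) object$q

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$q) - 1, class = "logLik")
}

#' Fit admixture for every individual in a likelihood matrix
#'
#' @inheritParams estimate_admixture
#' @param gl a \code{gl_matrix}.
#' @return matrix of admixture vectors (individuals x populations) with
#'   a \code{loglik} attribute.
#' @export
fit_cohort_ancestry <- function(gl, panel, restarts = 50, seed = NULL, ...) {
  stopifnot(inherits(gl, "gl_matrix"))
  seeds <- if (is.null(seed)) rep(list(NULL), length(gl$ids)) else
    as.list(seed + seq_along(gl$ids))
  fits <- lapply(seq_along(gl$ids), function(i)
    estimate_admixture(gl, panel, restarts = restarts,
                       seed = seeds[[i]], id = gl$ids[i], ...))
  q <- do.call(rbind, lapply(fits, coef))
  rownames(q) <- gl$ids
  attr(q, "loglik") <- vapply(fits, function(f) f$loglik, 0)
  q
}

# ---- block bootstrap --------------------------------------------------

# contiguous nonoverlapping blocks of `block_bp` by physical position,
# per chromosome; the final short block is kept as its own block
block_index <- function(map, block_bp) {
  key <- paste(map$chrom, map$pos_bp %/% block_bp, sep = ":")
  match(key, unique(key))
}

#' Block bootstrap for admixture confidence intervals
#'
#' Chromosomes are partitioned into contiguous nonoverlapping blocks of
#' \code{block_bp} (default 10 Mb) by physical position; each replicate
#' draws as many blocks as exist, with replacement, from the pooled
#' block list, concatenates their sites and re-estimates the admixture
#' vector.  Replicate fits warm-start at the point estimate (plus
#' \code{restarts - 1} random restarts), which preserves mode identity
#' across replicates.
#'
#' @param gl a \code{gl_matrix} (one individual, or pass \code{id}).
#' @param panel a \code{ref_panel} or frequency matrix.
#' @param block_bp block size in base pairs.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param restarts EM restarts per replicate (first one warm-started).
#' @param point optional precomputed \code{admix_fit} for the warm start.
#' @param id individual id within \code{gl}.
#' @return an \code{admix_boot}: \code{replicates} (B x K), per-component
#'   \code{sd} and percentile \code{ci} (2.5/97.5\%), the \code{point}
#'   estimate, \code{B}, \code{block_bp}, \code{n_blocks}.
#' @export
block_bootstrap <- function(gl, panel, block_bp = 1e7, B = 100,
                            seed = NULL, restarts = 5, point = NULL,
                            id = NULL) {
  stopifnot(inherits(gl, "gl_matrix"))
  if (B < 2) stop("B must be at least 2")
  glm1 <- individual_gl(gl, id)
  freqs <- panel_freqs(panel)
  blocks <- block_index(gl$map, block_bp)
  n_blocks <- max(blocks)
  if (n_blocks < 2) stop("fewer than 2 blocks; use a smaller block size")
  block_rows <- split(seq_len(nrow(gl$map)), blocks)
  if (is.null(point))
    point <- estimate_admixture(glm1, freqs, restarts = max(restarts, 5),
                                seed = seed)
  with_seed(seed, {
    reps <- matrix(NA_real_, B, length(point$q),
                   dimnames = list(NULL, names(point$q)))
    for (b in seq_len(B)) {
      take <- sample.int(n_blocks, n_blocks, replace = TRUE)
      rows <- unlist(block_rows[take], use.names = FALSE)
      fit <- estimate_admixture(glm1[rows, , drop = FALSE],
                                freqs[rows, , drop = FALSE],
                                restarts = restarts,
                                init = list(unname(point$q)))
      reps[b, ] <- coef(fit)
    }
    ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    structure(list(replicates = reps,
                   sd = apply(reps, 2, sd),
                   ci = t(ci),
                   point = point, B = B, block_bp = block_bp,
                   n_blocks = n_blocks),
              class = "admix_boot")
  })
}

#' @export
print.admix_boot <- function(x, digits = 4, ...) {
  cat("Block bootstrap:", x$B, "replicates over", x$n_blocks,
      sprintf("blocks of %.0f Mb\n", x$block_bp / 1e6))
  tab <- cbind(estimate = x$point$q, sd = x$sd,
               ci_low = x$ci[, 1], ci_high = x$ci[, 2])
  print(round(tab, digits))
  invisible(x)
}

#' Pool admixture components
#'
#' Weakly differentiated panel populations trade ancestry back and forth
#' across restarts and bootstrap replicates, inflating per-component
#' intervals; summing the members of such a pair per replicate removes
#' the label switching and narrows the interval.
#'
#' @param result an \code{admix_boot}.
#' @param pairs list of length-2 character vectors of population names
#'   (optionally named; names label the pooled components).
#' @return data frame with pooled \code{estimate}, \code{sd},
#'   \code{ci_low}, \code{ci_high} per pooled pair.
#' @export
pool_components <- function(result, pairs) {
  stopifnot(inherits(result, "admix_boot"))
  if (!is.list(pairs)) pairs <- list(pairs)
  pops <- colnames(result$replicates)
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    if (!all(pr %in% pops))
      stop("unknown population name: ",
           paste(setdiff(pr, pops), collapse = ", "))
    pooled <- rowSums(result$replicates[, pr, drop = FALSE])
    data.frame(pool = names(pairs)[i] %||% paste(pr, collapse = "+"),
               members = paste(pr, collapse = "+"),
               estimate = sum(result$point$q[pr]),
               sd = sd(pooled),
               ci_low = quantile(pooled, 0.025, names = FALSE),
               ci_high = quantile(pooled, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

#' Congruence correlation between two sets of ancestry estimates
#'
#' Pearson product-moment correlation of a (possibly pooled) ancestry
#' component across individuals, used to compare two estimation methods
#' run on the same cohort.
#'
#' @param estimatesA,estimatesB individuals x populations matrices with
#'   matching rownames (or identical row order).
#' @param component a column name, or several names to pool by summation.
#' @return Pearson's r.
#' @export
congruence_correlation <- function(estimatesA, estimatesB, component) {
  a <- pooled_component(estimatesA, component)
  b <- pooled_component(estimatesB, component)
  if (length(a) != length(b)) stop("estimate sets differ in individuals")
  if (!is.null(rownames(estimatesA)) && !is.null(rownames(estimatesB))) {
    if (!setequal(rownames(estimatesA), rownames(estimatesB)))
      stop("estimate sets cover different individuals")
    b <- b[rownames(estimatesA)]
  }
  if (length(a) < 3) stop("need at least 3 individuals")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in a component; correlation undefined")
  cor(a, b)
}

pooled_component <- function(est, component) {
  est <- as.matrix(est)
  if (!all(component %in% colnames(est)))
    stop("unknown component: ",
         paste(setdiff(component, colnames(est)), collapse = ", "))
  rowSums(est[, component, drop = FALSE])
}
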