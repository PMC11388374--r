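#' Filter IBD segments by minimum length
#'
#' Only segments strictly longer than \code{min_cm} are retained; short
#' segments are both noisier to call at low coverage and more likely to
#' reflect background relatedness than recent common ancestry.
#'
#' @param segments data frame with columns \code{id1}, \code{id2},
#'   \code{chrom}, \code{start_cm}, \code{end_cm}, \code{length_cm}.
#' @param min_cm length threshold in centimorgans (default 12).
#' @return the retained rows.
#' @export
filter_segments <- function(segments, min_cm = 12) {
  if (nrow(segments) == 0) return(segments)
  if (any(segments$length_cm <= 0)) stop("segment lengths must be positive")
  if (any(abs(segments$end_cm - segments$start_cm - segments$length_cm) >
            1e-6))
    stop("segment length must equal end - start")
  out <- segments[segments$length_cm > min_cm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinship-proportion statistic for one pair from its IBD segments
#'
#' \eqn{\hat\pi} is the summed segment length divided by the total
#' genetic map length.  Because segment callers on unphased low-coverage
#' data cannot separate IBD2 from IBD1, known sibling pairs are adjusted
#' to the expected 0.5 regardless of their segment sum.
#'
#' @param segments data frame of segments for a single pair (may be
#'   empty).
#' @param genome_total_cm total genetic length of the genome in cM
#'   (default 3540, a sex-averaged autosomal map).
#' @param known_sibling logical; apply the sibling adjustment.
#' @return adjusted \eqn{\hat\pi}, or \code{NULL} when no segments
#'   survive and the pair is not a known sibling pair (no edge).
#' @export
pair_pihat <- function(segments, genome_total_cm = 3540,
                       known_sibling = FALSE) {
  if (genome_total_cm <= 0) stop("genome_total_cm must be positive")
  if (nrow(segments) > 0 &&
      length(unique(paste(pmin(segments$id1, segments$id2),
                          pmax(segments$id1, segments$id2)))) > 1)
    stop("segments from more than one pair supplied")
  if (known_sibling) return(0.5)
  if (nrow(segments) == 0) return(NULL)
  sum(segments$length_cm) / genome_total_cm
}

#' Pairwise adjusted kinship proportions from a segment table
#'
#' @param segments segment data frame (several pairs), already filtered.
#' @param genome_total_cm total genome length in cM.
#' @param siblings optional 2-column data frame of known sibling pairs.
#' @return data frame \code{id1}, \code{id2}, \code{raw_pihat}.
#' @export
pihat_table <- function(segments, genome_total_cm = 3540,
                        siblings = NULL) {
  sib_key <- character()
  if (!is.null(siblings) && nrow(siblings))
    sib_key <- paste(pmin(siblings[[1]], siblings[[2]]),
                     pmax(siblings[[1]], siblings[[2]]), sep = "\r")
  key <- paste(pmin(segments$id1, segments$id2),
               pmax(segments$id1, segments$id2), sep = "\r")
  rows <- lapply(unique(key), function(k) {
    d <- segments[key == k, , drop = FALSE]
    ph <- pair_pihat(d, genome_total_cm, known_sibling = k %in% sib_key)
    data.frame(id1 = pmin(d$id1[1], d$id2[1]),
               id2 = pmax(d$id1[1], d$id2[1]),
               raw_pihat = ph, stringsAsFactors = FALSE)
  })
  # sibling pairs with no surviving segments still get their 0.5 edge
  missing_sibs <- setdiff(sib_key, unique(key))
  if (length(missing_sibs)) {
    parts <- strsplit(missing_sibs, "\r", fixed = TRUE)
    rows <- c(rows, lapply(parts, function(p)
      data.frame(id1 = p[1], id2 = p[2], raw_pihat = 0.5,
                 stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the IBD-sharing network
#'
#' Nodes are individuals, undirected edges are pairs with at least one
#' surviving IBD segment, weighted by the adjusted \eqn{\hat\pi}.
#' Because raw values span orders of magnitude, edge weights are
#' min--max rescaled to [0, 1]; when all raw weights are equal (or there
#' is a single edge) every weight maps to 1.  Nodes without any edge
#' (degree 0) are excluded by construction.
#'
#' @param pair_pihats data frame \code{id1}, \code{id2},
#'   \code{raw_pihat} as from \code{\link{pihat_table}}.
#' @param annotations optional data frame with \code{id} plus columns to
#'   attach to nodes (site, ancestry class, ...).
#' @return an \code{ibd_network}: \code{graph} (igraph), \code{edges}
#'   (with \code{weight}), \code{nodes}.
#' @export
build_network <- function(pair_pihats, annotations = NULL) {
  if (is.null(pair_pihats) || nrow(pair_pihats) == 0)
    stop("no edges: network requires at least one pair with IBD sharing")
  if (any(pair_pihats$id1 == pair_pihats$id2))
    stop("self-edges are not allowed")
  raw <- pair_pihats$raw_pihat
  rng <- range(raw)
  w <- if (diff(rng) < .Machine$double.eps) rep(1, length(raw)) else
    (raw - rng[1]) / diff(rng)
  edges <- data.frame(id1 = pair_pihats$id1, id2 = pair_pihats$id2,
                      raw_pihat = raw, weight = w,
                      stringsAsFactors = FALSE)
  verts <- sort(unique(c(edges$id1, edges$id2)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  nodes <- data.frame(id = verts,
                      degree = as.integer(igraph::degree(g)[verts]),
                      stringsAsFactors = FALSE)
  if (!is.null(annotations))
    nodes <- merge(nodes, annotations, by = "id", all.x = TRUE,
                   sort = TRUE)
  structure(list(graph = g, edges = edges, nodes = nodes),
            class = "ibd_network")
}

#' Topology summary of an IBD network
#'
#' @param net an \code{ibd_network}.
#' @return list with \code{nodes}, \code{edges}, \code{average_degree}
#'   (defined as 2E/N for an undirected graph).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "ibd_network"))
  n <- nrow(net$nodes); e <- nrow(net$edges)
  list(nodes = n, edges = e, average_degree = 2 * e / n)
}

#' @export
print.ibd_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("IBD network: %d nodes, %d edges, average degree %.2f\n",
              s$nodes, s$edges, s$average_degree))
  invisible(x)
}
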