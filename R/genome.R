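#' Genome layout for simulation and block resampling
#'
#' Defines a scaled-down autosomal genome: a configurable number of
#' chromosomes with a uniform 1 cM/Mb recombination map.  Chromosome
#' lengths decrease roughly linearly, mimicking the human karyotype, and
#' sum to \code{total_cm} (default 3,540 cM, the sex-averaged autosomal
#' map length used as the kinship-proportion denominator).
#'
#' @param n_chrom number of chromosomes (1--22).
#' @param total_cm total genetic map length in centimorgans.
#' @param cm_per_mb recombination rate; physical lengths are derived as
#'   \code{length_cm / cm_per_mb} megabases.
#' @return a \code{genome_layout} data frame with columns \code{chrom},
#'   \code{length_cm}, \code{length_bp}.
#' @export
default_genome <- function(n_chrom = 22, total_cm = 3540, cm_per_mb = 1) {
  stopifnot(n_chrom >= 1, total_cm > 0, cm_per_mb > 0)
  w <- rev(seq_len(n_chrom)) + n_chrom / 2   # linear taper, chr1 longest
  len_cm <- total_cm * w / sum(w)
  out <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_cm = len_cm,
    length_bp = round(len_cm / cm_per_mb * 1e6)
  )
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Place SNP sites on a genome layout
#'
#' Sites are spread evenly along each chromosome (proportionally to its
#' genetic length), giving strictly increasing physical and genetic
#' coordinates within every chromosome.
#'
#' @param genome a \code{genome_layout}.
#' @param S total number of sites.
#' @param cm_per_mb recombination rate used to convert cM to bp.
#' @return a \code{genetic_map} data frame with columns \code{chrom},
#'   \code{pos_bp}, \code{pos_cm}.
#' @export
place_sites <- function(genome, S, cm_per_mb = 1) {
  stopifnot(inherits(genome, "genome_layout"), S >= 1)
  n_per <- pmax(1L, round(S * genome$length_cm / sum(genome$length_cm)))
  # adjust rounding drift on the largest chromosome
  n_per[1] <- n_per[1] + (S - sum(n_per))
  if (n_per[1] < 1L) stop("too few sites for this many chromosomes")
  maps <- lapply(seq_len(nrow(genome)), function(i) {
    k <- n_per[i]
    cm <- genome$length_cm[i] * (seq_len(k) - 0.5) / k
    data.frame(chrom = genome$chrom[i],
               pos_bp = round(cm / cm_per_mb * 1e6) + seq_len(k) %% 2L,
               pos_cm = cm)
  })
  map <- do.call(rbind, maps)
  map$pos_bp <- as.integer(map$pos_bp)
  rownames(map) <- NULL
  map <- validate_genetic_map(map)
  attr(map, "chrom_cm") <- as.list(stats::setNames(genome$length_cm,
                                                   genome$chrom))
  map
}

#' Construct and validate a genetic map
#'
#' @param map data frame with \code{chrom}, \code{pos_bp}, \code{pos_cm}.
#' @return the validated map, classed \code{genetic_map}.
#' @export
validate_genetic_map <- function(map) {
  stopifnot(all(c("chrom", "pos_bp", "pos_cm") %in% names(map)))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    o <- order(m$pos_bp)
    if (any(diff(m$pos_bp[o]) <= 0))
      stop("physical positions must be strictly increasing within ", ch)
    if (any(diff(m$pos_cm[o]) < 0))
      stop("genetic positions must be nondecreasing with bp within ", ch)
  }
  if (total_map_cm(map) <= 0) stop("total map length must be positive")
  class(map) <- unique(c("genetic_map", class(map)))
  map
}

#' Total genetic map length spanned by a map's sites
#' @param map a \code{genetic_map}.
#' @return length in cM (sum over chromosomes of the spanned interval).
#' @export
total_map_cm <- function(map) {
  sum(tapply(map$pos_cm, map$chrom, function(x) max(x) - min(x)))
}
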