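# All writers emit a comment header (version, seed, config hash) and all
# readers skip '#' lines, so every artifact records its provenance.

output_header <- function(seed = NULL, extra = character()) {
  c(paste0("# paleocomm v",
           as.character(utils::packageVersion("paleocomm"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra)
}

write_table_with_header <- function(df, path, header, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
}

#' Read a beagle-style genotype-likelihood file
#'
#' Expected layout: columns \code{marker} (\code{chrom_pos}),
#' \code{allele1}, \code{allele2}, then three likelihood columns per
#' individual.  The \code{linear} dialect carries normalized
#' likelihoods; the \code{phred} dialect carries PL values converted as
#' likelihood \eqn{\propto 10^{-PL/10}} and renormalized per site.
#' Triples that are uniform after normalization are flagged missing.
#' Malformed lines are rejected with their line numbers.
#'
#' @param path file path.
#' @param dialect \code{"linear"} or \code{"phred"}.
#' @param cm_per_mb map rate used to assign genetic coordinates when no
#'   \code{map} is given.
#' @param map optional \code{genetic_map} matching the file's sites.
#' @return a \code{gl_matrix}.
#' @export
read_gl_file <- function(path, dialect = c("linear", "phred"),
                         cm_per_mb = 1, map = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) stop("GL file has no data rows")
  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop("inconsistent column counts on line(s): ",
         paste(lineno[ncols != ncols[1]], collapse = ", "))
  if ((ncols[1] - 3) %% 3 != 0 || ncols[1] < 6)
    stop("expected 3 marker columns plus 3 likelihood columns per ",
         "individual; got ", ncols[1], " columns")
  header <- fields[[1]]
  ids <- unique(header[-(1:3)])
  n_ind <- (ncols[1] - 3) / 3
  if (length(ids) != n_ind)
    stop("header must repeat each individual id three times")
  body <- fields[-1]
  body_line <- lineno[-1]
  mk <- vapply(body, `[`, "", 1)
  num <- matrix(NA_real_, length(body), ncols[1] - 3)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-(1:3)]))
    if (anyNA(v))
      stop("non-numeric likelihood on line ", body_line[i])
    num[i, ] <- v
  }
  if (dialect == "phred") num <- 10^(-num / 10)
  S <- nrow(num)
  gl <- array(NA_real_, c(S, 3, n_ind),
              dimnames = list(NULL, c("g0", "g1", "g2"), ids))
  missing <- matrix(FALSE, S, n_ind, dimnames = list(NULL, ids))
  for (j in seq_len(n_ind)) {
    tri <- num[, (3 * j - 2):(3 * j), drop = FALSE]
    tot <- rowSums(tri)
    if (any(tot <= 0))
      stop("non-positive likelihood triple on line ",
           body_line[which(tot <= 0)[1]])
    tri <- tri / tot
    gl[, , j] <- tri
    missing[, j] <- apply(abs(tri - 1 / 3) < 1e-9, 1, all)
  }
  if (is.null(map)) {
    parts <- strsplit(mk, "_")
    chrom <- vapply(parts, function(p)
      paste(p[-length(p)], collapse = "_"), "")
    pos <- as.integer(vapply(parts, function(p) p[length(p)], ""))
    if (anyNA(pos)) stop("markers must be chrom_pos")
    map <- data.frame(chrom = chrom, pos_bp = pos,
                      pos_cm = pos / 1e6 * cm_per_mb)
    map <- validate_genetic_map(map)
  }
  if (nrow(map) != S) stop("map does not match the file's sites")
  structure(list(ids = ids, map = map, gl = gl, missing = missing),
            class = "gl_matrix")
}

#' Write a beagle-style genotype-likelihood file
#'
#' @param gl a \code{gl_matrix}.
#' @param path output path.
#' @param dialect \code{"linear"} (normalized likelihoods) or
#'   \code{"phred"} (PL = -10 log10 likelihood, 4 decimals).
#' @param seed seed recorded in the file header.
#' @export
write_gl_file <- function(gl, path, dialect = c("linear", "phred"),
                          seed = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gl, "gl_matrix"))
  marker <- paste(gl$map$chrom, gl$map$pos_bp, sep = "_")
  cols <- list(marker = marker, allele1 = rep(0L, nrow(gl$map)),
               allele2 = rep(1L, nrow(gl$map)))
  for (j in seq_along(gl$ids)) {
    tri <- gl$gl[, , j]
    if (dialect == "phred")
      tri <- round(-10 * log10(pmax(tri, 1e-300)), 4)
    for (g in 1:3)
      cols[[paste0("c", j, g)]] <- signif(tri[, g], 8)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  names(df) <- c("marker", "allele1", "allele2",
                 rep(gl$ids, each = 3))
  write_table_with_header(df, path,
                          output_header(seed, paste0("# dialect: ",
                                                     dialect)))
}

#' Write / read a reference-panel frequency table
#'
#' Tab-separated columns: \code{marker}, then one derived-allele
#' frequency column per population.
#'
#' @param panel a \code{ref_panel}.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
write_panel_tsv <- function(panel, path, seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  df <- data.frame(marker = paste(panel$map$chrom, panel$map$pos_bp,
                                  sep = "_"),
                   check.names = FALSE)
  df[panel$pops] <- as.data.frame(panel$freqs)
  write_table_with_header(df, path, output_header(seed))
}

#' @rdname write_panel_tsv
#' @param cm_per_mb map rate for genetic coordinates.
#' @export
read_panel_tsv <- function(path, cm_per_mb = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  parts <- strsplit(df$marker, "_")
  chrom <- vapply(parts, function(p) paste(p[-length(p)], collapse = "_"),
                  "")
  pos <- as.integer(vapply(parts, function(p) p[length(p)], ""))
  map <- validate_genetic_map(
    data.frame(chrom = chrom, pos_bp = pos,
               pos_cm = pos / 1e6 * cm_per_mb))
  freqs <- as.matrix(df[, -1, drop = FALSE])
  structure(list(pops = colnames(freqs), freqs = clamp_freq(freqs),
                 anc_freq = NULL, map = map),
            class = "ref_panel")
}

#' Write / read an IBD segment table
#'
#' Tab-separated: \code{id1}, \code{id2}, \code{chrom},
#' \code{start_cm}, \code{end_cm}, \code{length_cm} (1-based inclusive
#' genetic coordinates).
#'
#' @param segments segment data frame.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
write_ibd_tsv <- function(segments, path, seed = NULL) {
  write_table_with_header(
    segments[, c("id1", "id2", "chrom", "start_cm", "end_cm",
                 "length_cm")],
    path, output_header(seed))
}

#' @rdname write_ibd_tsv
#' @export
read_ibd_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read an isotope record table
#'
#' Comma-separated: \code{id}, \code{sr_ratio}, \code{d13C},
#' \code{d15N}, \code{pctC}, \code{pctN}, \code{age_class}, \code{sex}.
#'
#' @param records isotope data frame.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
write_isotope_csv <- function(records, path, seed = NULL) {
  write_table_with_header(records, path, output_header(seed), sep = ",")
}

#' @rdname write_isotope_csv
#' @export
read_isotope_csv <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
}
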