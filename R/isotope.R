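#' Derive the two-tier local strontium baseline
#'
#' The strict "local center" interval is the nonadult mean plus/minus
#' two SDs: individuals who died before adulthood formed their enamel
#' locally, so their values bound the local signal tightly.  The wider
#' (conservative) interval is the mean plus/minus two SDs of all human
#' values; environmental samples, when supplied, serve as a consistency
#' check on the wider range rather than defining it.  The center is
#' clipped into the wider interval.
#'
#' @param humans data frame with \code{sr_ratio} and \code{age_class}
#'   (\code{adult}/\code{nonadult}).
#' @param environmental optional data frame with \code{sr_ratio}.
#' @return a \code{locality_ranges}: \code{center} and \code{wider}
#'   intervals \code{c(low, high)} plus derivation metadata.
#' @export
derive_locality_ranges <- function(humans, environmental = NULL) {
  sr <- humans$sr_ratio[!is.na(humans$sr_ratio)]
  if (length(sr) < 2) stop("need at least 2 human Sr values")
  nona <- humans$sr_ratio[humans$age_class == "nonadult" &
                            !is.na(humans$sr_ratio)]
  wider <- mean(sr) + c(-2, 2) * sd(sr)
  fallback <- length(nona) < 2
  center <- if (fallback) wider else mean(nona) + c(-2, 2) * sd(nona)
  center <- c(max(center[1], wider[1]), min(center[2], wider[2]))
  n_env <- 0L
  if (!is.null(environmental)) {
    env <- environmental$sr_ratio[!is.na(environmental$sr_ratio)]
    n_env <- length(env)
    if (any(env < wider[1] | env > wider[2]))
      warning("environmental Sr value(s) fall outside the wider human ",
              "range; the local baseline may be too narrow")
  }
  structure(list(center = center, wider = wider,
                 n_nonadults = length(nona), n_humans = length(sr),
                 n_environmental = n_env, center_fallback = fallback),
            class = "locality_ranges")
}

#' @export
print.locality_ranges <- function(x, digits = 5, ...) {
  cat(sprintf("Local Sr baseline (n = %d humans, %d nonadults, %d env)\n",
              x$n_humans, x$n_nonadults, x$n_environmental))
  cat(sprintf("  local center: [%.*f, %.*f]%s\n", digits, x$center[1],
              digits, x$center[2],
              if (x$center_fallback) "  (fallback: too few nonadults)"
              else ""))
  cat(sprintf("  wider local:  [%.*f, %.*f]\n", digits, x$wider[1],
              digits, x$wider[2]))
  invisible(x)
}

#' Classify individuals against the local strontium baseline
#'
#' @param records data frame with \code{sr_ratio} (NA allowed), or a
#'   numeric vector of ratios.
#' @param ranges a \code{locality_ranges}.
#' @return character vector over \code{local_center}, \code{wider_local},
#'   \code{nonlocal}, \code{unknown} (missing ratio).
#' @export
classify_locality <- function(records, ranges) {
  stopifnot(inherits(ranges, "locality_ranges"))
  sr <- if (is.data.frame(records)) records$sr_ratio else records
  ifelse(is.na(sr), "unknown",
  ifelse(sr >= ranges$center[1] & sr <= ranges$center[2], "local_center",
  ifelse(sr >= ranges$wider[1] & sr <= ranges$wider[2], "wider_local",
         "nonlocal")))
}

#' Collagen quality control
#'
#' Collagen is accepted when carbon concentration exceeds 13 weight
#' percent, nitrogen exceeds 4.8 percent, and the atomic C/N ratio
#' \eqn{(\%C / 12.011) / (\%N / 14.007)} lies in [2.9, 3.6] (the
#' standard well-preserved-collagen window).  Failed criteria are
#' listed per sample.
#'
#' @param records data frame with \code{pctC} and \code{pctN}.
#' @return data frame with \code{pass}, \code{cn_atomic} and a
#'   \code{reasons} string (semicolon-separated failed criteria).
#' @export
collagen_qc <- function(records) {
  pctC <- records$pctC; pctN <- records$pctN
  cn <- ifelse(pctN > 0, (pctC / 12.011) / (pctN / 14.007), NA_real_)
  reasons <- character(nrow(records))
  add <- function(reasons, bad, msg)
    ifelse(bad, ifelse(reasons == "", msg, paste(reasons, msg, sep = ";")),
           reasons)
  reasons <- add(reasons, !(pctC > 13), "carbon below 13%")
  reasons <- add(reasons, !(pctN > 4.8), "nitrogen below 4.8%")
  reasons <- add(reasons, pctN <= 0, "undefined ratio")
  reasons <- add(reasons, pctN > 0 & !(cn >= 2.9 & cn <= 3.6),
                 "C/N outside 2.9-3.6")
  out <- data.frame(pass = reasons == "", cn_atomic = cn,
                    reasons = reasons, stringsAsFactors = FALSE)
  if ("id" %in% names(records)) out <- cbind(id = records$id, out)
  out
}

#' Compare an isotope value between two groups
#'
#' Two-sided permutation test on the difference of group means,
#' restricted to QC-passing records.
#'
#' @param records isotope data frame (with the \code{isotope_field}
#'   column and \code{pctC}/\code{pctN} for QC unless \code{qc} is
#'   \code{FALSE}).
#' @param grouping logical or two-level vector aligned with
#'   \code{records}: the two diet groups to compare.
#' @param isotope_field column to compare (e.g. \code{"d13C"}).
#' @param B number of permutations.
#' @param seed integer seed.
#' @param qc apply \code{\link{collagen_qc}} before comparing.
#' @return list with group \code{n}s and means, \code{difference}
#'   (first level minus second), and the permutation \code{p} (withheld,
#'   \code{NA}, when a group has fewer than 2 members).
#' @export
diet_group_compare <- function(records, grouping, isotope_field = "d13C",
                               B = 10000, seed = NULL, qc = TRUE) {
  stopifnot(isotope_field %in% names(records),
            length(grouping) == nrow(records))
  keep <- !is.na(records[[isotope_field]]) & !is.na(grouping)
  if (qc) keep <- keep & collagen_qc(records)$pass
  x <- records[[isotope_field]][keep]
  gr <- factor(grouping[keep])
  if (nlevels(gr) != 2) stop("grouping must have exactly two levels")
  n <- table(gr)
  if (any(n == 0)) stop("both groups must be nonempty")
  means <- tapply(x, gr, mean)
  res <- list(groups = levels(gr), n = as.integer(n),
              means = as.numeric(means),
              difference = unname(means[1] - means[2]),
              p = NA_real_, B = B)
  if (all(n >= 2)) {
    pt <- permutation_test(x, gr, B = B, seed = seed)
    res$p <- pt$p
    res$seed <- pt$seed
  }
  res
}
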