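#' A 24-member, five-generation demonstration pedigree
#'
#' Three intermarrying sibling groups spanning five generations, the
#' scale of extended early-medieval cemetery pedigrees, used by the
#' end-to-end pipeline and recovery tests.  Founders marry in at each
#' generation.
#'
#' @return list with \code{ped} (id/father/mother data frame) and
#'   \code{founders} (ids needing admixture vectors).
#' @export
demo_pedigree <- function() {
  ped <- rbind(
    data.frame(id = c("F1", "M1", "S1", "S2", "T1", "T2", "U1"),
               father = NA_character_, mother = NA_character_),
    data.frame(id = c("C1", "C2", "C3", "C4"),
               father = "F1", mother = "M1"),
    data.frame(id = c("D1", "D2", "D5"), father = "C1", mother = "S1"),
    data.frame(id = c("D3", "D4"), father = "C2", mother = "S2"),
    data.frame(id = c("E1", "E2", "E5"), father = "D1", mother = "T1"),
    data.frame(id = c("E3", "E4"), father = "D3", mother = "T2"),
    data.frame(id = c("G1", "G2", "G3"), father = "E1", mother = "U1"))
  list(ped = ped, founders = c("F1", "M1", "S1", "S2", "T1", "T2", "U1"))
}

#' Pipeline configuration
#'
#' Thresholds default to the standard settings of this analysis class:
#' pairs under 10,000 shared SNPs disregarded, IBD segments over 12 cM
#' retained, 10 Mb bootstrap blocks, 50 EM restarts, a 3,540 cM genome
#' and 10,000 permutations.
#'
#' @param seed master seed; every stochastic stage derives its seed
#'   from it and records it in output headers.
#' @param out_dir output directory (created if needed).
#' @param S number of simulated sites.
#' @param K number of reference populations.
#' @param F_st Balding--Nichols differentiation per population.
#' @param depth mean sequencing depth.
#' @param error base error rate.
#' @param n_unrelated unrelated (non-pedigree) individuals to add.
#' @param min_snps,min_cm,block_mb,restarts,genome_cm,perms thresholds
#'   as above.
#' @param bootstrap_B bootstrap replicates per individual (0 disables
#'   the CI stage, the default for desk-scale runs).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("paleocomm_"),
                            S = 20000, K = 3, F_st = 0.1, depth = 1,
                            error = 0.01, n_unrelated = 16,
                            min_snps = 10000, min_cm = 12,
                            block_mb = 10, restarts = 50,
                            genome_cm = 3540, perms = 10000,
                            bootstrap_B = 0) {
  cfg <- list(seed = seed, out_dir = out_dir, S = S, K = K, F_st = F_st,
              depth = depth, error = error, n_unrelated = n_unrelated,
              min_snps = min_snps, min_cm = min_cm, block_mb = block_mb,
              restarts = restarts, genome_cm = genome_cm, perms = perms,
              bootstrap_B = bootstrap_B)
  thresholds <- c(cfg$min_snps, cfg$min_cm, cfg$block_mb, cfg$restarts,
                  cfg$genome_cm, cfg$perms)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL                 # a location, not a parameter
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ";")
  # small rolling hash; enough to fingerprint a config in file headers
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the synthetic-to-report community reconstruction pipeline
#'
#' Stages run in order: simulate, ancestry, kinship, ibd-net, isotope,
#' mortuary, report.  Each stage writes its outputs (with version, seed
#' and config-hash headers) into \code{config$out_dir} before the next
#' stage starts; a failure aborts with the stage name.  The synthetic
#' cohort couples a five-generation pedigree with unrelated individuals
#' whose admixture, relationships, IBD segments, localities, diets and
#' grave-good assignments are all known, so the report can be checked
#' against truth.
#'
#' @param config a \code{pipeline_config}.
#' @return a \code{community_report} list: ancestry estimates, pedigree
#'   components, network summary, locality classes, diet comparison,
#'   mortuary association, truth, and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  path <- function(f) file.path(config$out_dir, f)
  hdr <- function(seed) output_header(seed, paste0("# config: ", hash))
  stage <- "simulate"
  report <- tryCatch({
    # ---- simulate -----------------------------------------------------
    seed <- config$seed
    panel <- simulate_reference_panel(config$K, config$S, config$F_st,
                                      seed = seed)
    dp <- demo_pedigree()
    extra <- if (config$n_unrelated > 0)
      data.frame(id = sprintf("U%02d", seq_len(config$n_unrelated)),
                 father = NA_character_, mother = NA_character_) else NULL
    ped <- rbind(dp$ped, extra)
    founders <- c(dp$founders, extra$id)
    K <- config$K
    # pedigree founders share one ancestry profile, unrelated
    # individuals another, so ancestry separates the groups
    q_ped <- c(0.7, rep(0.3 / (K - 1), K - 1))
    q_other <- c(rep(0.3 / (K - 1), K - 1), 0.7)
    founder_q <- rbind(
      matrix(rep(q_ped, length(dp$founders)), ncol = K, byrow = TRUE,
             dimnames = list(dp$founders, panel$pops)),
      if (!is.null(extra))
        matrix(rep(q_other, nrow(extra)), ncol = K, byrow = TRUE,
               dimnames = list(extra$id, panel$pops)))
    cohort <- simulate_pedigree_genotypes(panel, ped, founder_q,
                                          seed = seed + 1)
    gl <- emit_genotype_likelihoods(cohort, config$depth, config$error,
                                    seed = seed + 2)
    meta <- data.frame(id = cohort$ids,
                       age_class = ifelse(cohort$ids %in%
                                            c("G1", "G2", "G3"),
                                          "nonadult", "adult"),
                       sex = "unknown", stringsAsFactors = FALSE)
    in_ped <- cohort$ids %in% dp$ped$id
    iso_members <- data.frame(
      id = cohort$ids, age_class = meta$age_class, sex = meta$sex,
      diet_group = ifelse(in_ped, "pedigree", "community"),
      locality = ifelse(cohort$ids %in% c("F1", "S2", "U01", "U02"),
                        "nonlocal", "local"))
    iso_params <- isotope_sim_params()
    iso_params$diet <- list(pedigree = list(d13C = -16.5, d15N = 9.5),
                            community = list(d13C = -19.0, d15N = 9.0))
    iso_params$qc_fail_fraction <- 0.05
    iso <- simulate_isotopes(iso_members, iso_params, seed = seed + 3)
    truth_seg <- truth_ibd_segments(cohort)
    write_gl_file(gl, path("cohort.beagle"), seed = seed)
    write_panel_tsv(panel, path("panel.tsv"), seed = seed)
    write_ibd_tsv(truth_seg, path("ibd_segments.tsv"), seed = seed)
    write_isotope_csv(iso$records, path("isotopes.csv"), seed = seed)

    # ---- ancestry -----------------------------------------------------
    stage <- "ancestry"
    anc <- fit_cohort_ancestry(gl, panel, restarts = config$restarts,
                               seed = seed + 10)
    anc_df <- data.frame(id = rownames(anc), as.data.frame(unclass(anc)),
                         loglik = attr(anc, "loglik"))
    write_table_with_header(anc_df, path("ancestry.tsv"), hdr(seed + 10))
    boot <- NULL
    if (config$bootstrap_B >= 2) {
      boot <- lapply(gl$ids, function(id)
        block_bootstrap(gl, panel, block_bp = config$block_mb * 1e6,
                        B = config$bootstrap_B, seed = seed + 11,
                        id = id))
      names(boot) <- gl$ids
      bt <- do.call(rbind, lapply(gl$ids, function(id)
        data.frame(id = id, component = names(boot[[id]]$sd),
                   sd = boot[[id]]$sd,
                   ci_low = boot[[id]]$ci[, 1],
                   ci_high = boot[[id]]$ci[, 2])))
      write_table_with_header(bt, path("bootstrap.tsv"), hdr(seed + 11))
    }

    # ---- kinship ------------------------------------------------------
    stage <- "kinship"
    pooled_freq <- rowMeans(panel$freqs)
    # coarse scan is enough here: the EM refinement reaches the global
    # optimum of the concave pair likelihood from any interior start
    pairs <- estimate_relatedness_all(gl, pooled_freq, grid_step = 0.1)
    pairs_kept <- filter_by_overlap(pairs, config$min_snps)
    pairs_kept$degree <- classify_degree(pairs_kept)
    calls <- data.frame(id1 = pairs_kept$id1, id2 = pairs_kept$id2,
                        estimator = "ml", degree = pairs_kept$degree)
    consensus <- reconcile(calls)
    pedg <- assemble_pedigrees(consensus, meta)
    write_table_with_header(pairs_kept, path("kinship.tsv"), hdr(seed))
    write_table_with_header(pedg$components, path("pedigrees.csv"),
                            hdr(seed), sep = ",")

    # ---- ibd-net ------------------------------------------------------
    stage <- "ibd-net"
    segs <- filter_segments(read_ibd_tsv(path("ibd_segments.tsv")),
                            config$min_cm)
    sibs <- consensus[consensus$degree == "sibling", c("id1", "id2")]
    net <- NULL
    net_sum <- list(nodes = 0L, edges = 0L, average_degree = NA_real_)
    if (nrow(segs)) {
      net <- build_network(pihat_table(segs, config$genome_cm, sibs))
      net_sum <- network_summary(net)
      write_table_with_header(net$edges, path("network_edges.csv"),
                              hdr(seed), sep = ",")
    }

    # ---- isotope ------------------------------------------------------
    stage <- "isotope"
    rec <- read_isotope_csv(path("isotopes.csv"))
    ranges <- derive_locality_ranges(rec)
    rec$locality <- classify_locality(rec, ranges)
    qc <- collagen_qc(rec)
    rec$qc_pass <- qc$pass
    diet <- diet_group_compare(rec, iso_members$diet_group,
                               "d13C", B = config$perms,
                               seed = seed + 20)
    write_table_with_header(rec, path("isotope_classes.csv"), hdr(seed),
                            sep = ",")

    # ---- mortuary -----------------------------------------------------
    stage <- "mortuary"
    # grave goods planted on pedigree adult males/adults (synthetic truth)
    adult <- meta$age_class == "adult"
    weapons <- in_ped & adult
    comp1 <- strsplit(pedg$components$members[1], ";")[[1]]
    tab <- table(factor(cohort$ids %in% comp1, c(TRUE, FALSE)),
                 factor(weapons, c(TRUE, FALSE)))
    mortuary <- list(table = unclass(tab), cramers_v = cramers_v(tab))

    # ---- report -------------------------------------------------------
    stage <- "report"
    report <- structure(list(
      config = config, config_hash = hash,
      ancestry = anc_df, bootstrap = boot,
      kinship = pairs_kept, pedigrees = pedg,
      network = net_sum,
      locality = data.frame(id = rec$id, class = rec$locality),
      locality_ranges = ranges,
      diet = diet, mortuary = mortuary,
      truth = list(q = cohort$q_truth, pedigree = ped,
                   isotopes = iso$truth, segments = truth_seg),
      files = list.files(config$out_dir, full.names = TRUE)),
      class = "community_report")
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("paleocomm")),
           seed = config$seed, config = config_hash(config),
           n_individuals = length(cohort$ids),
           network = net_sum,
           cramers_v = mortuary$cramers_v,
           diet_p = diet$p),
      path("report.json"), auto_unbox = TRUE, digits = NA)
    report
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE))
  report
}

#' @export
print.community_report <- function(x, ...) {
  cat("Community report (seed ", x$config$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  cat("  individuals:", nrow(x$ancestry), "\n")
  cat("  pedigree components:", nrow(x$pedigrees$components),
      "; largest:", x$pedigrees$components$size[1], "members, depth",
      x$pedigrees$components$generation_depth[1], "\n")
  cat(sprintf("  IBD network: %d nodes / %d edges\n",
              x$network$nodes, x$network$edges))
  cat("  nonlocal individuals:",
      sum(x$locality$class == "nonlocal"), "\n")
  cat(sprintf("  diet contrast p = %.4g; mortuary Cramer's V = %.2f\n",
              x$diet$p, x$mortuary$cramers_v))
  invisible(x)
}
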