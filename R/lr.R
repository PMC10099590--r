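#' Split records into whole and partial datasets for forward validation
#'
#' The whole dataset keeps every record. The partial dataset removes all
#' records of animals born after the cutoff date, plus the own and progeny
#' records of the focal individuals. Focal individuals are the genotyped
#' animals born after the cutoff that have own or progeny phenotypes in the
#' whole data — the young selection candidates whose predictions are
#' validated.
#'
#' @param records Phenotype records with \code{animal_id} (and a response).
#' @param genotyped_ids Genotyped animal ids.
#' @param ped Sorted \code{"pedigree"} (supplies birth dates and
#'   parent-offspring links).
#' @param cutoff_date Cutoff (Date or ISO string); animals born strictly
#'   after it are candidates.
#' @param min_focal,min_share Reporting criteria: at least this many focal
#'   individuals and at least this share of the genotyped cohort (warnings
#'   when unmet, mirroring fallback to trait-specific dates).
#' @return List of class \code{"data_split"}: \code{whole}, \code{partial}
#'   (record data frames), \code{focal_ids}, \code{diagnostics}.
#' @export
split_whole_partial <- function(records, genotyped_ids, ped, cutoff_date,
                                min_focal = 100, min_share = 0.20) {
  cutoff_date <- as.Date(cutoff_date)
  bd <- stats::setNames(ped$birth_date, ped$id)
  if (all(is.na(bd))) stop("pedigree has no birth dates")
  born_after <- names(bd)[!is.na(bd) & bd > cutoff_date]
  parent_of <- rbind(
    data.frame(child = ped$id, parent = ped$sire),
    data.frame(child = ped$id, parent = ped$dam))
  parent_of <- parent_of[!is.na(parent_of$parent), ]
  phen_ids <- unique(records$animal_id)
  progeny_phen <- unique(parent_of$parent[parent_of$child %in% phen_ids])
  has_link <- union(phen_ids, progeny_phen)
  focal <- intersect(intersect(as.character(genotyped_ids), born_after),
                     has_link)
  if (!length(focal)) stop("no focal individuals for cutoff ", cutoff_date)
  # partial removes records of animals born after the cutoff and focal
  # own/progeny records
  late <- records$animal_id %in% born_after
  own <- records$animal_id %in% focal
  prog <- records$animal_id %in%
    parent_of$child[parent_of$parent %in% focal]
  partial <- records[!(late | own | prog), , drop = FALSE]
  share <- length(focal) / length(genotyped_ids)
  if (length(focal) < min_focal)
    warning("only ", length(focal), " focal individuals (< ", min_focal, ")")
  if (share < min_share)
    warning("focal share ", round(share, 3), " below ", min_share)
  structure(list(whole = records, partial = partial, focal_ids = focal,
                 cutoff_date = cutoff_date,
                 diagnostics = list(n_focal = length(focal),
                                    share_of_genotyped = share,
                                    n_whole = nrow(records),
                                    n_partial = nrow(partial))),
            class = "data_split")
}

#' LR-method validation statistics
#'
#' Compares predictions from the whole and partial datasets over the focal
#' individuals: accuracy = cov(w, p) / ((1 - mean F) sigma_u^2) (the printed
#' estimator; an estimate of squared accuracy under LR theory — set
#' \code{sqrt_form = TRUE} for its square root), bias = mean(p) - mean(w)
#' (trait units), and dispersion = cov(w, p)/var(p) - 1 (0 = no inflation).
#' Covariances use the n - 1 denominator.
#'
#' @param ebv_whole,ebv_partial Named vectors of (G)EBV covering the focal
#'   ids.
#' @param focal_ids Ids over which the statistics are computed.
#' @param mean_F Average inbreeding of the focal set.
#' @param sigma2_u Direct additive genetic variance.
#' @param sqrt_form Report the square root of the accuracy estimator.
#' @return List of class \code{"lr_stats"}: accuracy, bias, dispersion,
#'   n_focal, mean_F.
#' @export
lr_statistics <- function(ebv_whole, ebv_partial, focal_ids, mean_F = 0,
                          sigma2_u, sqrt_form = FALSE) {
  focal_ids <- as.character(focal_ids)
  if (length(focal_ids) < 2) stop("need at least 2 focal individuals")
  if (!all(focal_ids %in% names(ebv_whole)) ||
      !all(focal_ids %in% names(ebv_partial)))
    stop("EBV vectors do not cover all focal individuals")
  w <- ebv_whole[focal_ids]
  p <- ebv_partial[focal_ids]
  cwp <- stats::cov(w, p)
  vp <- stats::var(p)
  acc <- cwp / ((1 - mean_F) * sigma2_u)
  if (sqrt_form) acc <- sqrt(max(acc, 0))
  disp <- if (vp > 0) cwp / vp - 1 else NA_real_
  structure(list(accuracy = acc,
                 bias = mean(p) - mean(w),
                 dispersion = disp,
                 dispersion_defined = vp > 0,
                 n_focal = length(focal_ids), mean_F = mean_F),
            class = "lr_stats")
}

#' @export
print.lr_stats <- function(x, ...) {
  cat("LR validation over", x$n_focal, "focal individuals (mean F =",
      format(x$mean_F, digits = 3), ")\n")
  cat("  accuracy  :", format(x$accuracy, digits = 4), "\n")
  cat("  bias      :", format(x$bias, digits = 4), "\n")
  cat("  dispersion:", format(x$dispersion, digits = 4),
      "(0 = no inflation)\n")
  invisible(x)
}

#' Derived genetic parameters from variance components
#'
#' Phenotypic variance and the standard ratios: heritability
#' h2 = sigma_u^2 / sigma_P^2, maternal heritability hm2, the maternal
#' permanent-environment fraction c2, and the animal permanent-environment
#' fraction (repeatability minus h2). Values are reported to 3 decimals.
#'
#' @param vc A [var_comp()].
#' @return Named list: sigma2_p, h2, hm2, c2, pe2 (rounded to 3 decimals).
#' @export
genetic_parameters <- function(vc) {
  sp <- vc$sigma2_u + vc$sigma2_pe + vc$sigma2_m + vc$sigma2_q + vc$sigma2_e
  r3 <- function(x) round(x, 3)
  list(sigma2_p = r3(sp),
       h2 = r3(vc$sigma2_u / sp),
       hm2 = r3(vc$sigma2_m / sp),
       c2 = r3(vc$sigma2_q / sp),
       pe2 = r3(vc$sigma2_pe / sp))
}

#' Enumerate the evaluation scenario grid
#'
#' Deterministic, stably ordered enumeration of predictor scenarios: pedigree
#' A-BLUP first, then SNP-based H-BLUP by descending alpha, then
#' haplotype-based HAP-BLUP by ascending LD threshold and descending alpha.
#' The default grid (alphas 0.95 and 0.50; LD thresholds 0.15, 0.35, 0.50,
#' 0.65, 0.80) has 1 + 2 + 10 = 13 scenarios per trait.
#'
#' @param alphas Blending weights for the genomic scenarios.
#' @param ld_thresholds r^2 thresholds for the haplotype scenarios.
#' @param traits Optional trait vector; when given, the grid is crossed with
#'   traits (78 runs for the six default traits).
#' @return Data frame with scenario_id, predictor, alpha, ld_threshold (and
#'   trait when requested).
#' @export
scenario_grid <- function(alphas = c(0.95, 0.50),
                          ld_thresholds = c(0.15, 0.35, 0.50, 0.65, 0.80),
                          traits = NULL) {
  rows <- list(data.frame(predictor = "A-BLUP", alpha = NA_real_,
                          ld_threshold = NA_real_))
  for (a in sort(alphas, decreasing = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(predictor = "H-BLUP", alpha = a,
                                            ld_threshold = NA_real_)
  for (ld in sort(ld_thresholds))
    for (a in sort(alphas, decreasing = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(predictor = "HAP-BLUP",
                                              alpha = a, ld_threshold = ld)
  grid <- do.call(rbind, rows)
  grid$scenario_id <- paste0(
    grid$predictor,
    ifelse(is.na(grid$ld_threshold), "",
           paste0("-LD", format(grid$ld_threshold, nsmall = 2))),
    ifelse(is.na(grid$alpha), "", paste0("-a", format(grid$alpha, nsmall = 2))))
  grid <- grid[, c("scenario_id", "predictor", "alpha", "ld_threshold")]
  if (!is.null(traits)) {
    grid <- merge(data.frame(trait = traits), grid, by = NULL)
    grid <- grid[order(match(grid$trait, traits),
                       match(grid$scenario_id, unique(grid$scenario_id))), ]
    rownames(grid) <- NULL
  }
  grid
}

#' Run the scenario grid on a data bundle
#'
#' End-to-end evaluation driver: for each trait and scenario it builds the
#' required relationship structure (pedigree-only, SNP genomic, or
#' haplotype pseudo-SNP genomic with the scenario's LD threshold and alpha),
#' fits the whole- and partial-data models, and computes the LR statistics
#' plus the mean whole-data theoretical accuracy over the focal animals.
#'
#' @param grid Scenario data frame from [scenario_grid()] (without traits).
#' @param bundle List with \code{ped}, \code{markers} (phased, QC'd
#'   [marker_set()] of the genotyped cohort), \code{genotyped_ids},
#'   \code{records_by_trait} (named list of corrected-phenotype data frames),
#'   \code{vc_by_trait} (named list of [var_comp()]),
#'   \code{model_by_trait} (named character), \code{cutoff_date}.
#' @param tau,omega H-inverse scaling parameters (default 1).
#' @param window_markers Haploblock window (default 50).
#' @param compute_ta Compute focal-set theoretical accuracies (default TRUE).
#' @param qc_t Thresholds for pseudo-SNP QC, from [qc_thresholds()].
#' @return Data frame: trait, scenario_id, predictor, alpha, ld_threshold,
#'   accuracy, bias, dispersion, mean_ta_whole, n_focal.
#' @export
run_evaluation <- function(grid, bundle, tau = 1, omega = 1,
                           window_markers = 50, compute_ta = TRUE,
                           qc_t = qc_thresholds()) {
  ped <- bundle$ped
  f <- inbreeding(ped)
  a_inv <- nrm_inverse(ped, f = f)
  gids <- as.character(bundle$genotyped_ids)
  a22p <- extract_a22(ped, gids)
  ms <- bundle$markers

  # genomic matrices shared across traits: one per (predictor, ld)
  g_cache <- list()
  get_g <- function(predictor, ld) {
    key <- paste(predictor, ld)
    if (!is.null(g_cache[[key]])) return(g_cache[[key]])
    G <- if (predictor == "H-BLUP") {
      vanraden_g(ms$geno[gids, , drop = FALSE])
    } else {
      part <- build_haploblocks(ms, ld_threshold = ld,
                                window_markers = window_markers)
      enc <- pseudo_snp_encode(ms, part)
      enc <- pseudo_snp_qc(enc, qc_t)
      vanraden_g(enc$merged[gids, , drop = FALSE])
    }
    g_cache[[key]] <<- G
    G
  }

  out <- list()
  for (trait in names(bundle$records_by_trait)) {
    recs <- bundle$records_by_trait[[trait]]
    vc <- bundle$vc_by_trait[[trait]]
    model <- bundle$model_by_trait[[trait]]
    split <- split_whole_partial(recs, gids, ped, bundle$cutoff_date,
                                 min_focal = bundle$min_focal %||% 2,
                                 min_share = bundle$min_share %||% 0)
    focal <- split$focal_ids
    mean_F <- mean(f[focal])
    for (r in seq_len(nrow(grid))) {
      sc <- grid[r, ]
      hinv <- if (sc$predictor == "A-BLUP") NULL else
        h_inverse(a_inv, a22p, get_g(sc$predictor, sc$ld_threshold),
                  alpha = sc$alpha, tau = tau, omega = omega)
      fw <- ssgblup(split$whole, ped, vc, model = model, hinv = hinv,
                    pev_ids = if (compute_ta) focal, a_inv = a_inv, f = f)
      fp <- ssgblup(split$partial, ped, vc, model = model, hinv = hinv,
                    a_inv = a_inv, f = f)
      st <- lr_statistics(fw$u, fp$u, focal, mean_F = mean_F,
                          sigma2_u = vc$sigma2_u)
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, scenario_id = sc$scenario_id,
        predictor = sc$predictor, alpha = sc$alpha,
        ld_threshold = sc$ld_threshold,
        accuracy = st$accuracy, bias = st$bias, dispersion = st$dispersion,
        mean_ta_whole = if (compute_ta) mean(fw$ta) else NA_real_,
        n_focal = st$n_focal)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
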