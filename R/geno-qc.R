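#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test on the heterozygote count given the
#' allele counts (Wigginton, Cutler & Abecasis, 2005). The p-value is the sum
#' of probabilities of all heterozygote counts no more likely than the one
#' observed. Monomorphic markers return p = 1.
#'
#' @param n_aa Count of reference-homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of alternate-homozygotes.
#' @param midp Use the mid-p correction (default FALSE, matching common
#'   genotype-QC practice).
#' @return Exact p-value in (0, 1].
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("empty genotype counts")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # P(n_ab = h | n_a, n) up to a constant:
  # n! / (n_aa! n_ab! n_bb!) * 2^n_ab  with n_aa=(n_a-h)/2 etc.
  logp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - rare - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  if (!length(obs)) stop("heterozygote count incompatible with allele counts")
  pv <- sum(p[p <= p[obs] * (1 + 1e-12)])
  if (midp) pv <- pv - 0.5 * p[obs]
  min(1, pv)
}

#' Default genotype quality-control thresholds
#'
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param marker_call_min Minimum marker call rate (default 0.90).
#' @param sample_call_min Minimum sample call rate (default 0.90).
#' @param hwe_p_min Hardy-Weinberg exact-test p-value floor (default 1e-8).
#' @param autosomes Chromosome labels retained (default \code{as.character(1:26)},
#'   the ovine autosomes); set NULL to keep all.
#' @param drop_duplicates Drop markers duplicated at the same chrom+pos.
#' @return List of thresholds used by [snp_qc()] and [pseudo_snp_qc()].
#' @export
qc_thresholds <- function(maf_min = 0.05, marker_call_min = 0.90,
                          sample_call_min = 0.90, hwe_p_min = 1e-8,
                          autosomes = as.character(1:26),
                          drop_duplicates = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 1, marker_call_min >= 0,
            marker_call_min <= 1, sample_call_min >= 0, sample_call_min <= 1)
  list(maf_min = maf_min, marker_call_min = marker_call_min,
       sample_call_min = sample_call_min, hwe_p_min = hwe_p_min,
       autosomes = autosomes, drop_duplicates = drop_duplicates)
}

#' Marker and sample quality control
#'
#' Applies the filters in a fixed order: non-autosomal markers, duplicated
#' positions, sample call rate, marker call rate, minor-allele frequency, and
#' the exact Hardy-Weinberg test. Allele frequencies are recomputed on the
#' surviving samples.
#'
#' @param ms A [marker_set()].
#' @param t Thresholds from [qc_thresholds()].
#' @return List with \code{markers} (the filtered [marker_set()]) and
#'   \code{report} (named removal counts per filter, plus survivors).
#' @export
snp_qc <- function(ms, t = qc_thresholds()) {
  report <- c(non_autosomal = 0L, duplicate_pos = 0L, sample_call = 0L,
              marker_call = 0L, maf = 0L, hwe = 0L)
  keep_m <- rep(TRUE, nrow(ms$map))
  if (!is.null(t$autosomes)) {
    bad <- !(ms$map$chrom %in% t$autosomes)
    report["non_autosomal"] <- sum(bad)
    keep_m[bad] <- FALSE
  }
  if (isTRUE(t$drop_duplicates)) {
    key <- paste(ms$map$chrom, ms$map$pos)
    bad <- duplicated(key) & keep_m
    report["duplicate_pos"] <- sum(bad)
    keep_m[bad] <- FALSE
  }
  g <- ms$geno[, keep_m, drop = FALSE]
  sample_cr <- rowMeans(!is.na(g))
  keep_s <- sample_cr >= t$sample_call_min
  report["sample_call"] <- sum(!keep_s)
  g <- g[keep_s, , drop = FALSE]

  idx_m <- which(keep_m)
  call_rate <- colMeans(!is.na(g))
  drop <- call_rate < t$marker_call_min
  report["marker_call"] <- sum(drop)
  keep_m[idx_m[drop]] <- FALSE
  g <- g[, !drop, drop = FALSE]
  idx_m <- idx_m[!drop]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- is.na(maf) | maf < t$maf_min
  report["maf"] <- sum(drop)
  keep_m[idx_m[drop]] <- FALSE
  g <- g[, !drop, drop = FALSE]
  idx_m <- idx_m[!drop]

  if (ncol(g)) {
    hwe_p <- vapply(seq_len(ncol(g)), function(j) {
      gj <- g[, j]
      hwe_test(sum(gj == 2, na.rm = TRUE), sum(gj == 1, na.rm = TRUE),
               sum(gj == 0, na.rm = TRUE))
    }, numeric(1))
    drop <- hwe_p < t$hwe_p_min
    report["hwe"] <- sum(drop)
    keep_m[idx_m[drop]] <- FALSE
  }
  if (!any(keep_m)) stop("all markers removed by quality control")
  out <- subset_markers(ms, which(keep_m), which(keep_s))
  list(markers = out,
       report = c(as.list(report),
                  list(markers_retained = sum(keep_m),
                       samples_retained = sum(keep_s))))
}
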