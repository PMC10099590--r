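#' Linkage disequilibrium r-squared from phased haplotypes
#'
#' Computes r^2 = D^2 / (pA pa pB pb) with haplotype frequencies counted
#' directly from the phased haplotype matrices (Hill-Robertson metric).
#' Haplotypes with a missing allele at either marker are dropped pairwise.
#'
#' @param ms A phased [marker_set()].
#' @param i,j Marker indices (same chromosome).
#' @return r^2 in [0, 1]; 0 with attribute \code{"monomorphic" = TRUE} when
#'   either marker has no variation among the counted haplotypes.
#' @export
ld_r2 <- function(ms, i, j) {
  if (!ms$phased) stop("ld_r2 requires phased haplotypes")
  if (ms$map$chrom[i] != ms$map$chrom[j])
    stop("markers on different chromosomes")
  a <- c(ms$hap1[, i], ms$hap2[, i])
  b <- c(ms$hap1[, j], ms$hap2[, j])
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pA <- mean(a); pB <- mean(b)
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(structure(0, monomorphic = TRUE))
  D <- mean(a * b) - pA * pB
  min(1, D * D / den)
}

# pairwise r^2 among a set of markers on one chromosome (haplotypes in
# columns of H = rbind over the two phases); vectorised via crossprod
ld_r2_matrix <- function(ms, idx) {
  H <- rbind(ms$hap1[, idx, drop = FALSE], ms$hap2[, idx, drop = FALSE])
  if (anyNA(H)) {
    k <- length(idx)
    out <- matrix(NA_real_, k, k)
    for (a in seq_len(k)) for (b in a:k) {
      out[a, b] <- out[b, a] <- as.numeric(ld_r2(ms, idx[a], idx[b]))
    }
    return(out)
  }
  n <- nrow(H)
  p <- colMeans(H)
  Dm <- crossprod(H) / n - tcrossprod(p)
  den <- tcrossprod(sqrt(p * (1 - p)))
  out <- (Dm / den)^2
  out[den == 0] <- 0
  pmin(out, 1)
}

#' Partition markers into LD haploblocks
#'
#' Greedy contiguous clustering per chromosome: a block is seeded at the
#' leftmost unassigned adjacent marker pair with r^2 at or above the
#' threshold, then extended rightwards while the candidate marker's mean r^2
#' with the current block members stays at or above the threshold and the
#' block holds at most \code{window_markers} markers. Markers in no block are
#' returned as non-clustered SNP (NCSNP). The procedure is deterministic
#' (leftmost-first).
#'
#' @param ms A phased, quality-controlled [marker_set()].
#' @param ld_threshold r^2 threshold in (0, 1]; the study grid uses 0.15,
#'   0.35, 0.50, 0.65 and 0.80.
#' @param window_markers Maximum markers per block (default 50); r^2 is only
#'   evaluated within this window.
#' @return Object of class \code{"haploblocks"}: list with \code{blocks}
#'   (list of integer marker-index vectors, each >= 2 contiguous markers on
#'   one chromosome), \code{ncsnp} (integer indices), \code{ld_threshold}.
#' @export
build_haploblocks <- function(ms, ld_threshold, window_markers = 50) {
  if (!is.numeric(ld_threshold) || ld_threshold <= 0 || ld_threshold > 1)
    stop("ld_threshold must be in (0, 1]")
  if (!ms$phased) stop("haploblock construction requires phased haplotypes")
  blocks <- list()
  assigned <- rep(FALSE, nrow(ms$map))
  for (ch in unique(ms$map$chrom)) {
    idx <- which(ms$map$chrom == ch)
    k <- length(idx)
    if (k < 2) next
    R <- ld_r2_matrix(ms, idx)
    pos <- 1L
    while (pos < k) {
      if (R[pos, pos + 1L] >= ld_threshold) {
        block <- c(pos, pos + 1L)
        nxt <- pos + 2L
        while (nxt <= k && length(block) < window_markers &&
               mean(R[block, nxt]) >= ld_threshold) {
          block <- c(block, nxt)
          nxt <- nxt + 1L
        }
        blocks[[length(blocks) + 1L]] <- idx[block]
        assigned[idx[block]] <- TRUE
        pos <- nxt
      } else {
        pos <- pos + 1L
      }
    }
  }
  structure(list(blocks = blocks, ncsnp = which(!assigned),
                 ld_threshold = ld_threshold,
                 window_markers = window_markers),
            class = "haploblocks")
}

#' @export
print.haploblocks <- function(x, ...) {
  in_blocks <- sum(lengths(x$blocks))
  cat("haploblocks: ", length(x$blocks), " blocks (", in_blocks,
      " markers), ", length(x$ncsnp), " non-clustered SNP; r2 >= ",
      x$ld_threshold, "\n", sep = "")
  invisible(x)
}

#' Encode haplotype-block alleles as pseudo-SNP
#'
#' Within each block, every distinct haplotype allele (the string of phased
#' alleles across the block's markers) observed in the population becomes one
#' pseudo-SNP column, coded 0/1/2 as the number of copies the individual
#' carries. The merged output matrix holds the non-clustered SNP dosage
#' columns plus the pseudo-SNP columns, ordered along the genome (block
#' columns by descending allele frequency within block). Individuals with
#' missing phase inside a block get NA for all of that block's columns.
#'
#' @param ms A phased [marker_set()].
#' @param partition A \code{"haploblocks"} object from [build_haploblocks()].
#' @return List with \code{merged} (individuals x columns dosage matrix),
#'   \code{col_info} (data frame: column name, type \code{"snp"}/\code{"ps"},
#'   chrom, pos, block id, allele string, frequency), \code{n_ps} columns.
#' @export
pseudo_snp_encode <- function(ms, partition) {
  stopifnot(inherits(partition, "haploblocks"))
  pieces <- list()
  info <- list()
  # genome ordering key: position of first marker of the block / the SNP
  entries <- c(
    lapply(partition$ncsnp, function(j) list(type = "snp", idx = j, key = j)),
    lapply(seq_along(partition$blocks), function(b)
      list(type = "block", idx = partition$blocks[[b]], b = b,
           key = partition$blocks[[b]][1]))
  )
  entries <- entries[order(vapply(entries, `[[`, numeric(1), "key"))]
  for (e in entries) {
    if (e$type == "snp") {
      j <- e$idx
      pieces[[length(pieces) + 1L]] <- ms$geno[, j, drop = FALSE]
      info[[length(info) + 1L]] <- data.frame(
        name = ms$map$name[j], type = "snp", chrom = ms$map$chrom[j],
        pos = ms$map$pos[j], block = NA_integer_, allele = NA_character_,
        freq = mean(ms$geno[, j], na.rm = TRUE) / 2)
    } else {
      j <- e$idx
      h1 <- ms$hap1[, j, drop = FALSE]
      h2 <- ms$hap2[, j, drop = FALSE]
      ok1 <- rowSums(is.na(h1)) == 0
      ok2 <- rowSums(is.na(h2)) == 0
      s1 <- ifelse(ok1, apply(h1, 1, paste0, collapse = ""), NA)
      s2 <- ifelse(ok2, apply(h2, 1, paste0, collapse = ""), NA)
      tab <- sort(table(c(s1[ok1], s2[ok2])), decreasing = TRUE)
      alleles <- names(tab)
      freq <- as.numeric(tab) / sum(tab)
      cols <- matrix(NA_integer_, length(ms$ids), length(alleles))
      full <- ok1 & ok2
      for (a in seq_along(alleles))
        cols[full, a] <- (s1[full] == alleles[a]) + (s2[full] == alleles[a])
      colnames(cols) <- paste0("blk", e$b, "_", alleles)
      pieces[[length(pieces) + 1L]] <- cols
      info[[length(info) + 1L]] <- data.frame(
        name = colnames(cols), type = "ps", chrom = ms$map$chrom[j[1]],
        pos = ms$map$pos[j[1]], block = e$b, allele = alleles, freq = freq)
    }
  }
  merged <- do.call(cbind, pieces)
  col_info <- do.call(rbind, info)
  rownames(merged) <- ms$ids
  colnames(merged) <- col_info$name
  list(merged = merged, col_info = col_info,
       n_ps = sum(col_info$type == "ps"))
}

#' Quality control on the merged pseudo-SNP matrix
#'
#' Applies the MAF, call-rate and Hardy-Weinberg filters to the pseudo-SNP
#' columns exactly as [snp_qc()] applies them to SNP; non-clustered SNP
#' columns pass through untouched (they were already quality controlled).
#'
#' @param encoded Output of [pseudo_snp_encode()].
#' @param t Thresholds from [qc_thresholds()].
#' @return Same shape as \code{encoded}, plus a \code{report} element with
#'   pseudo-SNP counts before and after.
#' @export
pseudo_snp_qc <- function(encoded, t = qc_thresholds()) {
  ci <- encoded$col_info
  m <- encoded$merged
  is_ps <- ci$type == "ps"
  keep <- rep(TRUE, ncol(m))
  for (j in which(is_ps)) {
    col <- m[, j]
    cr <- mean(!is.na(col))
    if (cr < t$marker_call_min) { keep[j] <- FALSE; next }
    p <- mean(col, na.rm = TRUE) / 2
    if (is.na(p) || min(p, 1 - p) < t$maf_min) { keep[j] <- FALSE; next }
    pv <- hwe_test(sum(col == 2, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
                   sum(col == 0, na.rm = TRUE))
    if (pv < t$hwe_p_min) keep[j] <- FALSE
  }
  list(merged = m[, keep, drop = FALSE],
       col_info = ci[keep, , drop = FALSE],
       n_ps = sum(is_ps & keep),
       report = list(ps_before = sum(is_ps), ps_after = sum(is_ps & keep),
                     total_before = ncol(m), total_after = sum(keep)))
}
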