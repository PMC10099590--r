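#' VanRaden genomic relationship matrix
#'
#' G = M M' / (2 sum p_i (1 - p_i)) where M is the 0/1/2 dosage matrix centred
#' columnwise by twice the reference-allele frequency. Missing dosages become
#' 0 after centring (mean imputation).
#'
#' @param dosage Individuals x markers matrix of 0/1/2/NA reference-allele
#'   counts (a plain matrix, e.g. \code{ms$geno} or a merged pseudo-SNP
#'   matrix).
#' @param freqs Optional per-marker reference-allele frequencies; by default
#'   observed frequencies within the genotyped set.
#' @return List of class \code{"g_matrix"}: \code{values} (symmetric dense
#'   matrix with individual ids as dimnames), \code{freqs}, \code{denom},
#'   \code{n_markers}.
#' @export
vanraden_g <- function(dosage, freqs = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2) stop("need at least 2 genotyped individuals")
  if (is.null(freqs)) freqs <- colMeans(dosage, na.rm = TRUE) / 2
  freqs[is.na(freqs)] <- 0
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  M <- sweep(dosage, 2, 2 * freqs)
  M[is.na(M)] <- 0
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(dosage), rownames(dosage))
  structure(list(values = G, freqs = freqs, denom = denom,
                 n_markers = ncol(dosage)),
            class = "g_matrix")
}

#' @export
print.g_matrix <- function(x, ...) {
  cat("VanRaden G:", nrow(x$values), "individuals,", x$n_markers,
      "markers; mean diag =", round(mean(diag(x$values)), 4), "\n")
  invisible(x)
}

#' Blend the genomic and pedigree relationship matrices
#'
#' Gw = alpha G + (1 - alpha) A22, the convex combination that restores
#' residual polygenic signal and guarantees invertibility.
#'
#' @param G A \code{"g_matrix"} from [vanraden_g()] (or a plain matrix).
#' @param a22 Pedigree relationships among the genotyped animals, in the same
#'   id order.
#' @param alpha Weight on G in [0, 1]; the study uses 0.95 and 0.50.
#' @return Dense symmetric matrix with a \code{"condition"} attribute (2-norm
#'   condition number estimate).
#' @export
blend_g <- function(G, a22, alpha = 0.95) {
  stopifnot(alpha >= 0, alpha <= 1)
  Gv <- if (inherits(G, "g_matrix")) G$values else as.matrix(G)
  a22 <- as.matrix(a22)
  if (!is.null(rownames(Gv)) && !is.null(rownames(a22)) &&
      !identical(rownames(Gv), rownames(a22)))
    stop("id order of G and A22 differ")
  if (!all(dim(Gv) == dim(a22))) stop("G and A22 dimensions differ")
  Gw <- alpha * Gv + (1 - alpha) * a22
  attr(Gw, "alpha") <- alpha
  attr(Gw, "condition") <- kappa(Gw, exact = FALSE)
  Gw
}

#' Single-step H-inverse in its two-part form
#'
#' Builds the inverse relationship matrix of single-step GBLUP,
#' H^-1 = A^-1 + [0 0; 0 tau (alpha G + beta A22)^-1 - omega A22^-1],
#' keeping A^-1 sparse over all animals and the correction dense over the
#' genotyped block only. Dense H over all animals is never formed.
#'
#' @param a_inv Sparse A^-1 over the full pedigree (from [nrm_inverse()]).
#' @param a22_parts List with \code{a22} and \code{a22_inv} (from
#'   [extract_a22()]).
#' @param G A \code{"g_matrix"} (or matrix) over the same genotyped ids, or
#'   NULL with \code{alpha = 0}.
#' @param alpha,tau,omega Blending and scaling parameters; defaults
#'   \code{tau = omega = 1} as in standard single-step software.
#' @return Object of class \code{"h_inverse"}: \code{a_inv}, \code{correction}
#'   (dense genotyped block), \code{genotyped} (ids), \code{idx} (positions of
#'   genotyped animals in the pedigree order), parameters.
#' @export
h_inverse <- function(a_inv, a22_parts, G, alpha = 0.95, tau = 1, omega = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  ids_all <- rownames(a_inv)
  gids <- rownames(a22_parts$a22)
  idx <- match(gids, ids_all)
  if (anyNA(idx)) stop("genotyped ids missing from A-inverse")
  if (alpha == 0) {
    Gw_inv <- a22_parts$a22_inv
  } else {
    Gv <- if (inherits(G, "g_matrix")) G$values else as.matrix(G)
    Gw <- alpha * Gv + (1 - alpha) * a22_parts$a22
    Gw_inv <- tryCatch(solve(Gw), error = function(e)
      stop("blended genomic matrix is singular; increase beta ",
           "(lower alpha): ", conditionMessage(e)))
  }
  correction <- tau * Gw_inv - omega * a22_parts$a22_inv
  correction <- (correction + t(correction)) / 2
  dimnames(correction) <- list(gids, gids)
  structure(list(a_inv = a_inv, correction = correction, genotyped = gids,
                 idx = idx, alpha = alpha, tau = tau, omega = omega),
            class = "h_inverse")
}

#' @export
print.h_inverse <- function(x, ...) {
  cat("H-inverse:", nrow(x$a_inv), "animals,", length(x$genotyped),
      "genotyped; alpha =", x$alpha, "tau =", x$tau, "omega =", x$omega, "\n")
  invisible(x)
}

# full sparse matrix A^-1 + correction placed on the genotyped block
hinv_sparse <- function(h) {
  n <- nrow(h$a_inv)
  k <- length(h$idx)
  corr <- Matrix::sparseMatrix(
    i = rep(h$idx, each = k), j = rep(h$idx, k),
    x = as.numeric(t(h$correction)), dims = c(n, n),
    dimnames = dimnames(h$a_inv))
  Matrix::forceSymmetric(h$a_inv + corr)
}

#' Multiply the H-inverse by a vector without densifying
#'
#' @param h An \code{"h_inverse"}.
#' @param v Numeric vector over all pedigree animals (pedigree order).
#' @return Numeric vector H^-1 v.
#' @export
hinv_matvec <- function(h, v) {
  out <- as.numeric(h$a_inv %*% v)
  out[h$idx] <- out[h$idx] + as.numeric(h$correction %*% v[h$idx])
  out
}
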