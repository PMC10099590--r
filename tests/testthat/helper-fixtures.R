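# shared fixtures and independent oracles for the test suite

# 5-animal full-sib toy: 1,2 founders; 3 and 4 full sibs; 5 = 3 x 4
fullsib_ped <- function() {
  as_pedigree(data.frame(
    id = as.character(1:5),
    sire = c(NA, NA, "1", "1", "3"),
    dam = c(NA, NA, "2", "2", "4"),
    birth_date = as.Date("2000-01-01") + c(0, 0, 400, 400, 800),
    stringsAsFactors = FALSE))
}

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders carry unique alleles, inheritance is simulated `reps` times, and
# A_ij is estimated as twice the average probability that random alleles from
# i and j are identical by descent (diagonal: 1 + P(the two alleles of i are
# IBD)). Independent of the tabular recursion it checks.
gene_drop_A <- function(ped, reps = 1e5) {
  pc <- ssgblup:::ped_codes(ped)
  n <- length(pc$ids)
  a1 <- matrix(0L, n, reps)
  a2 <- matrix(0L, n, reps)
  allele <- 0L
  for (i in seq_len(n)) {
    s <- pc$s[i]; d <- pc$d[i]
    if (s == 0L) {
      allele <- allele + 1L
      a1[i, ] <- allele
    } else {
      pick <- stats::runif(reps) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    }
    if (d == 0L) {
      allele <- allele + 1L
      a2[i, ] <- allele
    } else {
      pick <- stats::runif(reps) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(pc$ids, pc$ids))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
    } else {
      ibd <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
        (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      A[i, j] <- A[j, i] <- 2 * mean(ibd) / 4
    }
  }
  A
}

# phased marker set from explicit haplotype matrices (rows = individuals)
phased_ms <- function(h1, h2, chrom = NULL, pos = NULL) {
  m <- ncol(h1)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  marker_set(h1 + h2,
             data.frame(name = paste0("m", seq_len(m)), chrom = chrom,
                        pos = pos),
             ids = rownames(h1) %||% paste0("i", seq_len(nrow(h1))),
             hap1 = h1, hap2 = h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense generalized-least-squares oracle for the animal models: builds V from
# the covariance structure and computes BLUE/BLUP directly, independent of
# the MME assembly it checks.
gls_blup <- function(ped, records, vc, model = "additive",
                     value_col = "value", K = NULL) {
  A <- build_nrm(ped)
  ids <- ped$id
  if (is.null(K)) K <- A
  if (model == "maternal") {
    dam_of <- stats::setNames(ped$dam, ped$id)
    keep <- !is.na(dam_of[records$animal_id])
    records <- records[keep, , drop = FALSE]
  }
  y <- records[[value_col]]
  nrec <- length(y)
  Z <- matrix(0, nrec, length(ids), dimnames = list(NULL, ids))
  Z[cbind(seq_len(nrec), match(records$animal_id, ids))] <- 1
  X <- matrix(1, nrec, 1)
  V <- vc$sigma2_u * Z %*% K %*% t(Z) + vc$sigma2_e * diag(nrec)
  extra <- list()
  if (model == "repeatability") {
    W <- Z  # one pe level per animal with records; Z already maps records
    V <- V + vc$sigma2_pe * W %*% t(W)
    extra$W <- W
  }
  if (model == "maternal") {
    dam <- stats::setNames(ped$dam, ped$id)[records$animal_id]
    Z2 <- matrix(0, nrec, length(ids), dimnames = list(NULL, ids))
    Z2[cbind(seq_len(nrec), match(dam, ids))] <- 1
    V <- V + vc$sigma2_m * Z2 %*% A %*% t(Z2) + vc$sigma2_q * Z2 %*% t(Z2)
    extra$Z2 <- Z2
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u <- as.numeric(vc$sigma2_u * K %*% t(Z) %*% Vi %*% r)
  names(u) <- ids
  out <- list(mu = as.numeric(beta), u = u)
  if (model == "maternal") {
    out$m <- as.numeric(vc$sigma2_m * A %*% t(extra$Z2) %*% Vi %*% r)
    names(out$m) <- ids
  }
  out
}

# dense single-step H oracle: replace the genotyped block of A by Gw using
# the conditional-multivariate-normal identity, then invert numerically.
# Independent of the sparse two-part construction it checks.
dense_h <- function(A, gids, Gw) {
  ids <- rownames(A)
  g <- match(gids, ids)
  p <- setdiff(seq_along(ids), g)
  A22 <- A[g, g, drop = FALSE]
  A22i <- solve(A22)
  D <- Gw - A22
  H <- A
  H[p, p] <- A[p, p] + A[p, g] %*% A22i %*% D %*% A22i %*% A[g, p]
  H[p, g] <- A[p, g] %*% A22i %*% Gw
  H[g, p] <- t(H[p, g])
  H[g, g] <- Gw
  H
}

# moderate simulated population shared across test files (built lazily once)
.shared <- new.env(parent = emptyenv())
demo_pop <- function() {
  if (is.null(.shared$pop)) {
    cfg <- sim_config(n_founders = 80, n_generations = 6, n_chrom = 4,
                      markers_per_chrom = 50, chrom_length_m = 0.3,
                      n_qtl = 40, n_genotyped = 100,
                      genotyping_strategy = "random", seed = 42)
    .shared$pop <- simulate_population(cfg, vc = var_comp(0.3, 0.7))
  }
  .shared$pop
}

# forward-validation cutoff for demo_pop: the last simulated generation
# (born in 2005) forms the validation cohort
demo_cutoff <- function() as.Date("2004-12-31")
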