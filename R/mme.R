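#' Variance components for an animal model
#'
#' @param sigma2_u Direct additive genetic variance (trait units^2).
#' @param sigma2_e Residual variance (> 0).
#' @param sigma2_pe Animal permanent-environment variance (repeated records).
#' @param sigma2_m Maternal additive genetic variance.
#' @param sigma2_q Maternal permanent-environment variance.
#' @return List of class \code{"var_comp"}.
#' @export
var_comp <- function(sigma2_u, sigma2_e, sigma2_pe = 0, sigma2_m = 0,
                     sigma2_q = 0) {
  stopifnot(sigma2_u >= 0, sigma2_e > 0, sigma2_pe >= 0, sigma2_m >= 0,
            sigma2_q >= 0)
  structure(list(sigma2_u = sigma2_u, sigma2_pe = sigma2_pe,
                 sigma2_m = sigma2_m, sigma2_q = sigma2_q,
                 sigma2_e = sigma2_e), class = "var_comp")
}

#' Variance components of the six study trait archetypes
#'
#' The national-evaluation components used for the sheep traits: birth weight
#' (BWT), postweaning weight (PWT), yearling weight (YWT), yearling fibre
#' diameter (YFD), yearling greasy fleece weight (YGFW) and number of lambs
#' born (NLB). YFD is evaluated with the plain additive model, NLB with the
#' repeatability model, and the remaining traits with the maternal model.
#'
#' @param trait Trait code.
#' @return A [var_comp()].
#' @export
trait_vc <- function(trait) {
  trait <- match.arg(trait, c("BWT", "PWT", "YWT", "YFD", "YGFW", "NLB"))
  switch(trait,
    BWT  = var_comp(0.085, 0.372, sigma2_m = 0.091, sigma2_q = 0.061),
    PWT  = var_comp(3.211, 25.046, sigma2_m = 1.926, sigma2_q = 1.926),
    YWT  = var_comp(15.402, 40.283, sigma2_m = 1.777, sigma2_q = 1.777),
    YFD  = var_comp(1.311, 0.989),
    YGFW = var_comp(0.122, 0.181, sigma2_m = 0.013, sigma2_q = 0.013),
    NLB  = var_comp(0.025, 0.250, sigma2_pe = 0.009))
}

#' Default model class for a study trait
#'
#' @param trait Trait code.
#' @return \code{"additive"}, \code{"repeatability"} or \code{"maternal"}.
#' @export
trait_model <- function(trait) {
  trait <- match.arg(trait, c("BWT", "PWT", "YWT", "YFD", "YGFW", "NLB"))
  switch(trait, YFD = "additive", NLB = "repeatability", "maternal")
}

# Assemble the mixed-model equations.
#
# records: data.frame with animal_id and the response column; model 3 uses the
# pedigree to find each record's dam. kinv: sparse inverse relationship matrix
# over all pedigree animals (A^-1 or sparse H^-1). fixed: data.frame of fixed
# factors (default a single overall mean).
build_mme <- function(ped, records, value, model, vc, kinv, a_inv = NULL,
                      fixed = NULL) {
  ids <- ped$id
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  miss <- setdiff(records$animal_id, ids)
  if (length(miss))
    stop("phenotyped animals missing from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  dropped_records <- 0L
  if (model == "maternal") {
    dam_of <- stats::setNames(ped$dam, ped$id)
    rec_dam <- dam_of[records$animal_id]
    keep <- !is.na(rec_dam)
    dropped_records <- sum(!keep)
    records <- records[keep, , drop = FALSE]
    value <- value[keep]
    rec_dam <- rec_dam[keep]
  }
  nrec <- nrow(records)
  if (!nrec) stop("no usable phenotype records")
  lam <- function(s2) vc$sigma2_e / s2

  # fixed design: overall mean unless an explicit factor frame is given
  if (is.null(fixed)) {
    X <- Matrix::Matrix(1, nrec, 1, sparse = TRUE)
    fix_names <- "(mu)"
  } else {
    f <- factor(fixed[[1]])
    X <- Matrix::sparse.model.matrix(~ f - 1)
    fix_names <- paste0(names(fixed)[1], levels(f))
  }
  nfix <- ncol(X)

  ri <- pos[records$animal_id]
  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = ri, x = 1,
                            dims = c(nrec, n))
  blocks <- list(X = X, Z = Z)
  pen <- list(NULL, lam(vc$sigma2_u) * kinv)
  eff_ids <- list(fix_names, ids)
  eff_names <- c("fixed", "u")

  if (model == "repeatability") {
    if (vc$sigma2_pe <= 0)
      stop("repeatability model requires sigma2_pe > 0")
    pe_ids <- sort(unique(records$animal_id))
    W <- Matrix::sparseMatrix(i = seq_len(nrec),
                              j = match(records$animal_id, pe_ids), x = 1,
                              dims = c(nrec, length(pe_ids)))
    blocks$W <- W
    pen <- c(pen, list(lam(vc$sigma2_pe) * Matrix::Diagonal(length(pe_ids))))
    eff_ids <- c(eff_ids, list(pe_ids))
    eff_names <- c(eff_names, "pe")
  }
  if (model == "maternal") {
    if (is.null(a_inv))
      stop("maternal model needs the pedigree A-inverse for the maternal effect")
    dam_of <- stats::setNames(ped$dam, ped$id)
    rec_dam <- dam_of[records$animal_id]
    Z2 <- Matrix::sparseMatrix(i = seq_len(nrec), j = pos[rec_dam], x = 1,
                               dims = c(nrec, n))
    q_ids <- sort(unique(rec_dam))
    S <- Matrix::sparseMatrix(i = seq_len(nrec), j = match(rec_dam, q_ids),
                              x = 1, dims = c(nrec, length(q_ids)))
    if (vc$sigma2_m <= 0 || vc$sigma2_q <= 0)
      stop("maternal model requires sigma2_m > 0 and sigma2_q > 0")
    blocks$Z2 <- Z2
    blocks$S <- S
    pen <- c(pen, list(lam(vc$sigma2_m) * a_inv,
                       lam(vc$sigma2_q) * Matrix::Diagonal(length(q_ids))))
    eff_ids <- c(eff_ids, list(ids), list(q_ids))
    eff_names <- c(eff_names, "m", "q")
  }

  D <- do.call(cbind, blocks)            # full design, records x effects
  C <- Matrix::crossprod(D)              # normal equations
  # add the variance-ratio penalties on the random blocks in one sweep
  sizes <- vapply(blocks, ncol, integer(1))
  offs <- cumsum(c(0, sizes))
  penm <- lapply(seq_along(pen), function(b) {
    if (is.null(pen[[b]]))
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(sizes[b], sizes[b]))
    else pen[[b]]
  })
  C <- C + Matrix::bdiag(penm)
  rhs <- as.numeric(Matrix::crossprod(D, value))
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, design = D,
                 y = value, sizes = sizes, offsets = offs,
                 eff_names = eff_names, eff_ids = eff_ids,
                 model = model, vc = vc,
                 dropped_records = dropped_records),
            class = "mme_system")
}

# Solve the assembled system by sparse Cholesky; PEV (sigma_e^2 times the
# requested diagonal entries of C^-1) via selected column solves.
solve_mme <- function(sys, pev_ids = NULL, method = c("direct", "pcg"),
                      tol = 1e-8, max_iter = 5000) {
  method <- match.arg(method)
  C <- sys$C
  rhs <- sys$rhs
  if (method == "direct") {
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, rhs))
    converged <- TRUE
    iter <- NA_integer_
  } else {
    res <- pcg_solve(C, rhs, tol = tol, max_iter = max_iter)
    sol <- res$x
    converged <- res$converged
    iter <- res$iter
    if (!converged)
      stop("conjugate-gradient solver did not reach tolerance ", tol,
           " in ", max_iter, " iterations (residual ", res$residual, ")")
    ch <- NULL
  }
  residual_norm <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)

  offs <- sys$offsets
  effects <- list()
  for (b in seq_along(sys$eff_names)) {
    v <- sol[(offs[b] + 1):offs[b + 1]]
    names(v) <- sys$eff_ids[[b]]
    effects[[sys$eff_names[b]]] <- v
  }
  pev <- NULL
  if (!is.null(pev_ids)) {
    if (method != "direct")
      stop("prediction error variances need the direct solver")
    u_off <- offs[which(sys$eff_names == "u")]
    cols <- u_off + match(pev_ids, sys$eff_ids[[which(sys$eff_names == "u")]])
    if (anyNA(cols)) stop("pev ids not among the model's animals")
    B <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(nrow(C), length(cols)))
    V <- Matrix::solve(ch, B)
    pev <- sys$vc$sigma2_e * vapply(seq_along(cols),
                                    function(k) V[cols[k], k], numeric(1))
    names(pev) <- pev_ids
  }
  list(mu = if ("(mu)" %in% names(effects$fixed)) effects$fixed[["(mu)"]]
            else NA_real_,
       fixed = effects$fixed,
       u = effects$u,
       pe = effects$pe,
       m = effects$m,
       q = effects$q,
       pev_u = pev,
       converged = converged, iter = iter,
       residual_norm = residual_norm)
}

pcg_solve <- function(C, b, tol = 1e-8, max_iter = 5000) {
  Mdiag <- Matrix::diag(C)
  Mdiag[Mdiag == 0] <- 1
  x <- numeric(length(b))
  r <- b - as.numeric(C %*% x)
  z <- r / Mdiag
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  for (it in seq_len(max_iter)) {
    Cp <- as.numeric(C %*% p)
    a <- rz / sum(p * Cp)
    x <- x + a * p
    r <- r - a * Cp
    if (sqrt(sum(r^2)) / bn < tol)
      return(list(x = x, converged = TRUE, iter = it,
                  residual = sqrt(sum(r^2)) / bn))
    z <- r / Mdiag
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, converged = FALSE, iter = max_iter,
       residual = sqrt(sum(r^2)) / bn)
}

#' Theoretical accuracy from prediction error variance
#'
#' TA_i = sqrt(1 - PEV_i / ((1 + f_i) sigma_u^2)), the standard conversion of
#' reliability to accuracy. Set \code{squared = TRUE} for the reliability-like
#' quantity without the square root. PEV values at or above the ceiling
#' (1 + f) sigma_u^2 are clamped to TA = 0.
#'
#' @param pev Named vector of prediction error variances.
#' @param f Inbreeding coefficients (named; matched by id, default 0).
#' @param sigma2_u Direct additive genetic variance (> 0).
#' @param squared Return 1 - PEV/((1+f) sigma_u^2) without the square root.
#' @return Named vector of accuracies in [0, 1].
#' @export
theoretical_accuracy <- function(pev, f = NULL, sigma2_u, squared = FALSE) {
  if (sigma2_u <= 0) stop("sigma2_u must be positive")
  fi <- rep(0, length(pev))
  if (!is.null(f)) {
    m <- match(names(pev), names(f))
    fi[!is.na(m)] <- f[m[!is.na(m)]]
  }
  rel <- 1 - pev / ((1 + fi) * sigma2_u)
  clamped <- rel < 0
  rel[clamped] <- 0
  ta <- if (squared) rel else sqrt(rel)
  names(ta) <- names(pev)
  attr(ta, "clamped") <- sum(clamped)
  ta
}

#' Connectedness between units by the variance of effect differences
#'
#' Fits the additive animal model with the unit factor (e.g. flock, or
#' training/validation group) as fixed effects and measures, for each unit
#' pair, VED_ij = Var(hat b_i - hat b_j) = sigma_e^2 (C^ii + C^jj - 2 C^ij)
#' from the inverse coefficient matrix. Low values mean well-connected units.
#'
#' @param ped Sorted \code{"pedigree"}.
#' @param records Data frame with \code{animal_id}, the response column and a
#'   unit column.
#' @param value_col,unit_col Column names for the response and the unit.
#' @param vc A [var_comp()] (only \code{sigma2_u} and \code{sigma2_e} used).
#' @param kinv Optional relationship inverse (default pedigree A-inverse).
#' @return List with \code{ved} (symmetric matrix over units, Inf for
#'   inestimable pairs) and \code{mean} over all cross pairs.
#' @export
connectedness_ved <- function(ped, records, value_col = "value",
                              unit_col = "unit", vc, kinv = NULL) {
  units <- factor(records[[unit_col]])
  if (nlevels(units) < 2) stop("need at least 2 units")
  if (is.null(kinv)) kinv <- nrm_inverse(ped)
  sys <- build_mme(ped, records, records[[value_col]], model = "additive",
                   vc = vc, kinv = kinv,
                   fixed = stats::setNames(data.frame(units), unit_col))
  k <- nlevels(units)
  Cf <- tryCatch({
    ch <- Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE)
    B <- Matrix::sparseMatrix(i = seq_len(k), j = seq_len(k), x = 1,
                              dims = c(nrow(sys$C), k))
    as.matrix(Matrix::solve(ch, B))[seq_len(k), , drop = FALSE]
  }, error = function(e) NULL)
  ved <- matrix(Inf, k, k, dimnames = list(levels(units), levels(units)))
  if (!is.null(Cf)) {
    Cf <- vc$sigma2_e * Cf
    for (i in seq_len(k)) for (j in seq_len(k))
      ved[i, j] <- Cf[i, i] + Cf[j, j] - 2 * Cf[i, j]
  }
  diag(ved) <- 0
  list(ved = ved, mean = mean(ved[upper.tri(ved)]))
}
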