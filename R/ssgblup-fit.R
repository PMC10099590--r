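#' Fit a pedigree or single-step genomic animal model
#'
#' The package's central fitting function. Assembles and solves Henderson's
#' mixed-model equations for one of three animal models — additive,
#' repeatability (adds an animal permanent-environment effect) or maternal
#' (adds maternal additive and maternal permanent-environment effects) —
#' with known variance components, using either the pedigree relationship
#' inverse (A-BLUP) or the blended single-step inverse (H-BLUP / HAP-BLUP,
#' via an [h_inverse()] object). The maternal additive effect always uses the
#' pedigree relationships, and the direct-maternal genetic covariance is
#' fixed at zero. Breeding values are predicted for every pedigree animal,
#' phenotyped or not.
#'
#' @param records Data frame of phenotype records with \code{animal_id} and
#'   the response column (corrected phenotypes; the model fits only an
#'   overall mean as fixed effect).
#' @param ped A sorted \code{"pedigree"} from [as_pedigree()].
#' @param vc Variance components from [var_comp()] or [trait_vc()].
#' @param model \code{"additive"}, \code{"repeatability"} or
#'   \code{"maternal"}.
#' @param hinv Optional \code{"h_inverse"} object; when supplied the direct
#'   additive effect uses single-step relationships, otherwise pedigree
#'   A-BLUP is fitted.
#' @param value_col Response column; defaults to \code{corrected_value} when
#'   present, else \code{value}.
#' @param pev_ids Animals for which prediction error variances (and hence
#'   theoretical accuracies) are computed; requires the direct solver.
#' @param method \code{"direct"} sparse Cholesky (default) or \code{"pcg"}
#'   preconditioned conjugate gradients (no PEV available).
#' @param a_inv Optional precomputed pedigree A-inverse (recycled across
#'   fits); computed from \code{ped} when absent.
#' @param f Optional precomputed inbreeding vector.
#' @return Object of class \code{"ssgblup"} with components \code{mu},
#'   \code{u} (direct (G)EBV, named by animal), \code{pe}, \code{m},
#'   \code{q}, \code{pev_u}, \code{ta} (when \code{pev_ids} given),
#'   \code{residual_norm}, \code{converged}, and bookkeeping fields.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("1", "2", "3"), sire = c(NA, NA, "1"), dam = c(NA, NA, "2")))
#' recs <- data.frame(animal_id = c("1", "2", "3"), value = c(10, 12, 14))
#' fit <- ssgblup(recs, ped, vc = var_comp(sigma2_u = 1, sigma2_e = 2))
#' coef(fit)
#' @export
ssgblup <- function(records, ped, vc,
                    model = c("additive", "repeatability", "maternal"),
                    hinv = NULL, value_col = NULL, pev_ids = NULL,
                    method = c("direct", "pcg"), a_inv = NULL, f = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(value_col))
    value_col <- if ("corrected_value" %in% names(records)) "corrected_value"
                 else "value"
  y <- records[[value_col]]
  if (is.null(y)) stop("records lack a '", value_col, "' column")
  if (is.null(f)) f <- inbreeding(ped)
  if (is.null(a_inv)) a_inv <- nrm_inverse(ped, f = f)
  kinv <- if (is.null(hinv)) a_inv else hinv_sparse(hinv)
  sys <- build_mme(ped, records, y, model = model, vc = vc, kinv = kinv,
                   a_inv = a_inv)
  sol <- solve_mme(sys, pev_ids = pev_ids, method = method)
  ta <- if (!is.null(sol$pev_u))
    theoretical_accuracy(sol$pev_u, f = f, sigma2_u = vc$sigma2_u) else NULL
  out <- structure(list(
    mu = sol$mu, u = sol$u, pe = sol$pe, m = sol$m, q = sol$q,
    pev_u = sol$pev_u, ta = ta,
    model = model, vc = vc,
    relationship = if (is.null(hinv)) "A" else "H",
    alpha = if (is.null(hinv)) NA_real_ else hinv$alpha,
    n_animals = nrow(ped), n_records = nrow(records),
    dropped_records = sys$dropped_records,
    residual_norm = sol$residual_norm, converged = sol$converged,
    inbreeding = f,
    records = records[, c("animal_id", value_col)],
    value_col = value_col), class = "ssgblup")
  out
}

#' @export
print.ssgblup <- function(x, ...) {
  cat("Single-step/pedigree BLUP fit (", x$model, " model, ",
      x$relationship, "-BLUP",
      if (!is.na(x$alpha)) paste0(", alpha = ", x$alpha), ")\n", sep = "")
  cat("  animals:", x$n_animals, "  records:", x$n_records,
      if (x$dropped_records) paste0("  (", x$dropped_records,
                                    " records dropped: unknown dam)"), "\n")
  cat("  overall mean:", format(x$mu, digits = 5),
      "  relative residual:", format(x$residual_norm, digits = 3), "\n")
  cat("  EBV range: [", format(min(x$u), digits = 4), ", ",
      format(max(x$u), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.ssgblup <- function(object, ...) {
  s <- list(model = object$model, relationship = object$relationship,
            alpha = object$alpha, mu = object$mu,
            n_animals = object$n_animals, n_records = object$n_records,
            sd_u = stats::sd(object$u),
            mean_f = mean(object$inbreeding),
            mean_ta = if (!is.null(object$ta)) mean(object$ta) else NA_real_,
            residual_norm = object$residual_norm)
  class(s) <- "summary.ssgblup"
  s
}

#' @export
print.summary.ssgblup <- function(x, ...) {
  cat(x$relationship, "-BLUP ", x$model, " model: ", x$n_records,
      " records on ", x$n_animals, " animals\n", sep = "")
  cat("  mu =", format(x$mu, digits = 5),
      "; sd(EBV) =", format(x$sd_u, digits = 4),
      "; mean f =", format(x$mean_f, digits = 4), "\n")
  if (!is.na(x$mean_ta)) cat("  mean theoretical accuracy:",
                             format(x$mean_ta, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.ssgblup <- function(object, effect = c("u", "m", "pe", "q"), ...) {
  effect <- match.arg(effect)
  object[[effect]]
}

#' Predicted breeding values (optionally total maternal merit)
#'
#' @param object An \code{"ssgblup"} fit.
#' @param ids Animals to predict for (default: all pedigree animals).
#' @param type \code{"direct"} for the direct (G)EBV, \code{"maternal"} for
#'   the maternal EBV (maternal model only).
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
predict.ssgblup <- function(object, ids = NULL,
                            type = c("direct", "maternal"), ...) {
  type <- match.arg(type)
  v <- if (type == "direct") object$u else object$m
  if (is.null(v)) stop("fit has no ", type, " effect")
  if (is.null(ids)) return(v)
  ids <- as.character(ids)
  if (!all(ids %in% names(v)))
    stop("unknown animal ids: ",
         paste(utils::head(setdiff(ids, names(v)), 5), collapse = ", "))
  v[ids]
}

#' @export
fitted.ssgblup <- function(object, ...) {
  ids <- object$records$animal_id
  fit <- object$mu + object$u[ids]
  if (!is.null(object$pe)) fit <- fit + object$pe[ids]
  # maternal terms attach to the record's dam and are already reflected in
  # residuals only for records whose dam is known
  unname(fit)
}

#' @export
residuals.ssgblup <- function(object, ...) {
  object$records[[object$value_col]] - fitted(object)
}

#' Caterpillar plot of predicted breeding values
#'
#' @param x An \code{"ssgblup"} fit.
#' @param ids Animals to plot (default: all, ranked).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ssgblup <- function(x, ids = NULL, ...) {
  u <- if (is.null(ids)) x$u else x$u[as.character(ids)]
  u <- sort(u)
  graphics::plot(seq_along(u), u, pch = 16, cex = 0.5,
                 xlab = "animal rank", ylab = "(G)EBV", ...)
  if (!is.null(x$pev_u)) {
    se <- sqrt(x$pev_u[names(u)])
    ok <- !is.na(se)
    graphics::segments(seq_along(u)[ok], (u - 1.96 * se)[ok],
                       seq_along(u)[ok], (u + 1.96 * se)[ok],
                       col = "grey70")
    graphics::points(seq_along(u), u, pch = 16, cex = 0.5)
  }
  invisible(x)
}

#' Export BLUP solutions as TSV
#'
#' Writes animal_id, effect, solution, pev, ta rows for all solved effects.
#'
#' @param fit An \code{"ssgblup"}.
#' @param path Output path.
#' @export
write_solutions <- function(fit, path) {
  pev <- if (is.null(fit$pev_u)) rep(NA_real_, length(fit$u))
         else unname(fit$pev_u[names(fit$u)])
  ta <- if (is.null(fit$ta)) rep(NA_real_, length(fit$u))
        else unname(fit$ta[names(fit$u)])
  rows <- list(data.frame(animal_id = names(fit$u), effect = "u",
                          solution = unname(fit$u), pev = pev, ta = ta))
  for (e in c("pe", "m", "q")) {
    v <- fit[[e]]
    if (!is.null(v))
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = names(v), effect = e, solution = unname(v),
        pev = NA_real_, ta = NA_real_)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
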