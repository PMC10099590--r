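#' Trait configuration for contemporary-group formation
#'
#' Returns the default factor list and age-window width used to build
#' contemporary groups for each trait. Body-weight and wool traits use
#' flock, year, season, management group, sex, recording date and 70-day age
#' windows on birth date; birth weight uses 35-day windows and no recording
#' date; litter size uses the ewe's flock, birth year, season, management
#' group and parity.
#'
#' @param trait One of \code{"BWT","PWT","YWT","YFD","YGFW","NLB"}.
#' @return List with \code{factors}, \code{age_window_days} (NA when no age
#'   window applies) and \code{use_record_date}.
#' @export
cg_config <- function(trait) {
  trait <- match.arg(trait, c("BWT", "PWT", "YWT", "YFD", "YGFW", "NLB"))
  if (trait == "NLB")
    return(list(factors = c("flock", "year", "season", "management_group",
                            "parity"),
                age_window_days = NA_real_, use_record_date = FALSE))
  if (trait == "BWT")
    return(list(factors = c("flock", "year", "season", "management_group",
                            "sex"),
                age_window_days = 35, use_record_date = FALSE))
  list(factors = c("flock", "year", "season", "management_group", "sex",
                   "record_date"),
       age_window_days = 70, use_record_date = TRUE)
}

#' Assign contemporary groups
#'
#' Builds the contemporary-group (CG) label for each record by concatenating
#' the trait's factor fields plus a consecutive birth-date age window (70-day
#' default, 35-day for birth weight), anchored at the earliest birth date
#' within each flock-year-season cell so the binning is deterministic.
#'
#' @param recs Phenotype records data frame; see [read_phenotypes()] for the
#'   column layout. A \code{birth_date} column is required for age binning.
#' @param trait Trait code; selects the CG recipe via [cg_config()].
#' @param config Optional explicit config (overrides \code{trait}).
#' @return List with \code{cg} (character label per retained record row),
#'   \code{keep} (logical per input row; records missing a factor level are
#'   dropped) and \code{dropped} (data frame of row, reason).
#' @export
make_contemporary_groups <- function(recs, trait, config = NULL) {
  cfg <- if (is.null(config)) cg_config(trait) else config
  n <- nrow(recs)
  keep <- rep(TRUE, n)
  reasons <- character(n)
  parts <- list()
  for (f in cfg$factors) {
    v <- recs[[f]]
    if (is.null(v)) stop("records lack required factor field '", f, "'")
    v <- as.character(v)
    miss <- is.na(v) | v == ""
    keep[miss & keep] <- FALSE
    reasons[miss] <- paste0("missing ", f)
    parts[[f]] <- v
  }
  if (!is.na(cfg$age_window_days)) {
    bd <- as.Date(recs$birth_date)
    miss <- is.na(bd)
    keep[miss & keep] <- FALSE
    reasons[miss & reasons == ""] <- "missing birth_date"
    cell <- paste(recs$flock, recs$year, recs$season, sep = "|")
    bin <- rep(NA_integer_, n)
    for (cl in unique(cell[keep])) {
      inc <- which(cell == cl & keep)
      anchor <- min(bd[inc])
      bin[inc] <- as.integer(floor(as.numeric(bd[inc] - anchor) /
                                     cfg$age_window_days))
    }
    parts[["age_bin"]] <- as.character(bin)
  }
  lab <- do.call(paste, c(parts, sep = "_"))
  lab[!keep] <- NA_character_
  dropped <- data.frame(row = which(!keep), reason = reasons[!keep])
  list(cg = lab, keep = keep, dropped = dropped)
}

#' Pre-adjust phenotypes for birth/rearing type and age of dam
#'
#' Applies the national-evaluation style pre-adjustment: a multiplicative
#' factor per birth-and-rearing-type class, then subtraction of a linear plus
#' quadratic regression on age of dam (centred so the mean adjustment over the
#' data is zero). Coefficients can be supplied or estimated internally by
#' least squares. Litter-size records (\code{trait == "NLB"}) pass through
#' unchanged.
#'
#' @param recs Phenotype records with \code{value}, \code{birth_rearing_type}
#'   and \code{age_of_dam_days} columns.
#' @param factors Optional named numeric vector of multiplicative factors per
#'   birth_rearing_type class.
#' @param age_coef Optional numeric \code{c(b1, b2)} linear and quadratic
#'   age-of-dam coefficients.
#' @param trait Trait code; \code{"NLB"} is returned unchanged.
#' @return \code{recs} with \code{value} replaced by the adjusted value and an
#'   attribute \code{"preadjust"} recording the coefficients used.
#' @export
preadjust <- function(recs, factors = NULL, age_coef = NULL, trait = "PWT") {
  if (trait == "NLB") {
    attr(recs, "preadjust") <- list(skipped = TRUE)
    return(recs)
  }
  brt <- as.character(recs$birth_rearing_type)
  age <- as.numeric(recs$age_of_dam_days)
  y <- recs$value
  estimated <- FALSE
  if (is.null(factors) || is.null(age_coef)) {
    estimated <- TRUE
    # Under the adjustment model raw = (target + b1*age + b2*age^2) / f_class,
    # alternate between the age regression on f-rescaled values and the
    # class-mean ratios; converges in a handful of sweeps.
    classes <- sort(unique(brt))
    fvec <- stats::setNames(rep(1, length(classes)), classes)
    abar <- mean(age)
    ac <- age - abar          # centred age: keeps the quadratic fit stable
    bc <- c(0, 0)
    for (iter in 1:6) {
      z <- y * unname(fvec[brt])
      cf <- stats::coef(stats::lm(z ~ ac + I(ac^2)))
      bc <- unname(c(cf[2], cf[3]))
      r <- bc[1] * ac + bc[2] * ac^2
      m_cl <- tapply(y - r / unname(fvec[brt]), brt, mean)[classes]
      if (any(m_cl <= 0))
        stop("pre-adjustment estimation failed: non-positive class mean")
      fvec <- stats::setNames(as.numeric(max(m_cl) / m_cl), classes)
    }
    # back to raw-age coefficients (the constant term is absorbed by the
    # mean-centring applied when the adjustment is used)
    if (is.null(age_coef)) age_coef <- c(bc[1] - 2 * bc[2] * abar, bc[2])
    if (is.null(factors)) factors <- fvec
  }
  missing_cls <- setdiff(unique(brt), names(factors))
  if (length(missing_cls))
    stop("no multiplicative factor for birth_rearing_type class(es): ",
         paste(missing_cls, collapse = ", "))
  age_coef[is.na(age_coef)] <- 0
  adj_reg <- age_coef[1] * age + age_coef[2] * age^2
  adj_reg <- adj_reg - mean(adj_reg)  # centre: zero mean adjustment
  recs$value <- y * unname(factors[brt]) - adj_reg
  attr(recs, "preadjust") <- list(factors = factors, age_coef = age_coef,
                                  estimated = estimated)
  recs
}

#' Remove outlying phenotype records
#'
#' Single-pass trait-wise quality control: the mean and SD are computed once
#' on the input and records deviating more than \code{k} standard deviations
#' from the mean are removed.
#'
#' @param recs Phenotype records with \code{trait} and \code{value} columns.
#' @param k SD multiplier (default 3).
#' @return List with \code{records} (survivors) and \code{removed} (data frame
#'   of animal_id, trait, value, reason).
#' @export
phenotype_qc <- function(recs, k = 3) {
  keep <- rep(TRUE, nrow(recs))
  reason <- character(nrow(recs))
  for (tr in unique(recs$trait)) {
    i <- which(recs$trait == tr)
    v <- recs$value[i]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      if (length(i) >= 2 && (is.na(s) || s == 0))
        warning("zero phenotypic variance for trait ", tr, "; nothing removed")
      next
    }
    m <- mean(v)
    out <- abs(v - m) > k * s
    keep[i[out]] <- FALSE
    reason[i[out]] <- sprintf("|%.4g - %.4g| > %g SD (%.4g)", v[out], m, k, s)
  }
  removed <- cbind(recs[!keep, c("animal_id", "trait", "value")],
                   reason = reason[!keep])
  list(records = recs[keep, , drop = FALSE], removed = removed)
}

#' Filter contemporary groups and correct phenotypes for the CG effect
#'
#' Drops contemporary groups with fewer than \code{min_size} animals or with
#' no within-group phenotypic variability, then fits the CG fixed effect by
#' least squares and returns the corrected phenotype = residual + grand mean.
#'
#' @param recs Phenotype records (single trait).
#' @param cg Character vector of CG labels aligned with \code{recs} rows.
#' @param min_size Minimum CG size (default 3).
#' @param filter Apply the size/variability CG filters (default TRUE).
#' @return List with \code{records} (filtered records plus \code{cg_label} and
#'   \code{corrected_value} columns) and \code{dropped_cg} (labels removed).
#' @export
correct_for_cg <- function(recs, cg, min_size = 3, filter = TRUE) {
  stopifnot(length(cg) == nrow(recs))
  ok <- !is.na(cg)
  recs <- recs[ok, , drop = FALSE]
  cg <- cg[ok]
  dropped <- character(0)
  if (filter) {
    sizes <- table(cg)
    vr <- tapply(recs$value, cg, stats::var)
    bad <- names(sizes)[sizes < min_size | is.na(vr) | vr == 0]
    dropped <- bad
    keep <- !(cg %in% bad)
    recs <- recs[keep, , drop = FALSE]
    cg <- cg[keep]
  }
  if (!nrow(recs)) stop("no records left after contemporary-group filtering")
  gm <- mean(recs$value)
  cg_mean <- tapply(recs$value, cg, mean)   # OLS fixed-effect solutions
  corrected <- as.numeric(recs$value - cg_mean[cg] + gm)
  recs$cg_label <- cg
  recs$corrected_value <- corrected
  list(records = recs, dropped_cg = dropped)
}

#' Read phenotype records from CSV
#'
#' Expected columns: \code{animal_id, trait, value, record_date, flock, year,
#' season, management_group, sex, birth_rearing_type, age_of_dam_days, parity}
#' (missing optional columns are filled with NA). A \code{birth_date} column,
#' if absent, can be merged from the pedigree downstream.
#'
#' @param path CSV path.
#' @return Data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  recs <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(recs) <- tolower(names(recs))
  need <- c("animal_id", "trait", "value")
  if (!all(need %in% names(recs)))
    stop("phenotype file must have columns animal_id, trait, value")
  recs$animal_id <- as.character(recs$animal_id)
  recs$value <- as.numeric(recs$value)
  for (col in c("record_date", "birth_date"))
    if (col %in% names(recs)) recs[[col]] <- as.Date(recs[[col]])
  recs
}
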