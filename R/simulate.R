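#' Configuration for the synthetic population generator
#'
#' The defaults emulate the structure of a multi-flock sheep evaluation at
#' desk scale: a closed population of constant size across discrete
#' generations, balanced sexes, flock structure with occasional sire
#' migration, evenly spaced biallelic markers on autosomes simulated by gene
#' dropping (Haldane recombination), a selectively genotyped cohort, and
#' contemporary-group-structured phenotypes with the study's variance
#' components.
#'
#' @param n_founders Founder count (even; sexes balanced). Default 200.
#' @param n_generations Total discrete generations including founders
#'   (default 10; 1 = founders only).
#' @param dams_per_sire Mating ratio (default 5).
#' @param offspring_per_dam Lambs per dam per generation (default 2, which
#'   keeps the population size constant).
#' @param n_flocks Number of flocks (default 3).
#' @param sire_migration Probability a dam is mated to a sire from another
#'   flock (default 0.1).
#' @param n_chrom,markers_per_chrom,chrom_length_m Genome layout: default 20
#'   autosomes x 100 markers, 1 Morgan each.
#' @param founder_maf_range Founder allele frequencies drawn uniformly on
#'   this range (default 0.05-0.5).
#' @param n_qtl QTL count for marker-based breeding values (default 200).
#' @param missing_rate Genotype missingness applied after truth is stored.
#' @param n_genotyped Size of the genotyped cohort (default 500).
#' @param genotyping_strategy \code{"progeny_tested"} (default) or
#'   \code{"random"}.
#' @param tbv_mode \code{"marker_qtl"} (default) or \code{"pedigree_flow"}.
#' @param base_year First birth year (default 2000).
#' @param seed Integer seed for the whole simulation (default 1).
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founders = 200, n_generations = 10,
                       dams_per_sire = 5, offspring_per_dam = 2,
                       n_flocks = 3, sire_migration = 0.1,
                       n_chrom = 20, markers_per_chrom = 100,
                       chrom_length_m = 1,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl = 200, missing_rate = 0,
                       n_genotyped = 500,
                       genotyping_strategy = c("progeny_tested", "random"),
                       tbv_mode = c("marker_qtl", "pedigree_flow"),
                       base_year = 2000, seed = 1) {
  stopifnot(n_founders >= 2, n_generations >= 1, dams_per_sire >= 1,
            offspring_per_dam >= 1, n_flocks >= 1,
            missing_rate >= 0, missing_rate <= 0.2)
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    dams_per_sire = dams_per_sire, offspring_per_dam = offspring_per_dam,
    n_flocks = n_flocks, sire_migration = sire_migration,
    n_chrom = n_chrom, markers_per_chrom = markers_per_chrom,
    chrom_length_m = chrom_length_m,
    founder_maf_range = founder_maf_range,
    n_qtl = n_qtl, missing_rate = missing_rate,
    n_genotyped = n_genotyped,
    genotyping_strategy = match.arg(genotyping_strategy),
    tbv_mode = match.arg(tbv_mode),
    base_year = base_year, seed = seed), class = "sim_config")
}

#' Simulate a multi-flock discrete-generation pedigree
#'
#' Founders are split round-robin across flocks with alternating sexes. In
#' each later generation every female of the previous generation is a dam,
#' sires are drawn at the configured mating ratio (with occasional
#' cross-flock migration), and each dam raises \code{offspring_per_dam}
#' lambs of alternating sex in her flock. Birth dates spread each
#' generation's lambs over about five months so contemporary-group age
#' binning has real work to do.
#'
#' @param cfg A [sim_config()].
#' @return A sorted \code{"pedigree"} with a \code{generation} column.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed + 101L)
  rows <- list()
  founders <- data.frame(
    id = sprintf("G0_%04d", seq_len(cfg$n_founders)),
    sire = NA_character_, dam = NA_character_,
    sex = rep_len(c("M", "F"), cfg$n_founders),
    flock = as.character(rep_len(seq_len(cfg$n_flocks), cfg$n_founders)),
    generation = 0L, stringsAsFactors = FALSE)
  founders$birth_date <- as.Date(sprintf("%d-01-01", cfg$base_year)) +
    sample(0:149, cfg$n_founders, replace = TRUE)
  rows[[1]] <- founders
  prev <- founders
  for (g in seq_len(cfg$n_generations - 1L)) {
    dams <- prev[prev$sex == "F", , drop = FALSE]
    males <- prev[prev$sex == "M", , drop = FALSE]
    if (!nrow(dams) || !nrow(males))
      stop("generation ", g, ": no available dams or sires ",
           "(infeasible mating configuration)")
    kids <- list()
    counter <- 0L
    for (fl in unique(dams$flock)) {
      fd <- dams[dams$flock == fl, , drop = FALSE]
      n_sires <- max(1L, ceiling(nrow(fd) / cfg$dams_per_sire))
      local_males <- males[males$flock == fl, , drop = FALSE]
      pool <- if (nrow(local_males)) local_males else males
      sires <- pool$id[sample.int(nrow(pool), n_sires,
                                  replace = n_sires > nrow(pool))]
      # occasional migration: replace a dam's sire with one from any flock
      assigned <- rep_len(sires, nrow(fd))
      migrate <- stats::runif(nrow(fd)) < cfg$sire_migration
      if (any(migrate))
        assigned[migrate] <- males$id[sample.int(nrow(males), sum(migrate),
                                                 replace = TRUE)]
      for (k in seq_len(nrow(fd))) {
        for (o in seq_len(cfg$offspring_per_dam)) {
          counter <- counter + 1L
          kids[[length(kids) + 1L]] <- data.frame(
            id = sprintf("G%d_%04d", g, counter),
            sire = assigned[k], dam = fd$id[k],
            sex = if (counter %% 2L == 1L) "M" else "F",
            flock = fl, generation = g, stringsAsFactors = FALSE)
        }
      }
    }
    gen <- do.call(rbind, kids)
    gen$birth_date <- as.Date(sprintf("%d-01-01", cfg$base_year + g)) +
      sample(0:149, nrow(gen), replace = TRUE)
    rows[[g + 1L]] <- gen
    prev <- gen
  }
  ped <- do.call(rbind, rows)
  gen_col <- stats::setNames(ped$generation, ped$id)
  ped <- as_pedigree(ped[, c("id", "sire", "dam", "birth_date", "sex",
                             "flock")])
  ped$generation <- unname(gen_col[ped$id])
  ped
}

#' Simulate phased genotypes by gene dropping
#'
#' Founder haplotypes are drawn in linkage equilibrium from per-marker
#' founder allele frequencies; descendants receive recombinant gametes with
#' crossover counts Poisson in the chromosome map length (Haldane model, no
#' interference) and uniform crossover positions. Markers are evenly spaced.
#' Genotypes are the haplotype sums; missingness, if configured, is applied
#' to the genotype matrix after the phased truth is stored.
#'
#' @param ped Sorted \code{"pedigree"}.
#' @param cfg A [sim_config()].
#' @return A phased [marker_set()]; when \code{missing_rate > 0} the
#'   complete matrices are kept in attribute \code{"truth"}.
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 202L)
  n <- nrow(ped)
  m_per <- cfg$markers_per_chrom
  M <- cfg$n_chrom * m_per
  chrom <- rep(seq_len(cfg$n_chrom), each = m_per)
  # genetic positions (Morgans) and physical bp, evenly spaced
  gpos <- rep((seq_len(m_per) - 0.5) / m_per * cfg$chrom_length_m,
              cfg$n_chrom)
  pos_bp <- rep(round(seq(1e5, 9.9e7, length.out = m_per)), cfg$n_chrom)
  map <- data.frame(name = sprintf("snp%d_%d", chrom, rep(seq_len(m_per),
                                                          cfg$n_chrom)),
                    chrom = as.character(chrom), pos = pos_bp)
  p <- stats::runif(M, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  h1 <- matrix(NA_integer_, n, M)
  h2 <- matrix(NA_integer_, n, M)
  pc <- ped_codes(ped)
  founder <- pc$s == 0L & pc$d == 0L
  nf <- sum(founder)
  h1[founder, ] <- matrix(stats::rbinom(nf * M, 1, rep(p, each = nf)), nf, M)
  h2[founder, ] <- matrix(stats::rbinom(nf * M, 1, rep(p, each = nf)), nf, M)
  chrom_idx <- split(seq_len(M), chrom)
  gpos_chrom <- (seq_len(m_per) - 0.5) / m_per * cfg$chrom_length_m
  gamete <- function(pa, pb) {
    # one recombinant haplotype from parent's pair (rows pa, pb of h1/h2)
    out <- integer(M)
    for (c in seq_len(cfg$n_chrom)) {
      idx <- chrom_idx[[c]]
      k <- stats::rpois(1, cfg$chrom_length_m)
      start <- stats::rbinom(1, 1, 0.5)
      strand <- if (k == 0) rep(start, m_per) else {
        br <- sort(stats::runif(k, 0, cfg$chrom_length_m))
        (start + findInterval(gpos_chrom, br)) %% 2L
      }
      out[idx] <- ifelse(strand == 0L, pa[idx], pb[idx])
    }
    out
  }
  for (i in which(!founder)) {
    s <- pc$s[i]; d <- pc$d[i]
    h1[i, ] <- gamete(h1[s, ], h2[s, ])  # paternal gamete
    h2[i, ] <- gamete(h1[d, ], h2[d, ])  # maternal gamete
  }
  geno <- h1 + h2
  rownames(geno) <- ped$id
  ms <- marker_set(geno, map, ped$id, hap1 = h1, hap2 = h2)
  if (cfg$missing_rate > 0) {
    truth <- ms
    gm <- ms$geno
    drop <- matrix(stats::runif(length(gm)) < cfg$missing_rate, nrow(gm))
    gm[drop] <- NA_integer_
    ms <- marker_set(gm, map, ped$id)
    attr(ms, "truth") <- truth
  }
  attr(ms, "founder_freq") <- p
  ms
}

#' Simulate true breeding values and permanent-environment deviates
#'
#' In \code{marker_qtl} mode a random QTL subset of the markers receives
#' i.i.d. normal additive effects, rescaled so the founder variance of the
#' direct true breeding values equals \code{sigma2_u} exactly; maternal
#' breeding values come from a disjoint QTL set scaled to \code{sigma2_m}
#' (direct-maternal correlation zero by construction). In
#' \code{pedigree_flow} mode founders are N(0, sigma2_u) and descendants are
#' the parent average plus a Mendelian deviate with variance
#' 0.5 (1 - (f_s + f_d)/2) sigma2_u.
#'
#' @param ped Sorted \code{"pedigree"}.
#' @param markers Phased [marker_set()] (marker_qtl mode; pass the truth
#'   matrix when missingness was applied).
#' @param vc A [var_comp()].
#' @param cfg A [sim_config()].
#' @return List: \code{tbv_direct}, \code{tbv_maternal}, \code{pe},
#'   \code{mpe} (named vectors over all animals), \code{qtl} indices.
#' @export
simulate_breeding_values <- function(ped, markers, vc, cfg) {
  set.seed(cfg$seed + 303L)
  n <- nrow(ped)
  ids <- ped$id
  founder <- is.na(ped$sire) & is.na(ped$dam)
  scale_to <- function(x, target_var) {
    if (target_var == 0) return(stats::setNames(rep(0, n), ids))
    v <- stats::var(x[founder])
    if (v == 0) stop("degenerate founder TBV variance")
    stats::setNames((x - mean(x[founder])) * sqrt(target_var / v), ids)
  }
  if (cfg$tbv_mode == "marker_qtl") {
    M <- nrow(markers$map)
    if (2 * cfg$n_qtl > M)
      stop("n_qtl too large for the simulated marker panel")
    qtl_all <- sample.int(M, 2 * cfg$n_qtl)
    qtl_d <- qtl_all[seq_len(cfg$n_qtl)]
    qtl_m <- qtl_all[-seq_len(cfg$n_qtl)]
    gd <- markers$geno[ids, qtl_d, drop = FALSE]
    gm <- markers$geno[ids, qtl_m, drop = FALSE]
    tbv_d <- scale_to(as.numeric(gd %*% stats::rnorm(cfg$n_qtl)),
                      vc$sigma2_u)
    tbv_m <- if (vc$sigma2_m > 0)
      scale_to(as.numeric(gm %*% stats::rnorm(cfg$n_qtl)), vc$sigma2_m)
    else stats::setNames(rep(0, n), ids)
    qtl <- list(direct = qtl_d, maternal = qtl_m)
  } else {
    f <- inbreeding(ped)
    pc <- ped_codes(ped)
    flow <- function(s2) {
      if (s2 == 0) return(stats::setNames(rep(0, n), ids))
      x <- numeric(n)
      for (i in seq_len(n)) {
        s <- pc$s[i]; d <- pc$d[i]
        if (s == 0L && d == 0L) {
          x[i] <- stats::rnorm(1, 0, sqrt(s2))
        } else {
          pa <- if (s > 0L) x[s] else 0
          ma <- if (d > 0L) x[d] else 0
          fs <- if (s > 0L) f[s] else 0
          fd <- if (d > 0L) f[d] else 0
          nkn <- (s > 0L) + (d > 0L)
          msv <- if (nkn == 2) 0.5 * (1 - (fs + fd) / 2) * s2
                 else if (nkn == 1) 0.75 * s2 else s2
          x[i] <- (pa + ma) / 2 + stats::rnorm(1, 0, sqrt(msv))
        }
      }
      stats::setNames(x, ids)
    }
    tbv_d <- flow(vc$sigma2_u)
    tbv_m <- flow(vc$sigma2_m)
    qtl <- NULL
  }
  pe <- stats::setNames(stats::rnorm(n, 0, sqrt(vc$sigma2_pe)), ids)
  mpe <- stats::setNames(stats::rnorm(n, 0, sqrt(vc$sigma2_q)), ids)
  list(tbv_direct = tbv_d, tbv_maternal = tbv_m, pe = pe, mpe = mpe,
       qtl = qtl)
}

#' Simulate contemporary-group-structured phenotype records
#'
#' Builds records for non-founder animals: y = trait mean + CG effect (drawn
#' N(0, sigma2_cg)) + direct TBV + maternal TBV of the dam + maternal PE of
#' the dam + (animal PE for repeated litter-size records) + residual. For
#' weight/wool archetypes a multiplicative birth-and-rearing-type effect and
#' a linear+quadratic age-of-dam effect are injected on the raw scale so the
#' pre-adjustment step has real work to do. The litter-size archetype
#' produces 1-3 repeated records per ewe with parity.
#'
#' @param ped Sorted \code{"pedigree"} (with \code{generation}).
#' @param tbv Output of [simulate_breeding_values()].
#' @param vc A [var_comp()].
#' @param cfg A [sim_config()].
#' @param trait Trait code used in the records (default "PWT").
#' @param sigma2_cg Contemporary-group variance (default half the residual).
#' @param mu Trait mean (default 35).
#' @param repeated Litter-size style repeated records (default TRUE when
#'   \code{vc$sigma2_pe > 0}).
#' @param inject_preadjustment Apply the birth-rearing and age-of-dam
#'   distortions (default TRUE for non-repeated archetypes).
#' @return Data frame of phenotype records (see [read_phenotypes()] layout,
#'   plus \code{birth_date}); attribute \code{"injected"} records the true
#'   adjustment coefficients.
#' @export
simulate_phenotypes <- function(ped, tbv, vc, cfg, trait = "PWT",
                                sigma2_cg = vc$sigma2_e / 2, mu = 35,
                                repeated = vc$sigma2_pe > 0,
                                inject_preadjustment = !repeated) {
  set.seed(cfg$seed + 404L)
  cand <- ped[!is.na(ped$dam), , drop = FALSE]
  if (repeated) cand <- cand[cand$sex == "F", , drop = FALSE]
  if (!nrow(cand)) stop("no candidate animals for phenotyping")
  season_of <- function(date) {
    mo <- as.integer(format(date, "%m"))
    c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
      "summer", "autumn", "autumn", "autumn", "winter")[mo]
  }
  n_rec_per <- if (repeated) sample(1:3, nrow(cand), replace = TRUE)
               else rep(1L, nrow(cand))
  idx <- rep(seq_len(nrow(cand)), n_rec_per)
  parity <- unlist(lapply(n_rec_per, seq_len))
  an <- cand[idx, , drop = FALSE]
  nrec <- nrow(an)
  bd <- stats::setNames(ped$birth_date, ped$id)
  year <- as.integer(format(an$birth_date, "%Y"))
  # recording happens in flock-year batches, as on real farms
  record_date <- if (repeated) an$birth_date + 365 * parity
                 else as.Date(sprintf("%d-10-01", year))
  mgmt <- sample(c("mg1", "mg2"), nrec, replace = TRUE)
  cg_key <- paste(an$flock, year, season_of(an$birth_date), mgmt,
                  if (!repeated) an$sex else "F")
  cg_lv <- unique(cg_key)
  cg_eff <- stats::setNames(stats::rnorm(length(cg_lv), 0, sqrt(sigma2_cg)),
                            cg_lv)
  target <- mu + cg_eff[cg_key] +
    tbv$tbv_direct[an$id] + tbv$tbv_maternal[an$dam] + tbv$mpe[an$dam] +
    (if (repeated) tbv$pe[an$id] else 0) +
    stats::rnorm(nrec, 0, sqrt(vc$sigma2_e))
  age_of_dam <- as.numeric(an$birth_date - bd[an$dam])
  age_of_dam[is.na(age_of_dam)] <- 365 * 3
  brt <- sample(c("1-1", "2-1", "2-2"), nrec, replace = TRUE,
                prob = c(0.4, 0.3, 0.3))
  injected <- list(factors = c("1-1" = 1, "2-1" = 1.06, "2-2" = 1.12),
                   age_coef = c(2e-3 * mu / 35, -8e-7 * mu / 35))
  value <- as.numeric(target)
  if (inject_preadjustment) {
    reg <- injected$age_coef[1] * age_of_dam +
      injected$age_coef[2] * age_of_dam^2
    value <- (value + reg) / injected$factors[brt]
  }
  recs <- data.frame(
    animal_id = an$id, trait = trait, value = value,
    record_date = record_date, birth_date = an$birth_date,
    flock = an$flock, year = year, season = season_of(an$birth_date),
    management_group = mgmt, sex = an$sex, birth_rearing_type = brt,
    age_of_dam_days = age_of_dam,
    parity = if (repeated) parity else NA_integer_,
    stringsAsFactors = FALSE)
  rownames(recs) <- NULL
  attr(recs, "injected") <- c(injected, list(cg_effects = cg_eff))
  recs
}

#' Choose the genotyped cohort
#'
#' \code{progeny_tested} ranks eligible animals (those with own or progeny
#' phenotypes) by number of phenotyped progeny, then own-phenotype presence,
#' then id; \code{random} samples uniformly from the eligible set.
#'
#' @param ped Sorted \code{"pedigree"}.
#' @param records Phenotype records.
#' @param n Cohort size.
#' @param strategy \code{"progeny_tested"} or \code{"random"}.
#' @return Character vector of genotyped ids.
#' @export
select_genotyping_subset <- function(ped, records, n,
                                     strategy = c("progeny_tested",
                                                  "random")) {
  strategy <- match.arg(strategy)
  phen <- unique(records$animal_id)
  n_prog <- integer(nrow(ped))
  names(n_prog) <- ped$id
  for (p in c("sire", "dam")) {
    tab <- table(ped[[p]][ped$id %in% phen & !is.na(ped[[p]])])
    n_prog[names(tab)] <- n_prog[names(tab)] + as.integer(tab)
  }
  own <- ped$id %in% phen
  eligible <- ped$id[own | n_prog > 0]
  if (length(eligible) < n) {
    warning("only ", length(eligible), " eligible animals (requested ", n, ")")
    return(eligible)
  }
  if (strategy == "random") return(sample(eligible, n))
  ord <- order(-n_prog[eligible], -as.integer(eligible %in% phen), eligible)
  eligible[ord][seq_len(n)]
}

#' Simulate a complete study population
#'
#' Orchestrates pedigree, phased genotypes, breeding values, phenotypes and
#' the genotyped cohort from one configuration and seed.
#'
#' @param cfg A [sim_config()].
#' @param vc A [var_comp()] (default: heritability 0.3 additive archetype,
#'   \code{var_comp(0.3, 0.7)}).
#' @param trait Trait code for the records.
#' @param ... Passed to [simulate_phenotypes()].
#' @return List of class \code{"sim_population"}: \code{ped}, \code{markers},
#'   \code{tbv}, \code{records}, \code{genotyped_ids}, \code{cfg},
#'   \code{vc}.
#' @export
simulate_population <- function(cfg = sim_config(), vc = var_comp(0.3, 0.7),
                                trait = "PWT", ...) {
  ped <- simulate_pedigree(cfg)
  markers <- simulate_genotypes(ped, cfg)
  truth <- attr(markers, "truth") %||% markers
  tbv <- simulate_breeding_values(ped, truth, vc, cfg)
  recs <- simulate_phenotypes(ped, tbv, vc, cfg, trait = trait, ...)
  set.seed(cfg$seed + 505L)
  gids <- select_genotyping_subset(ped, recs, cfg$n_genotyped,
                                   cfg$genotyping_strategy)
  structure(list(ped = ped, markers = markers, tbv = tbv, records = recs,
                 genotyped_ids = gids, cfg = cfg, vc = vc),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("simulated population:", nrow(x$ped), "animals,",
      nrow(x$markers$map), "markers,", length(x$genotyped_ids),
      "genotyped,", nrow(x$records), "records\n")
  invisible(x)
}
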