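test_that("pedigree generation sizes follow the closed form", {
  cfg <- sim_config(n_founders = 100, n_generations = 5, dams_per_sire = 5,
                    offspring_per_dam = 2, n_chrom = 2,
                    markers_per_chrom = 10, n_qtl = 4, seed = 3)
  ped <- simulate_pedigree(cfg)
  # 100 founders, 50 dams per generation x 2 lambs = 100 per generation
  expect_equal(nrow(ped), 100 + 4 * 100)
  expect_equal(as.integer(table(ped$generation)), c(100, 100, 100, 100, 100))
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 100)
  # balanced sexes throughout, flocks within the configured set
  expect_equal(unname(table(ped$sex)), unname(table(rep(c("M", "F"), 250))))
  expect_true(all(ped$flock %in% as.character(1:3)))
  # every non-founder's parents are one generation older and already sorted
  nf <- !is.na(ped$sire)
  gen <- setNames(ped$generation, ped$id)
  expect_true(all(gen[ped$sire[nf]] == ped$generation[nf] - 1))
  expect_true(all(match(ped$sire[nf], ped$id) < which(nf)))
  # founders only
  expect_equal(nrow(simulate_pedigree(sim_config(n_founders = 10,
                                                 n_generations = 1))), 10)
})

test_that("the generator is deterministic in the seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 3, n_chrom = 2,
                    markers_per_chrom = 15, n_qtl = 5, n_genotyped = 20,
                    genotyping_strategy = "random", seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$ped$id, b$ped$id)
  expect_identical(a$markers$geno, b$markers$geno)
  expect_identical(a$records$value, b$records$value)
  expect_identical(a$genotyped_ids, b$genotyped_ids)
  cfg2 <- sim_config(n_founders = 30, n_generations = 3, n_chrom = 2,
                     markers_per_chrom = 15, n_qtl = 5, n_genotyped = 20,
                     genotyping_strategy = "random", seed = 100)
  c <- simulate_population(cfg2)
  expect_false(identical(a$markers$geno, c$markers$geno))
})

test_that("gene dropping is Mendelian-consistent at every marker", {
  pop <- demo_pop()
  ped <- pop$ped
  ms <- pop$markers
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  nf <- which(!is.na(ped$sire))
  for (i in sample(nf, 50)) {
    s <- pos[ped$sire[i]]
    d <- pos[ped$dam[i]]
    # paternal haplotype comes allele-by-allele from the sire's pair
    expect_true(all(ms$hap1[i, ] == ms$hap1[s, ] |
                      ms$hap1[i, ] == ms$hap2[s, ]))
    expect_true(all(ms$hap2[i, ] == ms$hap1[d, ] |
                      ms$hap2[i, ] == ms$hap2[d, ]))
  }
  expect_true(all(ms$geno == ms$hap1 + ms$hap2))
})

test_that("founder allele frequencies match the configured distribution", {
  pop <- demo_pop()
  p <- attr(pop$markers, "founder_freq")
  expect_true(all(p >= 0.05 & p <= 0.5))
  founders <- is.na(pop$ped$sire) & is.na(pop$ped$dam)
  H <- rbind(pop$markers$hap1[founders, ], pop$markers$hap2[founders, ])
  phat <- colMeans(H)
  se <- sqrt(p * (1 - p) / nrow(H))
  expect_true(all(abs(phat - p) <= 4.5 * se + 1e-9))
  # founders in linkage equilibrium: weak LD between distant markers
  r2 <- ld_r2(marker_set(
    H[seq_len(sum(founders)), 1:50] + H[sum(founders) + seq_len(sum(founders)), 1:50],
    pop$markers$map[1:50, ],
    ids = paste0("f", seq_len(sum(founders))),
    hap1 = H[seq_len(sum(founders)), 1:50],
    hap2 = H[sum(founders) + seq_len(sum(founders)), 1:50]), 1, 50)
  expect_lt(as.numeric(r2), 0.2)
})

test_that("a zero-length genetic map transmits intact chromosomes", {
  cfg <- sim_config(n_founders = 20, n_generations = 3, n_chrom = 2,
                    markers_per_chrom = 25, chrom_length_m = 0, n_qtl = 5,
                    seed = 8)
  ped <- simulate_pedigree(cfg)
  ms <- simulate_genotypes(ped, cfg)
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (ch in c("1", "2")) {
    idx <- which(ms$map$chrom == ch)
    for (i in which(!is.na(ped$sire))) {
      s <- pos[ped$sire[i]]
      child <- ms$hap1[i, idx]
      expect_true(identical(child, ms$hap1[s, idx]) ||
                    identical(child, ms$hap2[s, idx]))
    }
  }
})

test_that("marker-QTL breeding values hit the founder variance exactly", {
  pop <- demo_pop()
  vc <- var_comp(0.3, 0.7)
  founders <- is.na(pop$ped$sire) & is.na(pop$ped$dam)
  tbv <- pop$tbv
  expect_equal(var(tbv$tbv_direct[founders]), vc$sigma2_u, tolerance = 1e-10)
  expect_equal(mean(tbv$tbv_direct[founders]), 0, tolerance = 1e-10)
  # direct and maternal QTL sets are disjoint
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_chrom = 2,
                    markers_per_chrom = 30, n_qtl = 10, seed = 5)
  ped <- simulate_pedigree(cfg)
  ms <- simulate_genotypes(ped, cfg)
  vcm <- var_comp(1, 1, sigma2_m = 0.5, sigma2_q = 0.2)
  bv <- simulate_breeding_values(ped, ms, vcm, cfg)
  expect_length(intersect(bv$qtl$direct, bv$qtl$maternal), 0)
  expect_equal(var(bv$tbv_maternal[is.na(ped$sire)]), 0.5, tolerance = 1e-10)
  # zero maternal variance yields identically zero maternal values
  bv0 <- simulate_breeding_values(ped, ms, var_comp(1, 1), cfg)
  expect_true(all(bv0$tbv_maternal == 0))
  expect_error(simulate_breeding_values(
    ped, ms, vcm, sim_config(n_founders = 40, n_generations = 2,
                             n_chrom = 2, markers_per_chrom = 30,
                             n_qtl = 50, seed = 5)), "n_qtl too large")
})

test_that("pedigree-flow breeding values reproduce sigma2_u * A", {
  ped <- fullsib_ped()
  A <- build_nrm(ped)
  reps <- 3000
  X <- matrix(0, reps, nrow(ped))
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_founders = 4, n_generations = 1,
                      tbv_mode = "pedigree_flow", seed = r)
    X[r, ] <- simulate_breeding_values(ped, NULL, var_comp(1, 1),
                                       cfg)$tbv_direct
  }
  emp <- cov(X)
  expect_lt(max(abs(emp - A)), 0.15)
  expect_equal(diag(emp)[5], 1.25, tolerance = 0.15)
})

test_that("phenotype records carry the documented structure", {
  pop <- demo_pop()
  recs <- pop$records
  ped <- pop$ped
  # one record per non-founder animal for the weight archetype
  expect_equal(sort(unique(recs$animal_id)),
               sort(ped$id[!is.na(ped$dam)]))
  expect_equal(as.integer(table(recs$animal_id)),
               rep(1L, length(unique(recs$animal_id))))
  expect_true(all(is.na(recs$parity)))
  expect_true(all(recs$age_of_dam_days > 0))
  inj <- attr(recs, "injected")
  expect_equal(unname(inj$factors["2-2"]), 1.12)
  expect_length(inj$age_coef, 2)
  # repeated litter-size records: ewes only, parity 1..3, shared identity
  cfg <- pop$cfg
  vc_nlb <- var_comp(0.025, 0.25, sigma2_pe = 0.009)
  recs_nlb <- simulate_phenotypes(ped, pop$tbv, vc_nlb, cfg, trait = "NLB",
                                  mu = 1.5)
  expect_true(all(recs_nlb$sex == "F"))
  cnt <- table(recs_nlb$animal_id)
  expect_true(all(cnt >= 1 & cnt <= 3))
  expect_true(any(cnt > 1))
  by_an <- split(recs_nlb$parity, recs_nlb$animal_id)
  expect_true(all(vapply(by_an, function(p) all(sort(p) == seq_along(p)),
                         logical(1))))
  # no multiplicative injection for the repeated archetype
  expect_true(all(recs_nlb$record_date > recs_nlb$birth_date))
})

test_that("true signals are recoverable: EBV correlate with TBV", {
  pop <- demo_pop()
  pa <- preadjust(pop$records)
  cg <- make_contemporary_groups(pa, "PWT")
  cor_recs <- correct_for_cg(pa, cg$cg)$records
  fit <- ssgblup(cor_recs, pop$ped, var_comp(0.3, 0.7))
  phen <- unique(cor_recs$animal_id)
  r <- cor(fit$u[phen], pop$tbv$tbv_direct[phen])
  expect_gt(r, 0.3)
})

test_that("progeny-tested genotyping ranks by phenotyped progeny count", {
  ped <- as_pedigree(data.frame(
    id = c("s1", "s2", "d1", "k1", "k2", "k3", "k4", "lone"),
    sire = c(NA, NA, NA, "s1", "s1", "s1", "s2", NA),
    dam = c(NA, NA, NA, "d1", "d1", "d1", "d1", NA)))
  recs <- data.frame(animal_id = c("k1", "k2", "k3", "k4", "lone"),
                     value = 1:5)
  # s1: 3 phenotyped progeny; d1: 4; s2: 1; k*: own records; lone: own only
  top2 <- select_genotyping_subset(ped, recs, 2)
  expect_equal(top2, c("d1", "s1"))
  top3 <- select_genotyping_subset(ped, recs, 3)
  expect_equal(top3, c("d1", "s1", "s2"))
  expect_warning(all_el <- select_genotyping_subset(ped, recs, 50),
                 "eligible")
  expect_setequal(all_el, c("s1", "s2", "d1", "k1", "k2", "k3", "k4",
                            "lone"))
  set.seed(4)
  rnd <- select_genotyping_subset(ped, recs, 4, strategy = "random")
  expect_length(rnd, 4)
  expect_true(all(rnd %in% all_el))
})

test_that("genotype missingness stores the phased truth", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_chrom = 2,
                    markers_per_chrom = 20, missing_rate = 0.1, n_qtl = 5,
                    seed = 12)
  ped <- simulate_pedigree(cfg)
  ms <- simulate_genotypes(ped, cfg)
  expect_false(ms$phased)
  expect_gt(mean(is.na(ms$geno)), 0.05)
  truth <- attr(ms, "truth")
  expect_true(truth$phased)
  expect_false(anyNA(truth$geno))
  obs <- !is.na(ms$geno)
  expect_equal(ms$geno[obs], truth$geno[obs])
})
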