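test_that("LR statistics satisfy the identical-prediction identities", {
  set.seed(19)
  ids <- paste0("f", 1:50)
  w <- setNames(rnorm(50), ids)
  # identical whole and partial predictions: zero bias, zero dispersion,
  # accuracy = var(w) / sigma2_u
  st <- lr_statistics(w, w, ids, sigma2_u = 2)
  expect_equal(st$bias, 0)
  expect_equal(st$dispersion, 0, tolerance = 1e-12)
  expect_equal(st$accuracy, var(w) / 2, tolerance = 1e-12)
  # doubled partial predictions: cov(w, 2w)/var(2w) - 1 = -0.5
  st2 <- lr_statistics(w, 2 * w, ids, sigma2_u = 2)
  expect_equal(st2$dispersion, -0.5, tolerance = 1e-12)
  expect_equal(st2$bias, mean(w), tolerance = 1e-12)
  # sqrt form is the square root of the estimator (floored at zero)
  st3 <- lr_statistics(w, w, ids, sigma2_u = 2, sqrt_form = TRUE)
  expect_equal(st3$accuracy, sqrt(var(w) / 2), tolerance = 1e-12)
  # the inbreeding correction rescales the accuracy denominator
  st4 <- lr_statistics(w, w, ids, mean_F = 0.5, sigma2_u = 2)
  expect_equal(st4$accuracy, 2 * st$accuracy, tolerance = 1e-12)
})

test_that("LR statistics are shift-equivariant and scale as expected", {
  set.seed(20)
  ids <- paste0("f", 1:80)
  w <- setNames(rnorm(80), ids)
  p <- 0.8 * w + setNames(rnorm(80, sd = 0.3), ids)
  base <- lr_statistics(w, p, ids, sigma2_u = 1)
  # shifting the partial predictions moves only the bias
  sh <- lr_statistics(w, p + 3, ids, sigma2_u = 1)
  expect_equal(sh$bias, base$bias + 3, tolerance = 1e-12)
  expect_equal(sh$accuracy, base$accuracy, tolerance = 1e-12)
  expect_equal(sh$dispersion, base$dispersion, tolerance = 1e-12)
  # shifting both leaves everything unchanged
  sh2 <- lr_statistics(w + 5, p + 5, ids, sigma2_u = 1)
  expect_equal(sh2$bias, base$bias, tolerance = 1e-12)
  expect_equal(sh2$dispersion, base$dispersion, tolerance = 1e-12)
  # constant partial predictions have undefined dispersion
  st0 <- lr_statistics(w, setNames(rep(1, 80), ids), ids, sigma2_u = 1)
  expect_false(st0$dispersion_defined)
  expect_true(is.na(st0$dispersion))
  expect_error(lr_statistics(w, p, "f1", sigma2_u = 1), "at least 2")
  expect_error(lr_statistics(w, p, c("f1", "nope"), sigma2_u = 1), "cover")
})

test_that("genetic parameter ratios reproduce the study trait table", {
  gp <- genetic_parameters(trait_vc("BWT"))
  expect_equal(gp$sigma2_p, 0.609)
  expect_equal(gp$h2, round(0.085 / 0.609, 3))
  expect_equal(gp$hm2, round(0.091 / 0.609, 3))
  expect_equal(gp$c2, 0.100)
  gp_yfd <- genetic_parameters(trait_vc("YFD"))
  expect_equal(gp_yfd$sigma2_p, 2.300)
  expect_equal(gp_yfd$h2, 0.570)
  expect_equal(gp_yfd$hm2, 0)
  gp_nlb <- genetic_parameters(trait_vc("NLB"))
  expect_equal(gp_nlb$sigma2_p, 0.284)
  expect_equal(gp_nlb$h2, 0.088)
  expect_equal(gp_nlb$pe2, round(0.009 / 0.284, 3))
})

test_that("the scenario grid enumerates 13 scenarios per trait, 78 overall", {
  g <- scenario_grid()
  expect_equal(nrow(g), 13)
  expect_equal(sum(g$predictor == "A-BLUP"), 1)
  expect_equal(sum(g$predictor == "H-BLUP"), 2)
  expect_equal(sum(g$predictor == "HAP-BLUP"), 10)
  expect_false(any(duplicated(g$scenario_id)))
  # deterministic ordering regardless of input order
  expect_identical(g, scenario_grid(alphas = c(0.50, 0.95),
                                    ld_thresholds = c(0.80, 0.15, 0.50,
                                                      0.35, 0.65)))
  traits <- c("BWT", "PWT", "YWT", "YFD", "YGFW", "NLB")
  g6 <- scenario_grid(traits = traits)
  expect_equal(nrow(g6), 78)
  expect_equal(unique(g6$trait), traits)
  expect_equal(as.integer(table(g6$trait)), rep(13L, 6))
})

test_that("whole/partial splitting removes exactly the right records", {
  pop <- demo_pop()
  ped <- pop$ped
  recs <- pop$records
  cutoff <- demo_cutoff()
  sp <- suppressWarnings(split_whole_partial(recs, pop$genotyped_ids, ped,
                                             cutoff, min_focal = 2,
                                             min_share = 0))
  expect_s3_class(sp, "data_split")
  expect_equal(nrow(sp$whole), nrow(recs))
  bd <- setNames(ped$birth_date, ped$id)
  # oracle recount: records kept are those of animals born on/before the
  # cutoff whose dam/sire is not focal
  parent_pairs <- rbind(data.frame(c = ped$id, p = ped$sire),
                        data.frame(c = ped$id, p = ped$dam))
  parent_pairs <- parent_pairs[!is.na(parent_pairs$p), ]
  late <- recs$animal_id %in% names(bd)[!is.na(bd) & bd > cutoff]
  prog <- recs$animal_id %in%
    parent_pairs$c[parent_pairs$p %in% sp$focal_ids]
  expect_equal(nrow(sp$partial), sum(!(late | prog |
                                         recs$animal_id %in% sp$focal_ids)))
  # no focal animal retains an own record in the partial data
  expect_false(any(sp$partial$animal_id %in% sp$focal_ids))
  # every focal animal is genotyped, born after the cutoff, and linked to
  # phenotypes in the whole data
  expect_true(all(sp$focal_ids %in% as.character(pop$genotyped_ids)))
  expect_true(all(bd[sp$focal_ids] > cutoff))
  own_or_prog <- union(unique(recs$animal_id),
                       unique(parent_pairs$p[parent_pairs$c %in%
                                               recs$animal_id]))
  expect_true(all(sp$focal_ids %in% own_or_prog))
  expect_equal(sp$diagnostics$n_focal, length(sp$focal_ids))
  # unmet reporting criteria warn rather than fail
  expect_warning(split_whole_partial(recs, pop$genotyped_ids, ped, cutoff,
                                     min_focal = 1e6, min_share = 0),
                 "focal individuals")
  expect_error(split_whole_partial(recs, pop$genotyped_ids, ped,
                                   as.Date("2999-01-01")), "no focal")
})

test_that("run_evaluation covers the grid and reduces to A-BLUP at alpha 0", {
  pop <- demo_pop()
  bundle <- list(ped = pop$ped, markers = pop$markers,
                 genotyped_ids = pop$genotyped_ids,
                 records_by_trait = list(PWT = pop$records),
                 vc_by_trait = list(PWT = var_comp(0.3, 0.7)),
                 model_by_trait = list(PWT = "additive"),
                 cutoff_date = demo_cutoff())
  grid <- scenario_grid(alphas = 0.95, ld_thresholds = 0.15)
  res <- run_evaluation(grid, bundle)
  expect_equal(nrow(res), nrow(grid))
  expect_equal(res$scenario_id, grid$scenario_id)
  expect_true(all(is.finite(res$accuracy)))
  expect_true(all(is.finite(res$dispersion)))
  expect_true(all(res$mean_ta_whole > 0 & res$mean_ta_whole < 1))
  # determinism: a second run reproduces the numbers exactly
  res2 <- run_evaluation(grid, bundle)
  expect_identical(res, res2)
  # alpha = 0 genomic scenarios collapse to the pedigree predictor
  grid0 <- scenario_grid(alphas = c(0.95, 0), ld_thresholds = 0.35)
  res0 <- run_evaluation(grid0[grid0$predictor != "HAP-BLUP", ], bundle,
                         compute_ta = FALSE)
  a_row <- res0[res0$predictor == "A-BLUP", ]
  h0_row <- res0[res0$predictor == "H-BLUP" & res0$alpha == 0, ]
  expect_equal(h0_row$accuracy, a_row$accuracy, tolerance = 1e-6)
  expect_equal(h0_row$bias, a_row$bias, tolerance = 1e-6)
  expect_equal(h0_row$dispersion, a_row$dispersion, tolerance = 1e-6)
})
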