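test_that("two unrelated animals solve the closed-form shrinkage", {
  ped <- as_pedigree(data.frame(id = c("a", "b"), sire = NA, dam = NA))
  recs <- data.frame(animal_id = c("a", "b"), value = c(10, 14))
  # lambda = sigma2_e / sigma2_u = 3: u_i = (y_i - ybar) / (1 + lambda)
  fit <- ssgblup(recs, ped, vc = var_comp(1, 3))
  expect_equal(fit$mu, 12, tolerance = 1e-10)
  expect_equal(unname(fit$u[c("a", "b")]), c(-0.5, 0.5), tolerance = 1e-10)
})

test_that("constant phenotypes give zero breeding values", {
  ped <- fullsib_ped()
  recs <- data.frame(animal_id = ped$id, value = 7)
  fit <- ssgblup(recs, ped, vc = var_comp(1, 2))
  expect_equal(fit$mu, 7, tolerance = 1e-10)
  expect_lt(max(abs(fit$u)), 1e-10)
})

test_that("MME solutions match the dense GLS oracle for all three models", {
  pop <- demo_pop()
  ped <- pop$ped
  set.seed(14)
  take <- sort(sample(nrow(ped), 120))
  sub_ids <- ped$id[take]
  # closed subset: keep the subset plus all its ancestors
  keep <- rep(FALSE, nrow(ped))
  keep[take] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      keep[match(ped$sire[i], ped$id, nomatch = 0)] <- TRUE
      keep[match(ped$dam[i], ped$id, nomatch = 0)] <- TRUE
    }
  }
  sped <- as_pedigree(ped[keep, c("id", "sire", "dam")])

  vc1 <- var_comp(1.2, 2.5)
  recs <- data.frame(animal_id = sped$id,
                     value = rnorm(nrow(sped), 20, 2))
  fit <- ssgblup(recs, sped, vc1, model = "additive")
  oracle <- gls_blup(sped, recs, vc1, "additive")
  expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(fit$u[sped$id], oracle$u[sped$id], tolerance = 1e-6)

  vc2 <- var_comp(1.2, 2.5, sigma2_pe = 0.6)
  reps <- recs[rep(seq_len(60), each = 2), ]
  reps$value <- reps$value + rnorm(nrow(reps))
  fit2 <- ssgblup(reps, sped, vc2, model = "repeatability")
  oracle2 <- gls_blup(sped, reps, vc2, "repeatability")
  expect_equal(fit2$mu, oracle2$mu, tolerance = 1e-8)
  expect_equal(fit2$u[sped$id], oracle2$u[sped$id], tolerance = 1e-6)

  vc3 <- var_comp(1.2, 2.5, sigma2_m = 0.8, sigma2_q = 0.4)
  fit3 <- ssgblup(recs, sped, vc3, model = "maternal")
  oracle3 <- gls_blup(sped, recs, vc3, "maternal")
  expect_equal(fit3$mu, oracle3$mu, tolerance = 1e-8)
  expect_equal(fit3$u[sped$id], oracle3$u[sped$id], tolerance = 1e-6)
  expect_equal(fit3$m[sped$id], oracle3$m[sped$id], tolerance = 1e-6)
  # records on animals with unknown dams are dropped and counted
  n_unknown <- sum(is.na(sped$dam[match(recs$animal_id, sped$id)]))
  expect_equal(fit3$dropped_records, n_unknown)
})

test_that("single-step fits equal GLS on the dense H covariance", {
  ped <- fullsib_ped()
  A <- build_nrm(ped)
  gids <- c("3", "4", "5")
  parts <- extract_a22(ped, gids)
  set.seed(16)
  M <- matrix(rnorm(3 * 50), 3)
  G <- tcrossprod(M) / 50 + 0.5 * parts$a22
  dimnames(G) <- list(gids, gids)
  Gw <- blend_g(G, parts$a22, 0.95)
  h <- h_inverse(nrm_inverse(ped), parts, G, alpha = 0.95)
  recs <- data.frame(animal_id = ped$id, value = c(9, 11, 10, 13, 12))
  vc <- var_comp(1, 1.5)
  fit <- ssgblup(recs, ped, vc, hinv = h)
  oracle <- gls_blup(ped, recs, vc, "additive", K = dense_h(A, gids, Gw))
  expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(fit$u[ped$id], oracle$u[ped$id], tolerance = 1e-8)
  expect_equal(fit$relationship, "H")
  expect_equal(fit$alpha, 0.95)
})

test_that("PEV equals sigma2_e times the coefficient-matrix inverse diagonal", {
  ped <- fullsib_ped()
  recs <- data.frame(animal_id = ped$id, value = c(9, 11, 10, 13, 12))
  vc <- var_comp(1, 2)
  fit <- ssgblup(recs, ped, vc, pev_ids = ped$id)
  sys <- ssgblup:::build_mme(ped, recs, recs$value, "additive", vc,
                             nrm_inverse(ped))
  Ci <- solve(as.matrix(sys$C))
  u_idx <- 1 + seq_len(nrow(ped))    # one fixed effect, then the u block
  expect_equal(unname(fit$pev_u[ped$id]),
               vc$sigma2_e * diag(Ci)[u_idx], tolerance = 1e-8)
  # PEV is bounded by the prior variance (1 + f) sigma2_u
  f <- inbreeding(ped)
  expect_true(all(fit$pev_u > 0))
  expect_true(all(fit$pev_u < (1 + f[names(fit$pev_u)]) * vc$sigma2_u))
  expect_error(ssgblup(recs, ped, vc, pev_ids = "zz"), "pev ids")
})

test_that("theoretical accuracy follows the reliability conversion", {
  ta <- theoretical_accuracy(c(a = 0.75), sigma2_u = 1)
  expect_equal(as.numeric(ta), 0.5)
  expect_equal(as.numeric(theoretical_accuracy(c(a = 0.75), sigma2_u = 1,
                                               squared = TRUE)), 0.25)
  # inbreeding raises the ceiling: pev = 1, f = 0.25 -> 1 - 1/1.25 = 0.2
  ta2 <- theoretical_accuracy(c(a = 1), f = c(a = 0.25), sigma2_u = 1,
                              squared = TRUE)
  expect_equal(as.numeric(ta2), 0.2, tolerance = 1e-12)
  # pev at/above the ceiling clamps to zero and is counted
  ta3 <- theoretical_accuracy(c(a = 1.4, b = 0.5), sigma2_u = 1)
  expect_equal(as.numeric(ta3), c(0, sqrt(0.5)))
  expect_equal(attr(ta3, "clamped"), 1L)
  expect_error(theoretical_accuracy(0.5, sigma2_u = 0), "positive")
})

test_that("the conjugate-gradient solver reproduces the direct solutions", {
  pop <- demo_pop()
  recs <- pop$records
  vc <- var_comp(0.3, 0.7)
  direct <- ssgblup(recs, pop$ped, vc)
  pcg <- ssgblup(recs, pop$ped, vc, method = "pcg")
  expect_true(pcg$converged)
  expect_equal(pcg$u, direct$u, tolerance = 1e-5)
  expect_equal(pcg$mu, direct$mu, tolerance = 1e-5)
  expect_error(ssgblup(recs, pop$ped, vc, method = "pcg",
                       pev_ids = pop$ped$id[1]), "direct solver")
})

test_that("study trait tables map to the documented components and models", {
  vc <- trait_vc("BWT")
  expect_equal(vc$sigma2_u, 0.085)
  expect_equal(vc$sigma2_m, 0.091)
  expect_equal(vc$sigma2_q, 0.061)
  expect_equal(vc$sigma2_e, 0.372)
  expect_equal(trait_vc("YFD")$sigma2_e, 0.989)
  expect_equal(trait_vc("NLB")$sigma2_pe, 0.009)
  expect_equal(trait_model("YFD"), "additive")
  expect_equal(trait_model("NLB"), "repeatability")
  expect_equal(trait_model("PWT"), "maternal")
  expect_equal(trait_model("BWT"), "maternal")
  expect_error(trait_vc("XXX"))
  expect_error(var_comp(1, 0))
  expect_error(var_comp(-1, 1))
})

test_that("genetically disconnected units show higher VED", {
  set.seed(18)
  # two half-sib families, each recorded in both units -> connected
  make_fam <- function(tag, n_off = 20) {
    data.frame(id = c(paste0(tag, "_s"), paste0(tag, "_", seq_len(n_off))),
               sire = c(NA, rep(paste0(tag, "_s"), n_off)),
               dam = NA_character_)
  }
  ped <- as_pedigree(rbind(make_fam("f1"), make_fam("f2")))
  off <- ped$id[!is.na(ped$sire)]
  vc <- var_comp(1, 2)
  tbv <- rnorm(length(off))
  recs <- data.frame(animal_id = off, value = 10 + tbv,
                     unit = rep(c("u1", "u2"), length.out = length(off)))
  conn <- connectedness_ved(ped, recs, vc = vc, unit_col = "unit")
  # disconnected: family 1 only in unit 1, family 2 only in unit 2
  recs2 <- recs
  recs2$unit <- ifelse(startsWith(recs2$animal_id, "f1"), "u1", "u2")
  disc <- connectedness_ved(ped, recs2, vc = vc, unit_col = "unit")
  expect_lt(conn$mean, disc$mean)
  expect_equal(diag(conn$ved), c(u1 = 0, u2 = 0))
  expect_equal(conn$ved, t(conn$ved))
  expect_error(connectedness_ved(ped, transform(recs, unit = "u1"),
                                 vc = vc, unit_col = "unit"), "2 units")
})

test_that("ssgblup S3 methods are coherent", {
  ped <- fullsib_ped()
  recs <- data.frame(animal_id = ped$id, value = c(9, 11, 10, 13, 12))
  fit <- ssgblup(recs, ped, var_comp(1, 2), pev_ids = ped$id)
  expect_output(print(fit), "additive model")
  expect_output(print(summary(fit)), "A-BLUP")
  expect_equal(coef(fit), fit$u)
  expect_equal(predict(fit, c("3", "5")), fit$u[c("3", "5")])
  expect_error(predict(fit, "zz"), "unknown animal")
  expect_error(predict(fit, type = "maternal"), "no maternal")
  expect_equal(residuals(fit),
               recs$value - fit$mu - unname(fit$u[recs$animal_id]))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_solutions(fit, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), 5)
  expect_equal(back$solution, unname(fit$u[as.character(back$animal_id)]))
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
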