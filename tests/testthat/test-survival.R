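# Seroconversion endpoints, KM incidence, log-rank, Cox models and the
# proportional-hazards diagnostic.

test_that("endpoint derivation follows the visit-time crossing rules", {
  # GADA crosses at the third visit (t = 0.75), others never
  p <- toy_panel(visits = c(0.25, 0.5, 0.75, 1.0),
                 GADA = c(1, 2, 15, 20), IAA = c(1, 1, 1, 1),
                 IA2A = c(2, 2, 2, 2))
  ov <- derive_seroconversion(p, "overall")
  expect_equal(ov$time, 0.75)
  expect_equal(ov$event, 1L)
  ga <- derive_seroconversion(p, "GADA")
  expect_equal(ga$time, 0.75)
  iaa <- derive_seroconversion(p, "IAA")
  expect_equal(iaa$event, 0L)
  expect_equal(iaa$time, 1.0)   # censored at last contact
  dbl <- derive_seroconversion(p, "double")
  expect_equal(dbl$event, 0L)

  # GADA at 0.5, IAA at 1.0: double seroconversion at the second crossing
  p2 <- toy_panel(visits = c(0.25, 0.5, 0.75, 1.0),
                  GADA = c(1, 15, 15, 15), IAA = c(1, 1, 1, 12),
                  IA2A = c(1, 1, 1, 1))
  expect_equal(derive_seroconversion(p2, "overall")$time, 0.5)
  d2 <- derive_seroconversion(p2, "double")
  expect_equal(d2$time, 1.0)
  expect_equal(d2$event, 1L)
})

test_that("threshold crossing is strict", {
  p <- toy_panel(visits = c(0.5, 1), GADA = c(10, 10), IAA = c(1, 1),
                 IA2A = c(1, 1))   # exactly at threshold: never positive
  expect_equal(derive_seroconversion(p, "GADA")$event, 0L)
})

test_that("panel validation rejects malformed input", {
  dat <- data.frame(id = "P1", visit_time = c(1, 1), GADA = 1, IAA = 1,
                    IA2A = 1)
  expect_error(antibody_panels(dat, c(GADA = 1, IAA = 1, IA2A = 1)),
               "strictly increasing")
  expect_error(antibody_panels(dat[0, ], c(GADA = 1, IAA = 1)),
               "thresholds")
})

test_that("overall is the minimum of antibody-specific endpoints", {
  sim <- simulate_cohort(cohort_sim_config(n = 400L, seed = 88L))
  outs <- lapply(c("overall", "GADA", "IAA", "IA2A"),
                 function(d) derive_seroconversion(sim$panels, d))
  names(outs) <- c("overall", "GADA", "IAA", "IA2A")
  spec_min <- pmin(ifelse(outs$GADA$event == 1, outs$GADA$time, Inf),
                   ifelse(outs$IAA$event == 1, outs$IAA$time, Inf),
                   ifelse(outs$IA2A$event == 1, outs$IA2A$time, Inf))
  ov <- ifelse(outs$overall$event == 1, outs$overall$time, Inf)
  expect_equal(ov, spec_min)
  dbl <- derive_seroconversion(sim$panels, "double")
  dblt <- ifelse(dbl$event == 1, dbl$time, Inf)
  expect_true(all(dblt >= ov))
})

test_that("KM incidence matches hand-computed product-limit values", {
  # 2 subjects, events at 1 and 2, no censoring
  ki <- km_incidence(data.frame(time = c(1, 2), event = c(1L, 1L)))
  expect_equal(ki$incidence[ki$time == 1], 0.5)
  expect_equal(ki$incidence[ki$time == 2], 1.0)
  # all censored: incidence identically zero
  ki0 <- km_incidence(data.frame(time = c(1, 2, 3), event = 0L))
  expect_true(all(ki0$incidence == 0))
  # mixed five-subject table: event 1, censor 1.5, event 2, censor 2.5, event 3
  # S(1) = 4/5; S(2) = 4/5 * 2/3; S(3) = 4/5 * 2/3 * 0
  ki5 <- km_incidence(data.frame(time = c(1, 1.5, 2, 2.5, 3),
                                 event = c(1L, 0L, 1L, 0L, 1L)))
  expect_equal(ki5$incidence[ki5$time == 1], 1 - 4 / 5)
  expect_equal(ki5$incidence[ki5$time == 2], 1 - 4 / 5 * 2 / 3)
  expect_equal(ki5$incidence[ki5$time == 3], 1)
  # monotone, right bounded
  expect_false(is.unsorted(ki5$incidence))
  expect_true(all(ki5$incidence >= 0 & ki5$incidence <= 1))
})

test_that("log-rank: identical groups give chi2 = 0, separated groups reject", {
  base <- data.frame(time = c(1, 2, 3, 4, 6, 8), event = c(1L, 1L, 0L, 1L, 1L, 0L))
  dup <- rbind(base, base)
  lr <- logrank_test(dup, rep(c("g1", "g2"), each = 6))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # all of A before any B, no censoring
  sep <- data.frame(time = c(1:20, 31:50), event = 1L)
  lr2 <- logrank_test(sep, rep(c("A", "B"), each = 20))
  expect_lt(lr2$p, 0.01)
  expect_equal(lr2$df, 1L)
  expect_error(logrank_test(base, rep("g1", 6)), "two non-empty groups")
})

test_that("log-rank asymptotic p agrees with a permutation oracle", {
  set.seed(505)
  n <- 30
  outc <- data.frame(time = rexp(n, 0.2), event = rbinom(n, 1L, 0.8))
  grp <- rep(c("a", "b"), each = 15)
  chi_obs <- logrank_test(outc, grp)$chi2
  perm <- replicate(2000, logrank_test(outc, sample(grp))$chi2)
  p_perm <- mean(perm >= chi_obs)
  p_asym <- logrank_test(outc, grp)$p
  expect_lt(abs(p_perm - p_asym), 3 * sqrt(p_asym * (1 - p_asym) / 2000) + 0.02)
})

test_that("cox_fit matches the brute-force partial-likelihood oracle", {
  # fixed 6-subject instance, one binary covariate, no ties
  outc <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                     event = c(1L, 1L, 0L, 1L, 1L, 1L))
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(outc, data.frame(x = x))
  beta_star <- partial_likelihood_argmax(outc$time, outc$event, x)
  expect_equal(fit$coef, beta_star, tolerance = 1e-6)
  expect_equal(fit$HR, exp(fit$coef))
  expect_equal(fit$Z, fit$coef / fit$SE)
  # empty design: empty result
  expect_equal(nrow(cox_fit(outc, NULL)), 0L)
  # separation: perfectly predictive covariate errors with the term name
  outs <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                     event = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  xs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(cox_fit(outs, data.frame(bad = xs)), "bad")
})

test_that("one-vs-rest on two complementary categories is antisymmetric", {
  td <- toy_cox_data(n = 120, beta = 0.8, seed = 506)
  cohort <- data.frame(id = seq_len(120),
                       drb1_1 = ifelse(td$x == 1, "DRB1*04:01", "DRB1*03:01"),
                       drb1_2 = ifelse(td$x == 1, "DRB1*04:01", "DRB1*03:01"),
                       stringsAsFactors = FALSE)
  res <- cox_one_vs_rest(cohort, td$outcomes, function(a) a, adjusters = NULL)
  expect_equal(nrow(res), 2L)
  expect_equal(res$coef[1], -res$coef[2], tolerance = 1e-8)
  expect_error(cox_one_vs_rest(cohort, td$outcomes, function(a) a,
                               adjusters = NULL, categories = "DRB1*07:01"),
               "carried by nobody")
})

test_that("multivariable reference model and dose model run end to end", {
  set.seed(507)
  sim <- simulate_cohort(cohort_sim_config(n = 1500L, seed = 507L))
  outc <- derive_seroconversion(sim$panels, "overall")
  outc <- outc[match(sim$subjects$id, outc$id), ]
  cat4 <- dr4_fixture_catalog()
  mapper <- motif_mapper(cat4, c(71, 74, 86))
  groups <- list(KAG = "KAG", RAV = "RAV", DR3 = c("KRV", "KRG"),
                 OTH = c("EAV", "RAG", "REG", "REV", "KAV", "OTHER"))
  res <- cox_multivar_reference(sim$subjects, outc, groups, "DR3", mapper)
  expect_true(all(res$term %in% c("KAG", "RAV", "OTH")))
  expect_true(all(res$HR > 0))
  # reference-only cohort: empty result
  mot1 <- vapply(sim$subjects$drb1_1, mapper, character(1))
  mot2 <- vapply(sim$subjects$drb1_2, mapper, character(1))
  ref_only <- sim$subjects[mot1 %in% c("KRV", "KRG") &
                             mot2 %in% c("KRV", "KRG"), ]
  res0 <- cox_multivar_reference(ref_only,
                                 outc[match(ref_only$id, sim$subjects$id), ],
                                 groups["DR3"], "DR3", mapper)
  expect_equal(nrow(res0), 0L)

  is_kag <- function(a) mapper(a) == "KAG"
  dose <- genotype_dose_assoc(sim$subjects, outc, is_kag)
  expect_setequal(dose$term, c("het", "hom"))
  km <- attr(dose, "km")
  expect_true(all(c("other/other", "motif/other", "motif/motif") %in%
                    km$genotype))
  # incidence curves nondecreasing within genotype
  for (g in unique(km$genotype)) {
    expect_false(is.unsorted(km$incidence[km$genotype == g]))
  }
})

test_that("dose model drops the homozygote term when none exist", {
  td <- toy_cox_data(n = 60, beta = 0.5, seed = 508)
  cohort <- data.frame(id = seq_len(60),
                       drb1_1 = ifelse(td$x == 1, "DRB1*04:01", "DRB1*03:01"),
                       drb1_2 = "DRB1*03:01", stringsAsFactors = FALSE)
  expect_message(
    res <- genotype_dose_assoc(cohort, td$outcomes,
                               function(a) a == "DRB1*04:01",
                               adjusters = NULL),
    "no homozygote")
  expect_equal(res$term, "het")
})

test_that("PH diagnostic: needs two events, flags a time-varying effect", {
  one_ev <- data.frame(time = c(1, 2, 3), event = c(1L, 0L, 0L))
  fit <- cox_fit(one_ev, data.frame(x = c(0.5, 1, 0)))
  expect_error(ph_diagnostic(fit), "two events")
  p <- experiment_ph_power(n = 600L, seed = 509L)
  expect_lt(p, 0.01)
})
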