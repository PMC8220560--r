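# Synthetic allele pools, case-control and cohort generators.

test_that("allele pool construction validates and plants structure", {
  expect_error(
    make_allele_pool(positions = 1:20, screening_positions = c(5, 10),
                     motifs = c("X*01:01" = "KAG")),
    "motif length")
  pool <- make_allele_pool(n_cluster_alleles = 4L, n_outgroup_alleles = 3L,
                           positions = 1:60, screening_positions = c(10, 20, 30),
                           seed = 99L)
  expect_equal(nrow(pool$seq), 7L)
  dm <- pairwise_distances(pool)
  clu <- grep("^CLU", rownames(dm$d), value = TRUE)
  out <- grep("^OUT", rownames(dm$d), value = TRUE)
  max_within <- max(dm$d[clu, clu])
  min_between <- min(dm$d[clu, out])
  expect_lt(max_within, min_between)
  # no outgroup: the whole catalog is one tight cluster
  pool0 <- make_allele_pool(n_cluster_alleles = 3L, n_outgroup_alleles = 0L,
                            positions = 1:30, screening_positions = c(5, 6),
                            seed = 100L)
  expect_equal(nrow(pool0$seq), 3L)
})

test_that("case-control generator is deterministic and honors quotas", {
  cfg <- casecontrol_sim_config(n_case = 150L, n_ctrl = 100L, seed = 321L)
  s1 <- simulate_case_control(cfg)
  s2 <- simulate_case_control(cfg)
  expect_identical(s1, s2)
  expect_equal(sum(s1$y == 1L), 150L)
  expect_equal(sum(s1$y == 0L), 100L)
  # different seed, different draw
  s3 <- simulate_case_control(casecontrol_sim_config(n_case = 150L, n_ctrl = 100L,
                                             seed = 322L))
  expect_false(identical(s1$drb1_1, s3$drb1_1))
  # latent sidecar rides along but carries no analysis input
  expect_true(!is.null(attr(s1, "latent")))
  expect_setequal(names(attr(s1, "latent")), c("id", "lp", "p"))
  # antibody flags exist for cases only
  expect_true(all(is.na(s1$GADA[s1$y == 0L])))
  expect_true(all(s1$GADA[s1$y == 1L] %in% 0:1))
})

test_that("generated allele frequencies converge to the configuration", {
  # with no motif effects, case/control sampling does not distort the
  # chromosome frequencies; 100k chromosomes pin them to within 3 SE
  cfg <- casecontrol_sim_config(n_case = 25000L, n_ctrl = 25000L, effects = c(KAG = 0),
                        antibody_models = list(), seed = 777L)
  subj <- simulate_case_control(cfg)
  chroms <- c(subj$drb1_1, subj$drb1_2)
  n_chr <- length(chroms)
  for (al in names(cfg$freqs)) {
    f_hat <- mean(chroms == al)
    se <- sqrt(cfg$freqs[[al]] * (1 - cfg$freqs[[al]]) / n_chr)
    expect_lt(abs(f_hat - cfg$freqs[[al]]), 3 * se + 1e-9)
  }
})

test_that("null effects give odds ratios centered at one", {
  cfg <- casecontrol_sim_config(n_case = 1500L, n_ctrl = 1500L, effects = c(KAG = 0),
                        antibody_models = list(), seed = 88L)
  subj <- simulate_case_control(cfg)
  tab <- motif_assoc_table(subj, cfg$catalog, cfg$motif_positions,
                           cluster = dr4_cluster_alleles())
  ors <- tab$OR[!is.na(tab$OR) & tab$n_case + tab$n_ctrl >= 30]
  expect_lt(abs(mean(log(ors))), 0.25)
})

test_that("cohort generator is deterministic with a faithful latent sidecar", {
  cfg <- cohort_sim_config(n = 500L, seed = 246L)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$subjects, sim2$subjects)
  expect_identical(sim1$panels$data, sim2$panels$data)
  lat <- attr(sim1, "latent")
  expect_setequal(names(lat),
                  c("id", "GADA", "IAA", "IA2A", "lp", "last_contact"))
  # derived event time is the first scheduled visit at or after the
  # latent crossing, for every subject and antibody
  for (ab in c("GADA", "IAA", "IA2A")) {
    outc <- derive_seroconversion(sim1$panels, ab)
    outc <- outc[match(lat$id, outc$id), ]
    expected_idx <- findInterval(lat[[ab]], cfg$schedule,
                                 left.open = TRUE) + 1L
    has_event <- lat[[ab]] <= lat$last_contact
    expect_equal(outc$event == 1L, unname(has_event))
    expect_equal(outc$time[has_event],
                 cfg$schedule[expected_idx[has_event]])
  }
})

test_that("covariates follow the configured design", {
  sim <- simulate_cohort(cohort_sim_config(n = 4000L, seed = 135L))
  s <- sim$subjects
  expect_true(all(s$sex %in% 0:1))
  expect_lt(abs(mean(s$family_history) - 0.10), 0.02)
  expect_setequal(unique(s$location), c("north", "south", "east", "west"))
  expect_equal(nrow(sim$panels$last_contact), 4000L)
})

test_that("zero baseline hazards yield a fully censored cohort", {
  cfg <- cohort_sim_config(n = 120L, p10 = c(GADA = 0, IAA = 0, IA2A = 0),
                          seed = 99L)
  sim <- simulate_cohort(cfg)
  for (d in c("overall", "double", "GADA", "IAA", "IA2A")) {
    outc <- derive_seroconversion(sim$panels, d)
    expect_true(all(outc$event == 0L))
    expect_equal(outc$time, sim$panels$last_contact$last_contact)
  }
})

test_that("the deterministic reference sample is reproducible and sized", {
  s1 <- dr4_reference_sample()
  s2 <- dr4_reference_sample()
  expect_identical(s1, s2)
  expect_equal(sum(s1$y == 1L), 962L)
  expect_equal(sum(s1$y == 0L), 636L)
  # exactly one chromosome carries the rare 04:06
  expect_equal(sum(c(s1$drb1_1, s1$drb1_2) == "DRB1*04:06"), 1L)
})
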