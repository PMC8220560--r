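# Chromosome counts, score test, virtual-reference OR, Fisher
# comparison, residue screening, motif and antibody association.

test_that("chromosome counts: each subject contributes two chromosomes", {
  subj <- toy_subjects(y = c(1L, 0L),
                       a1 = c("A*01:01", "A*01:01"),
                       a2 = c("A*01:01", "A*01:02"))
  cc <- chromosome_counts(subj, function(a) a)
  expect_equal(cc$f_case[cc$category == "A*01:01"], 1.0)
  expect_equal(cc$f_ctrl[cc$category == "A*01:01"], 0.5)
  expect_equal(sum(cc$f_case), 1)
  expect_equal(sum(cc$f_ctrl), 1)
})

test_that("chromosome counts agree with a brute-force tally", {
  set.seed(401)
  alleles <- c("A*01:01", "A*01:02", "A*02:01", "A*03:01")
  subj <- toy_subjects(y = rbinom(200, 1, 0.5),
                       a1 = sample(alleles, 200, TRUE),
                       a2 = sample(alleles, 200, TRUE))
  cc <- chromosome_counts(subj, function(a) a)
  for (al in alleles) {
    for (grp in 0:1) {
      tally <- 0L
      for (i in seq_len(nrow(subj))) {
        if (subj$y[i] == grp) {
          tally <- tally + (subj$drb1_1[i] == al) + (subj$drb1_2[i] == al)
        }
      }
      col <- if (grp == 1) "n_case" else "n_ctrl"
      expect_equal(cc[[col]][cc$category == al], tally)
    }
  }
})

test_that("frequencies sum to one under every mapper", {
  cat4 <- dr4_fixture_catalog()
  subj <- dr4_reference_sample()
  dr4 <- dr4_cluster_alleles()
  for (cc in list(
    chromosome_counts(subj, allele_mapper()),
    chromosome_counts(subj, motif_mapper(cat4, c(71, 74, 86), dr4)),
    chromosome_counts(subj, residue_mapper(cat4, 57L, dr4),
                      drop_unmapped = TRUE))) {
    expect_equal(sum(cc$f_case), 1)
    expect_equal(sum(cc$f_ctrl), 1)
  }
})

test_that("score test: constant dosage gives Z = 0, p = 1", {
  y <- rep(c(1, 0), each = 10)
  st <- score_test(y, rep(2, 20))
  expect_equal(st$Z, 0)
  expect_equal(st$p, 1)
})

test_that("score test equals the Cochran-Armitage trend statistic", {
  # balanced toy table: 10 cases all dosage 2, 10 controls all dosage 0
  y <- rep(c(1, 0), each = 10)
  d <- rep(c(2, 0), each = 10)
  st <- score_test(y, d)
  # hand-computed: U = 10, V = 0.25 * (40 - 400/20) = 5
  expect_equal(st$U, 10)
  expect_equal(st$V, 5)
  expect_equal(st$Z, trend_statistic(y, d), tolerance = 1e-12)

  set.seed(402)
  for (r in 1:25) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5)
    d <- rbinom(n, 2, runif(1, 0.2, 0.8))
    if (var(d) == 0 || var(y) == 0) next
    zt <- trend_statistic(y, d)
    st <- score_test(y, d)
    expect_equal(st$Z^2, zt^2, tolerance = 1e-8)
  }
})

test_that("an intercept-duplicating covariate leaves the score unchanged", {
  set.seed(403)
  y <- rbinom(60, 1, 0.5)
  d <- rbinom(60, 2, 0.4)
  st0 <- score_test(y, d)
  st1 <- score_test(y, d, covariates = data.frame(one = rep(1, 60)))
  expect_equal(st1$Z, st0$Z, tolerance = 1e-10)
})

test_that("score test adjusts for a real covariate", {
  set.seed(404)
  n <- 400
  x <- rnorm(n)
  d <- rbinom(n, 2, plogis(x))          # dosage correlated with covariate
  y <- rbinom(n, 1, plogis(-0.5 + x))   # outcome driven by covariate only
  st_raw <- score_test(y, d)
  st_adj <- score_test(y, d, covariates = data.frame(x = x))
  expect_true(abs(st_adj$Z) < abs(st_raw$Z))
})

test_that("virtual-reference OR is the case/control frequency ratio", {
  subj <- toy_subjects(y = rep(c(1L, 0L), each = 4),
                       a1 = c("A", "A", "A", "A", "A", "A", "B", "B"),
                       a2 = c("A", "A", "A", "B", "B", "B", "B", "B"))
  cc <- chromosome_counts(subj, function(a) a)
  res <- virtual_reference_or(cc, "A")
  expect_equal(res$OR, res$f_case / res$f_ctrl)
  # enriched in cases: positive Z, SE consistency
  expect_true(res$Z > 0)
  expect_equal(res$SE, log(res$OR) / res$Z)
  expect_equal(res$p, 2 * pnorm(-abs(res$Z)))
  # equal frequencies: OR exactly 1
  subj2 <- toy_subjects(y = c(1L, 0L), a1 = c("A", "A"), a2 = c("B", "B"))
  cc2 <- chromosome_counts(subj2, function(a) a)
  expect_equal(virtual_reference_or(cc2, "A")$OR, 1)
  # category absent in controls: flagged, no OR
  subj3 <- toy_subjects(y = c(1L, 1L, 0L), a1 = c("A", "A", "B"),
                        a2 = c("A", "B", "B"))
  cc3 <- chromosome_counts(subj3, function(a) a)
  res3 <- virtual_reference_or(cc3, "A")
  expect_true(is.na(res3$OR))
  expect_match(res3$note, "absent in controls")
})

test_that("OR is invariant to relabeling of other categories", {
  subj <- dr4_reference_sample()
  cc1 <- chromosome_counts(subj, function(a) a)
  lump <- function(a) if (a == "DRB1*04:01") a else "REST"
  cc2 <- chromosome_counts(subj, lump)
  expect_equal(virtual_reference_or(cc1, "DRB1*04:01")$OR,
               virtual_reference_or(cc2, "DRB1*04:01")$OR)
})

test_that("Fisher comparison of two categories", {
  mk <- function(nA1, nA0, nB1, nB0) {
    structure(data.frame(category = c("A", "B"),
                         n_case = c(nA1, nB1), n_ctrl = c(nA0, nB0),
                         f_case = 1, f_ctrl = 1),
              class = c("category_counts", "data.frame"))
  }
  expect_equal(fisher_compare(mk(5, 5, 5, 5), "A", "B"), 1)
  # extreme 10/0 vs 0/10 table: p = 2 / C(20,10)
  expect_equal(fisher_compare(mk(10, 0, 0, 10), "A", "B"),
               2 / choose(20, 10), tolerance = 1e-12)
  # symmetric in the category order
  p1 <- fisher_compare(mk(8, 3, 2, 9), "A", "B")
  p2 <- fisher_compare(mk(2, 9, 8, 3), "A", "B")
  expect_equal(p1, p2)
  expect_warning(pz <- fisher_compare(mk(0, 0, 5, 5), "A", "B"), "margin")
  expect_equal(pz, 1)
})

test_that("residue screening reproduces the fixture dispositions", {
  cat4 <- dr4_fixture_catalog()
  subj <- dr4_reference_sample()
  scr <- screen_residues(cat4, dr4_cluster_alleles(), subj,
                         c(37, 57, 67, 70, 71, 74, 86))
  status <- setNames(scr$status, scr$position)
  expect_equal(status[["37"]], "near_monomorphic")
  expect_equal(status[["70"]], "collapsed_LD")
  expect_equal(scr$ld_partner[scr$position == 70], position_label(67))
  expect_equal(unname(status[c("57", "67", "71", "74", "86")]),
               rep("kept", 5))
  expect_equal(attr(scr, "rare_alleles"), "DRB1*04:06")
})

test_that("degenerate screening cases", {
  # identical alleles: everything monomorphic
  cat <- allele_catalog(c("C*01:01" = "KAG", "C*01:02" = "KAG"), 1:3)
  subj <- toy_subjects(y = rep(c(1L, 0L), 5),
                       a1 = rep("C*01:01", 10), a2 = rep("C*01:02", 10))
  scr <- screen_residues(cat, c("C*01:01", "C*01:02"), subj, 1:3)
  expect_true(all(scr$status == "monomorphic"))
  # planted bijective pair collapses, non-bijective pair does not
  cat2 <- allele_catalog(c("D*01:01" = "KAGA", "D*01:02" = "RVGA",
                           "D*01:03" = "KAVC"), 1:4)
  subj2 <- toy_subjects(y = rep(c(1L, 0L), 6),
                        a1 = rep(c("D*01:01", "D*01:02", "D*01:03"), 4),
                        a2 = rep(c("D*01:02", "D*01:03", "D*01:01"), 4))
  scr2 <- screen_residues(cat2, paste0("D*01:0", 1:3), subj2, 1:4)
  # 2 (A/V/A) is a bijection of 1 (K/R/K); 3 (G/G/V) is not a bijection
  # of 1, but 4 (A/A/C) is a bijection of 3
  expect_equal(scr2$status, c("kept", "collapsed_LD", "kept", "collapsed_LD"))
  expect_equal(scr2$ld_partner, c(NA, position_label(1), NA,
                                  position_label(3)))
})

test_that("motif table: seven cluster motifs plus OTHER, planted ORs", {
  cat4 <- dr4_fixture_catalog()
  dr4 <- dr4_cluster_alleles()
  mots <- cluster_motifs(cat4, dr4, c(71, 74, 86))
  expect_equal(sort(unique(mots)),
               c("EAV", "KAG", "KAV", "RAG", "RAV", "REG", "REV"))
  # unique correspondences asserted by the planted design
  expect_equal(unname(mots["DRB1*04:01"]), "KAG")
  expect_equal(sum(mots == "KAG"), 1L)
  expect_equal(sum(mots == "REG"), 1L)
  expect_true(all(c("DRB1*04:04", "DRB1*04:08", "DRB1*04:10") %in%
                    names(mots)[mots == "RAV"]))

  tab <- motif_assoc_table(dr4_reference_sample(), cat4, c(71, 74, 86),
                           cluster = dr4)
  expect_setequal(tab$category, c(sort(unique(mots)), "OTHER"))
  # the deterministic sample is built to carry OR 3.64 on KAG
  expect_equal(tab$OR[tab$category == "KAG"], 3.64, tolerance = 0.01)
  expect_match(tab$note[tab$category == "KAV"], "rare")
  # carriers-only restriction changes the frequency base
  tab2 <- motif_assoc_table(dr4_reference_sample(), cat4, c(71, 74, 86),
                            cluster = dr4, carriers_only = TRUE)
  expect_false("OTHER" %in% tab2$category)
  expect_equal(sum(tab2$f_case), 1)
})

test_that("single-motif population yields OR 1", {
  subj <- toy_subjects(y = rep(c(1L, 0L), each = 5),
                       a1 = rep("DRB1*04:01", 10), a2 = rep("DRB1*04:01", 10))
  tab <- motif_assoc_table(subj, dr4_fixture_catalog(), c(71, 74, 86))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$OR, 1)
})

test_that("antibody association recodes the outcome among patients", {
  cat4 <- dr4_fixture_catalog()
  # positivity strongly (not perfectly) aligned with KAG carriage
  subj <- toy_subjects(y = rep(1L, 10),
                       a1 = rep(c("DRB1*04:01", "DRB1*04:04"), each = 5),
                       a2 = rep("DRB1*03:01", 10))
  subj$IA2A <- as.integer(subj$drb1_1 == "DRB1*04:01")
  subj$IA2A[c(1, 6)] <- 1L - subj$IA2A[c(1, 6)]
  res <- antibody_assoc(subj, cat4, c(71, 74, 86), "KAG", "IA2A",
                        cluster = dr4_cluster_alleles())
  expect_true(res$OR > 1)
  # flipping every flag inverts the log-OR
  subj$IA2A <- 1L - subj$IA2A
  res2 <- antibody_assoc(subj, cat4, c(71, 74, 86), "KAG", "IA2A",
                         cluster = dr4_cluster_alleles())
  expect_equal(log(res2$OR), -log(res$OR), tolerance = 1e-12)
  # all-positive antibody is an error; controls are rejected
  subj$IA2A <- 1L
  expect_error(antibody_assoc(subj, cat4, c(71, 74, 86), "KAG", "IA2A"),
               "constant")
  subj$y[1] <- 0L
  expect_error(antibody_assoc(subj, cat4, c(71, 74, 86), "KAG", "IA2A"),
               "patients-only")
})

test_that("missing antibody measurements are excluded with a message", {
  cat4 <- dr4_fixture_catalog()
  subj <- toy_subjects(y = rep(1L, 8),
                       a1 = rep(c("DRB1*04:01", "DRB1*04:04"), 4),
                       a2 = rep("DRB1*03:01", 8))
  subj$GADA <- c(NA, 1L, 0L, 1L, 0L, 1L, 0L, NA)
  expect_message(
    res <- antibody_assoc(subj, cat4, c(71, 74, 86), "KAG", "GADA"),
    "2 patient")
  expect_s3_class(res, "data.frame")
})
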