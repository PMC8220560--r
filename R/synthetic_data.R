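# Synthetic allele pools, case-control samples and birth-cohort antibody
# panels with planted, retrievable ground truth.

#' Generate an allele catalog with a planted cluster
#'
#' Cluster alleles share a random backbone sequence and differ only at
#' the screening positions (plus any explicit extra assignments), so
#' their mutual distances are small.  Outgroup alleles mutate the
#' backbone at a fraction \code{outgroup_divergence} of mature non-
#' screening positions, so every cluster-outgroup distance exceeds every
#' within-cluster distance.
#'
#' @param n_cluster_alleles,n_outgroup_alleles Counts used when motif
#'   tables are not supplied (alleles are then auto-named).
#' @param positions Integer vector of beta positions for the alignment.
#' @param screening_positions Positions carrying the assigned residues.
#' @param motifs Named character vector: cluster allele name -> residue
#'   string over \code{screening_positions}.
#' @param outgroup_motifs Same for outgroup alleles (optional).
#' @param extra_assignments Named list: allele -> named character vector
#'   (names = beta positions) of additional residue assignments.
#' @param outgroup_divergence Fraction of mature non-screening positions
#'   mutated per outgroup allele.
#' @param seed Integer seed (generation is deterministic given it).
#' @return An \code{allele_catalog}.
#' @export
make_allele_pool <- function(n_cluster_alleles = NULL,
                             n_outgroup_alleles = NULL,
                             positions,
                             screening_positions,
                             motifs = NULL,
                             outgroup_motifs = NULL,
                             extra_assignments = NULL,
                             outgroup_divergence = 0.2,
                             seed = 1L) {
  positions <- check_positions(as.integer(positions))
  screening_positions <- as.integer(screening_positions)
  if (!all(screening_positions %in% positions)) {
    stop("screening positions must be a subset of positions", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(motifs)) {
      if (is.null(n_cluster_alleles)) stop("need motifs or a cluster count",
                                           call. = FALSE)
      motifs <- stats::setNames(
        vapply(seq_len(n_cluster_alleles), function(i) {
          paste0(sample(AA_CODE, length(screening_positions), TRUE),
                 collapse = "")
        }, character(1)),
        sprintf("CLU*%02d:01", seq_len(n_cluster_alleles)))
    }
    if (is.null(outgroup_motifs) && !is.null(n_outgroup_alleles) &&
        n_outgroup_alleles > 0L) {
      outgroup_motifs <- stats::setNames(
        vapply(seq_len(n_outgroup_alleles), function(i) {
          paste0(sample(AA_CODE, length(screening_positions), TRUE),
                 collapse = "")
        }, character(1)),
        sprintf("OUT*%02d:01", seq_len(n_outgroup_alleles)))
    }
    if (any(nchar(motifs) != length(screening_positions)) ||
        any(nchar(outgroup_motifs %||% character(0)) !=
            length(screening_positions))) {
      stop("motif length does not match screening position count",
           call. = FALSE)
    }
    backbone <- sample(AA_CODE, length(positions), replace = TRUE)
    scr_idx <- match(screening_positions, positions)
    mature_free <- which(positions >= 1L & !positions %in% screening_positions)
    n_mut <- ceiling(outgroup_divergence * length(mature_free))

    assign_row <- function(allele, motif, mutate) {
      row <- backbone
      if (mutate) {
        at <- sample(mature_free, n_mut)
        row[at] <- vapply(row[at], function(aa) sample(setdiff(AA_CODE, aa), 1),
                          character(1))
      }
      row[scr_idx] <- strsplit(motif, "")[[1]]
      ex <- extra_assignments[[allele]]
      if (!is.null(ex)) row[match(as.integer(names(ex)), positions)] <- ex
      row
    }

    rows <- c(
      lapply(names(motifs), function(a) assign_row(a, motifs[[a]], FALSE)),
      lapply(names(outgroup_motifs %||% character(0)),
             function(a) assign_row(a, outgroup_motifs[[a]], TRUE))
    )
    mat <- do.call(rbind, rows)
    rownames(mat) <- c(names(motifs), names(outgroup_motifs %||% character(0)))
    allele_catalog(mat, positions)
  })
}

# planted residue assignments of the synthetic DR4 panel at the seven
# screening positions (b37, b57, b67, b70, b71, b74, b86)
DR4_SCREEN_POSITIONS <- c(37L, 57L, 67L, 70L, 71L, 74L, 86L)

DR4_SCREEN_TABLE <- c(
  "DRB1*04:01" = "YDLQKAG",
  "DRB1*04:02" = "YDIDEAV",
  "DRB1*04:03" = "YDLQREV",
  "DRB1*04:04" = "YDLQRAV",
  "DRB1*04:05" = "YSLQRAG",
  "DRB1*04:06" = "SDLQKAV",
  "DRB1*04:07" = "YDLQREG",
  "DRB1*04:08" = "YDLQRAV",
  "DRB1*04:10" = "YDLQRAV",
  "DRB1*04:11" = "YDLQRAG"
)

DR4_OUTGROUP_TABLE <- c(
  "DRB1*01:01" = "YDLQRAG",
  "DRB1*03:01" = "YDLQKRV",
  "DRB1*03:02" = "YDLQKRG",
  "DRB1*07:01" = "YDIDRQV",
  "DRB1*08:01" = "YSLDRAG",
  "DRB1*15:01" = "YDIQRAV"
)

#' Synthetic DR4 allele panel (fixture)
#'
#' A synthetic stand-in for an IMGT-style DRB1 protein alignment: ten
#' DR4-cluster alleles plus six outgroup alleles over beta positions
#' -5..-1 and 1..90.  The cluster carries the planted structure used
#' throughout the package's validation: at (b71, b74, b86) the ten DR4
#' alleles form exactly seven motifs with KAG unique to 04:01, REG
#' unique to 04:07 and RAV shared by 04:04/04:08/04:10; 04:03 and 04:07
#' differ at exactly one position (b86, V/G); b37 varies only on the
#' rare 04:06; b67 and b70 are in complete LD.  Outgroup alleles include
#' DR3 (03:01 = KRV, 03:02 = KRG at the motif positions).
#'
#' @return An \code{allele_catalog} (16 alleles x 95 positions).
#' @export
dr4_fixture_catalog <- function() {
  # b31 separates the RAV trio from the rest of the cluster so that
  # d(04:03, 04:07) is the unique minimum among pairs involving 04:03;
  # three private 04:01 residues make it the basal DR4 lineage, so the
  # clade spanned by 04:01 and any other DR4 allele is the whole cluster
  extra <- lapply(names(DR4_SCREEN_TABLE), function(a) {
    if (a %in% c("DRB1*04:04", "DRB1*04:08", "DRB1*04:10")) c("31" = "F")
    else if (a == "DRB1*04:01") c("31" = "I", "9" = "W", "12" = "K",
                                  "23" = "H")
    else c("31" = "I")
  })
  names(extra) <- names(DR4_SCREEN_TABLE)
  make_allele_pool(positions = c(-5:-1, 1:90),
                   screening_positions = DR4_SCREEN_POSITIONS,
                   motifs = DR4_SCREEN_TABLE,
                   outgroup_motifs = DR4_OUTGROUP_TABLE,
                   extra_assignments = extra,
                   outgroup_divergence = 0.22,
                   seed = 20210619L)
}

#' DR4 cluster allele names of the fixture catalog
#' @return Character vector of the ten DR4 allele names.
#' @export
dr4_cluster_alleles <- function() names(DR4_SCREEN_TABLE)

# --- case-control simulation -------------------------------------------

#' Configuration for a synthetic case-control sample
#'
#' Defaults emulate a Northern-European-style population sample typed at DRB1:
#' allele frequencies concentrated on common alleles, a logistic disease
#' model with per-chromosome-copy motif effects at (b71, b74, b86) set
#' to the risk spectrum reported for the DR4 motif system (KAG strongly
#' susceptible, REG/REV protective), and outcome-dependent sampling of
#' fixed case/control totals.
#'
#' @param n_case,n_ctrl Group sizes (sampled by outcome).
#' @param freqs Named population allele frequencies (normalized).
#' @param effects Named per-copy log-odds motif effects.
#' @param baseline Baseline log-odds of disease.
#' @param catalog Allele catalog (default the DR4 fixture).
#' @param motif_positions Positions defining motifs.
#' @param cluster Alleles whose motifs carry effects.
#' @param dq_noise Probability a chromosome's DQ haplotype is drawn at
#'   random instead of from the DR-linked default (breaks complete LD).
#' @param antibody_models Named list: antibody -> list(baseline, effects)
#'   logistic models for positivity among cases.
#' @param seed Integer seed.
#' @return A list of class \code{sim_cc_config}.
#' @export
casecontrol_sim_config <- function(n_case = 962L, n_ctrl = 636L,
                           freqs = NULL, effects = NULL, baseline = -1.8,
                           catalog = dr4_fixture_catalog(),
                           motif_positions = c(71L, 74L, 86L),
                           cluster = dr4_cluster_alleles(),
                           dq_noise = 0.02,
                           antibody_models = NULL,
                           seed = 1L) {
  if (is.null(freqs)) {
    freqs <- c("DRB1*01:01" = 0.170, "DRB1*03:01" = 0.150,
               "DRB1*03:02" = 0.010, "DRB1*07:01" = 0.140,
               "DRB1*08:01" = 0.050, "DRB1*15:01" = 0.250,
               "DRB1*04:01" = 0.100, "DRB1*04:02" = 0.005,
               "DRB1*04:03" = 0.008, "DRB1*04:04" = 0.060,
               "DRB1*04:05" = 0.005, "DRB1*04:06" = 0.000,
               "DRB1*04:07" = 0.007, "DRB1*04:08" = 0.004,
               "DRB1*04:10" = 0.002, "DRB1*04:11" = 0.003)
  }
  if (is.null(effects)) {
    effects <- c(KAG = log(3.64), EAV = log(2.55), RAG = log(1.93),
                 RAV = log(1.56), REG = log(0.11), REV = log(0.11))
  }
  if (is.null(antibody_models)) {
    antibody_models <- list(
      GADA = list(baseline = 0.6, effects = c(KAG = log(0.83))),
      IA2A = list(baseline = 0.0, effects = c(KAG = log(2.13)))
    )
  }
  structure(list(n_case = n_case, n_ctrl = n_ctrl,
                 freqs = freqs / sum(freqs), effects = effects,
                 baseline = baseline, catalog = catalog,
                 motif_positions = motif_positions, cluster = cluster,
                 dq_noise = dq_noise, antibody_models = antibody_models,
                 seed = seed),
            class = "sim_cc_config")
}

# default DR-linked DQ haplotypes for the fixture alleles
DR_DQ_MAP <- c(
  "DRB1*01:01" = "DQA1*01:01|DQB1*05:01",
  "DRB1*03:01" = "DQA1*05:01|DQB1*02:01",
  "DRB1*03:02" = "DQA1*05:01|DQB1*02:01",
  "DRB1*07:01" = "DQA1*02:01|DQB1*02:02",
  "DRB1*08:01" = "DQA1*04:01|DQB1*04:02",
  "DRB1*15:01" = "DQA1*01:02|DQB1*06:02",
  "DRB1*04:01" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:02" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:03" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:04" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:05" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:06" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:07" = "DQA1*03:03|DQB1*03:01",
  "DRB1*04:08" = "DQA1*03:01|DQB1*03:02",
  "DRB1*04:10" = "DQA1*03:03|DQB1*03:01",
  "DRB1*04:11" = "DQA1*03:03|DQB1*03:01"
)

#' Simulate a case-control subject table
#'
#' Genotypes are two independent draws from the configured allele
#' frequency vector; disease follows a logistic model with per-copy
#' motif effects; fixed case and control totals are filled by rejection
#' (outcome-dependent sampling).  Antibody positivity flags are
#' generated for cases from the configured logistic models.  The
#' returned table carries a \code{"latent"} attribute (per-subject
#' linear predictor and disease probability) for oracle checks; analysis
#' functions never read it.
#'
#' @param cfg A \code{sim_cc_config} (see \code{\link{casecontrol_sim_config}}).
#' @return Subject data.frame (columns id, y, drb1_1/2, dqa1_1/2,
#'   dqb1_1/2, antibody flags).
#' @export
simulate_case_control <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cc_config"))
  alleles <- names(cfg$freqs)
  if (!all(alleles %in% catalog_alleles(cfg$catalog))) {
    stop("frequency vector names must be catalog alleles", call. = FALSE)
  }
  motif_of_allele <- vapply(alleles, function(a) {
    if (a %in% cfg$cluster) motif_of(cfg$catalog, a, cfg$motif_positions)
    else "OTHER"
  }, character(1))
  eff <- function(m) ifelse(m %in% names(cfg$effects), cfg$effects[m], 0)
  dq_of <- DR_DQ_MAP[alleles]
  dq_pool <- unique(stats::na.omit(DR_DQ_MAP))

  with_seed(cfg$seed, {
    want_case <- cfg$n_case; want_ctrl <- cfg$n_ctrl
    got <- list()
    guard <- 0L
    while (want_case > 0L || want_ctrl > 0L) {
      guard <- guard + 1L
      if (guard > 2000L) stop("unattainable case/control quota", call. = FALSE)
      nb <- max(1000L, 3L * (want_case + want_ctrl))
      a1 <- sample(alleles, nb, TRUE, prob = cfg$freqs)
      a2 <- sample(alleles, nb, TRUE, prob = cfg$freqs)
      lp <- cfg$baseline + eff(motif_of_allele[a1]) + eff(motif_of_allele[a2])
      y <- stats::rbinom(nb, 1L, stats::plogis(lp))
      keep_case <- which(y == 1L)[seq_len(min(want_case, sum(y == 1L)))]
      keep_ctrl <- which(y == 0L)[seq_len(min(want_ctrl, sum(y == 0L)))]
      keep <- sort(c(keep_case, keep_ctrl))
      if (length(keep)) {
        got[[length(got) + 1L]] <- data.frame(
          y = y[keep], drb1_1 = a1[keep], drb1_2 = a2[keep], lp = lp[keep],
          stringsAsFactors = FALSE)
      }
      want_case <- want_case - length(keep_case)
      want_ctrl <- want_ctrl - length(keep_ctrl)
    }
    df <- do.call(rbind, got)
    n <- nrow(df)
    # DQ haplotypes linked to the DR chromosome, with occasional shuffling
    draw_dq <- function(a) {
      dq <- dq_of[a]
      flip <- stats::runif(n) < cfg$dq_noise
      dq[flip] <- sample(dq_pool, sum(flip), TRUE)
      dq
    }
    dq1 <- draw_dq(df$drb1_1); dq2 <- draw_dq(df$drb1_2)
    split_dq <- function(x, i) vapply(strsplit(x, "|", fixed = TRUE),
                                      `[[`, "", i)
    out <- data.frame(id = sprintf("S%05d", seq_len(n)), y = df$y,
                      drb1_1 = df$drb1_1, drb1_2 = df$drb1_2,
                      dqa1_1 = split_dq(dq1, 1L), dqa1_2 = split_dq(dq2, 1L),
                      dqb1_1 = split_dq(dq1, 2L), dqb1_2 = split_dq(dq2, 2L),
                      stringsAsFactors = FALSE)
    for (ab in names(cfg$antibody_models)) {
      m <- cfg$antibody_models[[ab]]
      em <- function(mm) ifelse(mm %in% names(m$effects), m$effects[mm], 0)
      lp_ab <- m$baseline + em(motif_of_allele[df$drb1_1]) +
        em(motif_of_allele[df$drb1_2])
      flag <- stats::rbinom(n, 1L, stats::plogis(lp_ab))
      flag[df$y == 0L] <- NA_integer_   # measured in patients only
      out[[ab]] <- flag
    }
    attr(out, "latent") <- data.frame(id = out$id, lp = df$lp,
                                      p = stats::plogis(df$lp))
    out
  })
}

# --- deterministic reference sample ------------------------------------

#' Deterministic synthetic case-control sample mirroring the DR4 fixture
#'
#' A fixed subject table (962 cases / 636 controls) whose chromosome
#' counts are derived from the configured control frequencies and a
#' planted odds-ratio spectrum over DR4 alleles (KAG-carrying 04:01 at
#' OR 3.64 down to protective 04:03/04:07 near OR 0.1); the rare 04:06
#' appears on exactly one case chromosome.  Chromosomes are paired into
#' genotypes deterministically, so the table is identical across calls
#' and exercises screening, motif and haplotype analyses without
#' simulation noise.
#'
#' @return Subject data.frame as in \code{\link{simulate_case_control}}
#'   (without antibody columns).
#' @export
dr4_reference_sample <- function() {
  cfg <- casecontrol_sim_config()
  f_ctrl <- cfg$freqs
  or <- c("DRB1*01:01" = 0.50, "DRB1*03:01" = 1.60, "DRB1*03:02" = 1.20,
          "DRB1*07:01" = 0.45, "DRB1*08:01" = 0.80, "DRB1*15:01" = 0.30,
          "DRB1*04:01" = 3.64, "DRB1*04:02" = 2.55, "DRB1*04:03" = 0.12,
          "DRB1*04:04" = 1.58, "DRB1*04:05" = 5.95, "DRB1*04:06" = 1.00,
          "DRB1*04:07" = 0.11, "DRB1*04:08" = 1.00, "DRB1*04:10" = 1.56,
          "DRB1*04:11" = 1.93)
  dr4 <- dr4_cluster_alleles()
  out <- setdiff(names(f_ctrl), dr4)
  # case frequencies: exact OR-scaled values for DR4 alleles, remainder
  # distributed over outgroup alleles
  f_case <- f_ctrl
  f_case[dr4] <- f_ctrl[dr4] * or[dr4]
  rest <- 1 - sum(f_case[dr4])
  w <- f_ctrl[out] * or[out]
  f_case[out] <- rest * w / sum(w)

  n_chr_ctrl <- 2L * 636L; n_chr_case <- 2L * 962L
  cnt_ctrl <- round(f_ctrl * n_chr_ctrl)
  cnt_case <- round(f_case * n_chr_case)
  cnt_case["DRB1*04:06"] <- 1L   # the rare motif, observed once
  # absorb rounding drift in the most common category
  fix <- function(cnt, total) {
    top <- names(which.max(cnt))
    cnt[top] <- cnt[top] + total - sum(cnt)
    cnt
  }
  cnt_ctrl <- fix(cnt_ctrl, n_chr_ctrl)
  cnt_case <- fix(cnt_case, n_chr_case)

  # chromosomes are paired into genotypes by a fixed seeded permutation:
  # deterministic, yet mixing categories like random mating would
  pair_up <- function(cnt, seed) {
    chroms <- rep(names(cnt), times = cnt)
    chroms <- with_seed(seed, sample(chroms))
    h <- length(chroms) / 2L
    data.frame(a1 = chroms[seq_len(h)], a2 = chroms[h + seq_len(h)],
               stringsAsFactors = FALSE)
  }
  gc_case <- pair_up(cnt_case, 101L); gc_ctrl <- pair_up(cnt_ctrl, 102L)
  df <- data.frame(
    id = sprintf("R%05d", seq_len(nrow(gc_case) + nrow(gc_ctrl))),
    y = c(rep(1L, nrow(gc_case)), rep(0L, nrow(gc_ctrl))),
    drb1_1 = c(gc_case$a1, gc_ctrl$a1),
    drb1_2 = c(gc_case$a2, gc_ctrl$a2),
    stringsAsFactors = FALSE)
  dq <- DR_DQ_MAP
  split_dq <- function(x, i) vapply(strsplit(x, "|", fixed = TRUE), `[[`, "", i)
  df$dqa1_1 <- split_dq(dq[df$drb1_1], 1L)
  df$dqa1_2 <- split_dq(dq[df$drb1_2], 1L)
  df$dqb1_1 <- split_dq(dq[df$drb1_1], 2L)
  df$dqb1_2 <- split_dq(dq[df$drb1_2], 2L)
  rownames(df) <- NULL
  df
}

# --- birth-cohort simulation -------------------------------------------

#' Configuration for a synthetic birth cohort with antibody follow-up
#'
#' Defaults emulate an HLA-risk-enriched newborn cohort: DR3/DR4-heavy
#' allele frequencies, three islet autoantibodies measured on a quarterly
#' (first four years) then semi-annual schedule to a ten-year horizon,
#' Weibull proportional-hazards latent seroconversion times with a
#' decelerating baseline, 10\% positive family history, and motif
#' effects on the genotype scale (separate heterozygote/homozygote
#' log-HRs, so both carrier-coded and dose-coded truths can be planted).
#'
#' @param n Number of children.
#' @param freqs Named allele frequencies (normalized).
#' @param motif_effects Named list: motif -> c(het, hom) log hazard
#'   ratios shared by the three antibodies.
#' @param sex_loghr,fh_loghr Covariate log-HRs (sex = 1, family history
#'   = 1).
#' @param location_levels,location_loghr Site labels and their log-HRs.
#' @param location_probs Site membership probabilities.
#' @param fh_prev Family-history prevalence.
#' @param shape Weibull shape (<1 = decelerating hazard).
#' @param p10 Named per-antibody baseline 10-year cumulative incidence.
#' @param schedule Visit times in years.
#' @param horizon Follow-up horizon (years).
#' @param dropout_rate Exponential dropout rate (per year).
#' @param thresholds Named antibody positivity cutoffs.
#' @param catalog,motif_positions,cluster As in \code{\link{casecontrol_sim_config}}.
#' @param seed Integer seed.
#' @return A list of class \code{sim_cohort_config}.
#' @export
cohort_sim_config <- function(n = 6000L, freqs = NULL, motif_effects = NULL,
                             sex_loghr = log(1.15), fh_loghr = log(1.8),
                             location_levels = c("north", "south", "east",
                                                 "west"),
                             location_loghr = c(0, 0.10, -0.10, 0.05),
                             location_probs = c(0.3, 0.3, 0.2, 0.2),
                             fh_prev = 0.10, shape = 0.7, p10 = NULL,
                             schedule = c(seq(0.25, 4, by = 0.25),
                                          seq(4.5, 10, by = 0.5)),
                             horizon = 10, dropout_rate = 0.03,
                             thresholds = c(GADA = 30, IAA = 1.5, IA2A = 5),
                             catalog = dr4_fixture_catalog(),
                             motif_positions = c(71L, 74L, 86L),
                             cluster = NULL,
                             seed = 1L) {
  if (is.null(freqs)) {
    freqs <- c("DRB1*04:01" = 0.35, "DRB1*03:01" = 0.25, "DRB1*03:02" = 0.02,
               "DRB1*04:04" = 0.10, "DRB1*04:02" = 0.01, "DRB1*04:03" = 0.005,
               "DRB1*04:05" = 0.01, "DRB1*04:07" = 0.005, "DRB1*04:08" = 0.01,
               "DRB1*04:10" = 0.005, "DRB1*04:11" = 0.005,
               "DRB1*01:01" = 0.08, "DRB1*07:01" = 0.05, "DRB1*08:01" = 0.05,
               "DRB1*15:01" = 0.05)
  }
  if (is.null(motif_effects)) {
    # carrier-coded planted truths: KAG risk, RAV and DR3 mildly protective
    motif_effects <- list(KAG = c(het = log(1.74), hom = log(1.74)),
                          RAV = c(het = log(0.75), hom = log(0.75)),
                          KRV = c(het = log(0.85), hom = log(0.85)),
                          KRG = c(het = log(0.85), hom = log(0.85)))
  }
  if (is.null(p10)) p10 <- c(GADA = 0.055, IAA = 0.045, IA2A = 0.04)
  structure(list(n = n, freqs = freqs / sum(freqs),
                 motif_effects = motif_effects, sex_loghr = sex_loghr,
                 fh_loghr = fh_loghr, location_levels = location_levels,
                 location_loghr = location_loghr,
                 location_probs = location_probs, fh_prev = fh_prev,
                 shape = shape, p10 = p10, schedule = sort(schedule),
                 horizon = horizon, dropout_rate = dropout_rate,
                 thresholds = thresholds, catalog = catalog,
                 motif_positions = motif_positions,
                 cluster = cluster %||% catalog_alleles(catalog),
                 seed = seed),
            class = "sim_cohort_config")
}

#' Simulate a birth cohort with longitudinal antibody panels
#'
#' Per antibody, a latent event time is drawn from a Weibull
#' proportional-hazards model with the subject's motif-genotype and
#' covariate linear predictor.  Measured values at scheduled visits sit
#' below the threshold before the latent time (log-normal deficit) and
#' above it afterwards (log-normal exceedance), so the derived event
#' time is the first scheduled visit at or after the latent time.
#' Censoring is at the last attended visit (random exponential dropout
#' or the horizon).  The latent truth (event times, linear predictors)
#' is attached as attribute \code{"latent"}; analysis functions never
#' read it.
#'
#' @param cfg A \code{sim_cohort_config} (see \code{\link{cohort_sim_config}}).
#' @return list with \code{subjects} (id, drb1_1/2, sex, family_history,
#'   location) and \code{panels} (an \code{\link{antibody_panels}});
#'   attribute \code{"latent"} carries the generating truth.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  alleles <- names(cfg$freqs)
  motif_of_allele <- vapply(alleles, function(a) {
    if (a %in% cfg$cluster) motif_of(cfg$catalog, a, cfg$motif_positions)
    else "OTHER"
  }, character(1))

  with_seed(cfg$seed, {
    n <- cfg$n
    a1 <- sample(alleles, n, TRUE, prob = cfg$freqs)
    a2 <- sample(alleles, n, TRUE, prob = cfg$freqs)
    sex <- stats::rbinom(n, 1L, 0.5)
    fh <- stats::rbinom(n, 1L, cfg$fh_prev)
    loc <- sample(cfg$location_levels, n, TRUE, prob = cfg$location_probs)
    loc_eff <- stats::setNames(cfg$location_loghr, cfg$location_levels)

    motif_lp <- numeric(n)
    for (m in names(cfg$motif_effects)) {
      copies <- (motif_of_allele[a1] == m) + (motif_of_allele[a2] == m)
      ef <- cfg$motif_effects[[m]]
      motif_lp <- motif_lp + ifelse(copies == 1L, ef[["het"]],
                                    ifelse(copies == 2L, ef[["hom"]], 0))
    }
    lp <- motif_lp + cfg$sex_loghr * sex + cfg$fh_loghr * fh + loc_eff[loc]

    lambda <- cfg$horizon / (-log(1 - cfg$p10))^(1 / cfg$shape)
    latent <- sapply(ANTIBODIES, function(ab) {
      u <- stats::runif(n)
      lambda[ab] * (-log(u) / exp(lp))^(1 / cfg$shape)
    })

    dropout <- stats::rexp(n, rate = cfg$dropout_rate)
    end <- pmin(dropout, cfg$horizon)
    sched <- cfg$schedule
    last_visit_idx <- pmax(1L, findInterval(end, sched))
    last_contact <- sched[last_visit_idx]

    # long panel: one row per attended visit
    reps <- last_visit_idx
    id <- sprintf("C%05d", seq_len(n))
    long_id <- rep(id, reps)
    long_t <- unlist(lapply(reps, function(k) sched[seq_len(k)]))
    row_sub <- rep(seq_len(n), reps)
    vals <- sapply(ANTIBODIES, function(ab) {
      thr <- cfg$thresholds[ab]
      post <- long_t >= latent[row_sub, ab]
      nlong <- length(long_t)
      pre_v <- thr * exp(-stats::rlnorm(nlong, meanlog = -0.7, sdlog = 0.5))
      post_v <- thr * (1 + stats::rlnorm(nlong, meanlog = -0.3, sdlog = 0.6))
      ifelse(post, post_v, pre_v)
    })
    panel_df <- data.frame(id = long_id, visit_time = long_t, vals,
                           stringsAsFactors = FALSE)
    subjects <- data.frame(id = id, drb1_1 = a1, drb1_2 = a2, sex = sex,
                           family_history = fh, location = loc,
                           stringsAsFactors = FALSE)
    panels <- antibody_panels(panel_df, cfg$thresholds,
                              data.frame(id = id, last_contact = last_contact))
    res <- list(subjects = subjects, panels = panels)
    attr(res, "latent") <- data.frame(id = id, latent, lp = lp,
                                      last_contact = last_contact)
    res
  })
}
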