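# Shared in-code fixtures for the test suite.

# tiny catalog: 4 alleles x 6 mature positions, built by hand
toy_catalog <- function() {
  seqs <- c("A*01:01" = "KAGDEF",
            "A*01:02" = "RAGDEF",
            "A*02:01" = "KAVDEF",
            "A*03:01" = "WWWWWW")
  allele_catalog(seqs, positions = 1:6)
}

# subjects with explicit genotypes
toy_subjects <- function(y, a1, a2) {
  data.frame(id = sprintf("T%03d", seq_along(y)), y = y,
             drb1_1 = a1, drb1_2 = a2, stringsAsFactors = FALSE)
}

# one-subject antibody panel from explicit values
toy_panel <- function(visits, GADA, IAA, IA2A,
                      thresholds = c(GADA = 10, IAA = 10, IA2A = 10),
                      id = "P1", last_contact = NULL) {
  dat <- data.frame(id = id, visit_time = visits, GADA = GADA, IAA = IAA,
                    IA2A = IA2A, stringsAsFactors = FALSE)
  lc <- if (is.null(last_contact)) NULL else
    data.frame(id = id, last_contact = last_contact)
  antibody_panels(dat, thresholds, lc)
}

# deterministic exponential-time cohort for Cox checks
toy_cox_data <- function(n = 80L, beta = 0.7, seed = 42L) {
  set.seed(seed)
  x <- rbinom(n, 1L, 0.5)
  t_ev <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- runif(n, 5, 25)
  list(outcomes = data.frame(time = pmin(t_ev, cens),
                             event = as.integer(t_ev <= cens)),
       x = x)
}
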