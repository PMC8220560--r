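# Multi-locus EM haplotype frequency estimation and DR-DQ haplotype
# association.

# Enumerate the phase configurations of one subject.  `pairs` is a list of
# length-2 character vectors (one per locus).  Returns a list of
# configurations, each a list(h1=, h2=) of "|"-joined haplotype labels.
phase_configurations <- function(pairs) {
  het <- vapply(pairs, function(p) p[1] != p[2], logical(1))
  nh <- sum(het)
  n_cfg <- if (nh <= 1L) 1L else 2L^(nh - 1L)
  cfgs <- vector("list", n_cfg)
  het_idx <- which(het)
  for (c in seq_len(n_cfg)) {
    flip <- rep(FALSE, length(pairs))
    if (nh > 1L) {
      # first heterozygous locus fixed to break the h1/h2 symmetry
      bits <- as.integer(intToBits(c - 1L))[seq_len(nh - 1L)]
      flip[het_idx[-1L]] <- bits == 1L
    }
    a1 <- mapply(function(p, f) if (f) p[2] else p[1], pairs, flip)
    a2 <- mapply(function(p, f) if (f) p[1] else p[2], pairs, flip)
    cfgs[[c]] <- list(h1 = paste(a1, collapse = "|"),
                      h2 = paste(a2, collapse = "|"))
  }
  cfgs
}

#' EM estimation of multi-locus haplotype frequencies
#'
#' Standard expectation-maximization over unobserved phase for unordered
#' multi-locus genotypes.  Initialization is uniform over all haplotypes
#' compatible with the sample, so the algorithm is deterministic.  The
#' log-likelihood is nondecreasing across iterations; haplotypes whose
#' converged frequency falls below \code{prune} are removed and the
#' remaining frequencies renormalized.
#'
#' @param genotypes A data.frame holding two columns per locus, named
#'   \code{<locus>.1} and \code{<locus>.2}.
#' @param loci Character vector of locus names, in haplotype label order.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @param prune Post-convergence frequency pruning threshold.
#' @return Object of class \code{haplo_em}: list with \code{freq} (named,
#'   sums to 1), \code{dosage} (subjects x haplotypes posterior expected
#'   copies; rows sum to 2), \code{loglik} (trace), \code{converged},
#'   \code{n_iter}.
#' @export
em_haplotype_freqs <- function(genotypes, loci, tol = 1e-8, max_iter = 500L,
                               prune = 1e-6) {
  n <- nrow(genotypes)
  if (n < 1L) stop("need at least one subject", call. = FALSE)
  cols <- c(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  miss <- setdiff(cols, names(genotypes))
  if (length(miss)) stop("missing genotype column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  subj_cfg <- lapply(seq_len(n), function(i) {
    pairs <- lapply(loci, function(l) {
      as.character(c(genotypes[[paste0(l, ".1")]][i],
                     genotypes[[paste0(l, ".2")]][i]))
    })
    phase_configurations(pairs)
  })
  haps <- sort(unique(unlist(lapply(subj_cfg, function(cfgs) {
    unlist(lapply(cfgs, function(cf) c(cf$h1, cf$h2)))
  }))))
  H <- length(haps)
  # integer-indexed configurations for speed
  subj_idx <- lapply(subj_cfg, function(cfgs) {
    cbind(h1 = match(vapply(cfgs, `[[`, "", "h1"), haps),
          h2 = match(vapply(cfgs, `[[`, "", "h2"), haps))
  })

  f <- rep(1 / H, H)
  loglik <- numeric(0)
  converged <- FALSE
  dosage <- matrix(0, n, H, dimnames = list(NULL, haps))
  for (it in seq_len(max_iter)) {
    newf <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      idx <- subj_idx[[i]]
      w <- f[idx[, 1L]] * f[idx[, 2L]] * ifelse(idx[, 1L] != idx[, 2L], 2, 1)
      tw <- sum(w)
      ll <- ll + log(tw)
      w <- w / tw
      di <- numeric(H)
      for (c in seq_len(nrow(idx))) {
        di[idx[c, 1L]] <- di[idx[c, 1L]] + w[c]
        di[idx[c, 2L]] <- di[idx[c, 2L]] + w[c]
      }
      dosage[i, ] <- di
      newf <- newf + di
    }
    loglik <- c(loglik, ll)
    newf <- newf / (2 * n)
    if (it > 1L && loglik[it] - loglik[it - 1L] < tol) {
      converged <- TRUE
      f <- newf
      break
    }
    f <- newf
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  keep <- f >= prune
  f <- f[keep] / sum(f[keep])
  dosage <- dosage[, keep, drop = FALSE]
  structure(list(freq = stats::setNames(f, haps[keep]), dosage = dosage,
                 loglik = loglik, converged = converged,
                 n_iter = length(loglik)),
            class = "haplo_em")
}

#' @export
print.haplo_em <- function(x, ...) {
  cat("<haplo_em>", length(x$freq), "haplotypes,", x$n_iter,
      "iterations, loglik", format(x$loglik[x$n_iter], digits = 6), "\n")
  invisible(x)
}

# build the motif|DQA1|DQB1 genotype frame from a subject table
dq_genotypes <- function(subjects, catalog, motif_positions, cluster = NULL) {
  need <- c("dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subject table lacks DQ column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mp <- motif_mapper(catalog, motif_positions, cluster)
  mot1 <- map_chr(as.character(subjects$drb1_1), mp)
  mot2 <- map_chr(as.character(subjects$drb1_2), mp)
  mot1[is.na(mot1)] <- "OTHER"; mot2[is.na(mot2)] <- "OTHER"
  data.frame(motif.1 = mot1, motif.2 = mot2,
             dqa1.1 = collapse_alleles(as.character(subjects$dqa1_1)),
             dqa1.2 = collapse_alleles(as.character(subjects$dqa1_2)),
             dqb1.1 = collapse_alleles(as.character(subjects$dqb1_1)),
             dqb1.2 = collapse_alleles(as.character(subjects$dqb1_2)),
             stringsAsFactors = FALSE)
}

#' DRB1-motif x DQA1 x DQB1 haplotype association
#'
#' Haplotype frequencies are estimated by EM separately within cases and
#' controls (frequency columns), and once in the pooled sample under the
#' null to obtain per-subject posterior dosages for the score test.
#' OR = case frequency / control frequency of the same haplotype
#' (virtual reference).  Haplotypes estimated in only one group are
#' reported with counts and flagged; no Z is computed for them.
#'
#' @param subjects Subject data.frame with DRB1 and DQ genotype columns.
#' @param catalog An \code{allele_catalog} for DRB1 motifs.
#' @param motif_positions Integer beta positions defining the DRB1 motif.
#' @param cluster Optional cluster restriction for motif assignment
#'   (non-cluster alleles contribute an \code{"OTHER"} motif).
#' @param tol,max_iter EM controls.
#' @return data.frame sorted by DQ haplotype: \code{haplotype},
#'   \code{n_case}, \code{n_ctrl} (EM-expected chromosome counts),
#'   \code{f_case}, \code{f_ctrl}, \code{OR}, \code{Z}, \code{SE},
#'   \code{p}, \code{note}.
#' @export
dq_haplotype_assoc <- function(subjects, catalog, motif_positions,
                               cluster = NULL, tol = 1e-8, max_iter = 500L) {
  geno <- dq_genotypes(subjects, catalog, motif_positions, cluster)
  loci <- c("motif", "dqa1", "dqb1")
  y <- as.integer(subjects$y)
  em_case <- em_haplotype_freqs(geno[y == 1L, , drop = FALSE], loci,
                                tol = tol, max_iter = max_iter)
  em_ctrl <- em_haplotype_freqs(geno[y == 0L, , drop = FALSE], loci,
                                tol = tol, max_iter = max_iter)
  em_pool <- em_haplotype_freqs(geno, loci, tol = tol, max_iter = max_iter)

  haps <- sort(union(names(em_case$freq), names(em_ctrl$freq)))
  fc <- unname(em_case$freq[haps]); fc[is.na(fc)] <- 0
  f0 <- unname(em_ctrl$freq[haps]); f0[is.na(f0)] <- 0
  n_case <- 2 * sum(y == 1L) * fc
  n_ctrl <- 2 * sum(y == 0L) * f0

  rows <- lapply(seq_along(haps), function(k) {
    h <- haps[k]
    OR <- Z <- SE <- p <- NA_real_
    note <- ""
    if (f0[k] == 0) {
      note <- "case-only haplotype"
    } else if (fc[k] == 0) {
      OR <- 0
      note <- "control-only haplotype"
    } else {
      OR <- fc[k] / f0[k]
      if (h %in% colnames(em_pool$dosage)) {
        st <- score_test(y, em_pool$dosage[, h])
        Z <- st$Z; p <- st$p
        SE <- if (Z != 0 && OR > 0) log(OR) / Z else NA_real_
      }
    }
    data.frame(haplotype = h, n_case = n_case[k], n_ctrl = n_ctrl[k],
               f_case = fc[k], f_ctrl = f0[k], OR = OR, Z = Z, SE = SE,
               p = p, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # group rows that share the same DQ haplotype
  dq <- sub("^[^|]*\\|", "", out$haplotype)
  out[order(dq, out$haplotype), , drop = FALSE]
}
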