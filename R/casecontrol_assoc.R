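# Case-control association: chromosome counts, virtual-reference odds
# ratios, haplotype score tests, residue screening (HOH step 2).

#' Read a case-control subject table
#'
#' Expected columns: \code{id}, \code{y} (0 control / 1 case),
#' \code{drb1_1}, \code{drb1_2}; optionally \code{dqa1_1}, \code{dqa1_2},
#' \code{dqb1_1}, \code{dqb1_2}, antibody 0/1 flags and covariates.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_subjects_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("id", "y", "drb1_1", "drb1_2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$y %in% c(0L, 1L))) stop("y must be 0/1", call. = FALSE)
  df
}

# --- category mappers ---------------------------------------------------

#' Category mappers for chromosome counting
#'
#' A mapper is a function from a canonical allele name to a category
#' label, or \code{NA} to exclude the chromosome.
#'
#' \code{allele_mapper} maps each allele to itself (collapsed to 2
#' fields); alleles outside \code{cluster} (when given) map to \code{NA}.
#' \code{residue_mapper} maps an allele to its amino acid at one beta
#' position.  \code{motif_mapper} maps an allele to its motif at several
#' positions.  With a \code{cluster}, non-cluster alleles map to \code{NA}
#' so that analyses are restricted to cluster chromosomes ("among
#' carriers").
#'
#' @param catalog An \code{allele_catalog}.
#' @param cluster Optional character vector of cluster allele names.
#' @param position,positions Beta position(s).
#' @return A function \code{allele -> category (or NA)}.
#' @name mappers
NULL

#' @rdname mappers
#' @export
allele_mapper <- function(cluster = NULL) {
  function(a) {
    a <- collapse_allele(a)
    if (!is.null(cluster) && !a %in% cluster) return(NA_character_)
    a
  }
}

#' @rdname mappers
#' @export
residue_mapper <- function(catalog, position, cluster = NULL) {
  function(a) {
    a <- collapse_allele(a)
    if (!is.null(cluster) && !a %in% cluster) return(NA_character_)
    motif_of(catalog, a, position)
  }
}

#' @rdname mappers
#' @export
motif_mapper <- function(catalog, positions, cluster = NULL) {
  function(a) {
    a <- collapse_allele(a)
    if (!is.null(cluster) && !a %in% cluster) return(NA_character_)
    motif_of(catalog, a, positions)
  }
}

# --- chromosome counting ------------------------------------------------

#' Chromosome counts and frequencies per category
#'
#' Each subject contributes two chromosomes; each chromosome is mapped to
#' a category.  Frequencies are normalized within the case and control
#' groups.  Chromosomes mapped to \code{NA} are excluded and subjects
#' left with zero mapped chromosomes are dropped (carrier restriction);
#' with \code{drop_unmapped = FALSE} they are counted as \code{"OTHER"}.
#'
#' @param subjects Subject data.frame (see \code{\link{read_subjects_tsv}}).
#' @param mapper A mapper function (see \code{\link{mappers}}).
#' @param drop_unmapped Drop NA-mapped chromosomes instead of relabelling
#'   them \code{"OTHER"}.
#' @param y Optional 0/1 outcome overriding \code{subjects$y}.
#' @return Object of class \code{category_counts}: a data.frame with
#'   columns \code{category}, \code{n_case}, \code{n_ctrl}, \code{f_case},
#'   \code{f_ctrl}; attributes carry the per-subject dosage matrix and
#'   outcome used by the score test.
#' @export
chromosome_counts <- function(subjects, mapper, drop_unmapped = FALSE,
                              y = NULL) {
  y <- as.integer(y %||% subjects$y)
  c1 <- map_chr(as.character(subjects$drb1_1), mapper)
  c2 <- map_chr(as.character(subjects$drb1_2), mapper)
  if (!drop_unmapped) {
    c1[is.na(c1)] <- "OTHER"
    c2[is.na(c2)] <- "OTHER"
  }
  keep <- !(is.na(c1) & is.na(c2))
  c1 <- c1[keep]; c2 <- c2[keep]; y <- y[keep]
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("need at least one case and one control with mapped chromosomes",
         call. = FALSE)
  }
  cats <- sort(unique(stats::na.omit(c(c1, c2))))
  dosage <- matrix(0L, length(y), length(cats),
                   dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    dosage[, k] <- (!is.na(c1) & c1 == cats[k]) + (!is.na(c2) & c2 == cats[k])
  }
  n_case <- colSums(dosage[y == 1L, , drop = FALSE])
  n_ctrl <- colSums(dosage[y == 0L, , drop = FALSE])
  out <- data.frame(category = cats, n_case = n_case, n_ctrl = n_ctrl,
                    f_case = n_case / sum(n_case),
                    f_ctrl = n_ctrl / sum(n_ctrl),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("category_counts", "data.frame"),
            dosage = dosage, y = y)
}

# --- score test ---------------------------------------------------------

#' Haplotype score test of a category dosage against a binary outcome
#'
#' Score statistic for adding an expected chromosome dosage (0..2, may be
#' fractional under phase uncertainty) to a null logistic model of the
#' outcome on covariates (intercept-only when none).  With fitted null
#' probabilities \eqn{\mu_i}: \eqn{U = \sum (y_i - \mu_i) d_i} and
#' \eqn{V = \sum \mu_i(1-\mu_i) d_i^2 - c' I^{-1} c}, where \eqn{c} is the
#' covariate-dosage cross term and \eqn{I} the null information;
#' \eqn{Z = U/\sqrt{V}}, two-sided normal p.  Positive Z means the
#' category is enriched in cases.
#'
#' @param y 0/1 outcome vector.
#' @param dosage Numeric dosage vector (same length).
#' @param covariates Optional data.frame of null-model covariates.
#' @return List with \code{Z}, \code{p}, \code{U}, \code{V}.
#' @export
score_test <- function(y, dosage, covariates = NULL) {
  y <- as.numeric(y)
  d <- as.numeric(dosage)
  if (length(d) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(d))) stop("dosage must be finite", call. = FALSE)
  if (!any(y == 1) || !any(y == 0)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    mu <- rep(mean(y), length(y))
    X <- matrix(1, length(y), 1L)
  } else {
    df <- as.data.frame(covariates)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    mu <- stats::fitted(fit)
    X <- stats::model.matrix(fit)
    X <- X[, !is.na(stats::coef(fit)), drop = FALSE]   # drop aliased columns
  }
  w <- mu * (1 - mu)
  U <- sum((y - mu) * d)
  cc <- crossprod(X, w * d)
  I <- crossprod(X, w * X)
  V <- sum(w * d^2) - drop(crossprod(cc, solve(I, cc)))
  if (!is.finite(V) || V < 0) stop("degenerate design in score test", call. = FALSE)
  if (V <= .Machine$double.eps * sum(w * d^2 + 1)) {
    # constant dosage (orthogonal to nothing to test): U is 0 as well
    if (abs(U) < 1e-8) return(list(Z = 0, p = 1, U = U, V = V))
    stop("zero score variance with nonzero score", call. = FALSE)
  }
  Z <- U / sqrt(V)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), U = U, V = V)
}

# --- virtual-reference odds ratio --------------------------------------

#' Virtual-reference odds ratio for one category
#'
#' OR is the case chromosome frequency over the control chromosome
#' frequency of the same category ("virtual reference": no reference
#' category is chosen).  Z and p come from \code{\link{score_test}} on
#' the category's per-subject dosage; SE is derived as \code{log(OR)/Z}.
#'
#' @param counts A \code{category_counts} object.
#' @param category Category label present in \code{counts}.
#' @param covariates Optional covariate data.frame for the score test.
#' @return One-row data.frame: \code{category}, \code{n_case},
#'   \code{n_ctrl}, \code{f_case}, \code{f_ctrl}, \code{OR}, \code{Z},
#'   \code{SE}, \code{p}, \code{note}.
#' @export
virtual_reference_or <- function(counts, category, covariates = NULL) {
  i <- match(category, counts$category)
  if (is.na(i)) stop("category not present: ", category, call. = FALSE)
  row <- counts[i, , drop = FALSE]
  dosage <- attr(counts, "dosage")[, category]
  y <- attr(counts, "y")
  rare <- row$n_case + row$n_ctrl < 3
  if (row$f_ctrl == 0) {
    note <- paste0("undefined: absent in controls",
                   if (rare) "; rare (<3 copies)")
    return(data.frame(row, OR = NA_real_, Z = NA_real_, SE = NA_real_,
                      p = NA_real_, note = note, stringsAsFactors = FALSE))
  }
  note <- ""
  OR <- row$f_case / row$f_ctrl
  st <- score_test(y, dosage, covariates)
  SE <- if (st$Z != 0 && OR > 0) log(OR) / st$Z else NA_real_
  if (st$Z == 0) note <- "SE undefined (Z = 0)"
  if (rare) note <- paste0(note, if (nzchar(note)) "; ", "rare (<3 copies)")
  data.frame(row, OR = OR, Z = st$Z, SE = SE, p = st$p, note = note,
             stringsAsFactors = FALSE)
}

#' Association table over all categories of a counts object
#'
#' @inheritParams virtual_reference_or
#' @return data.frame with one \code{\link{virtual_reference_or}} row per
#'   category.
#' @export
assoc_table <- function(counts, covariates = NULL) {
  do.call(rbind, lapply(counts$category, function(cat) {
    virtual_reference_or(counts, cat, covariates)
  }))
}

#' Fisher comparison of two categories' case/control counts
#'
#' Two-sided Fisher exact test on the 2x2 table of chromosome counts
#' \{A, B\} x \{case, control\}; used to ask whether two residues at the
#' same position carry different disease associations.
#'
#' @param counts A \code{category_counts}.
#' @param categoryA,categoryB Category labels.
#' @return Two-sided p-value.
#' @export
fisher_compare <- function(counts, categoryA, categoryB) {
  ia <- match(categoryA, counts$category)
  ib <- match(categoryB, counts$category)
  if (is.na(ia) || is.na(ib)) stop("category not present", call. = FALSE)
  tab <- matrix(c(counts$n_case[ia], counts$n_ctrl[ia],
                  counts$n_case[ib], counts$n_ctrl[ib]),
                2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in Fisher comparison; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

# --- residue screening --------------------------------------------------

#' Screen within-cluster residue positions
#'
#' Classifies each position within an allele cluster.  An allele is rare
#' when it carries fewer than \code{rare_copies} chromosome copies in the
#' pooled sample (unobserved alleles are rare).  A position is
#' \code{monomorphic} when one amino acid is shared by every cluster
#' allele; \code{near_monomorphic} when its only variation sits on rare
#' alleles; two polymorphic positions whose amino-acid assignments are a
#' bijection across all non-rare cluster alleles are in complete LD and
#' the later position is \code{collapsed_LD} onto the earlier; everything
#' else is \code{kept}.  Alleles missing a residue at a position are
#' excluded from that position's classification with a warning.
#'
#' @param catalog An \code{allele_catalog}.
#' @param cluster Character vector of cluster allele names (or an
#'   \code{allele_cluster}).
#' @param subjects Subject data.frame supplying chromosome counts.
#' @param positions Integer vector of beta positions to screen.
#' @param rare_copies Rarity threshold in chromosome copies (default 3).
#' @return Object of class \code{residue_screen}: data.frame with columns
#'   \code{position}, \code{label}, \code{status}, \code{ld_partner};
#'   attribute \code{rare_alleles}.
#' @export
screen_residues <- function(catalog, cluster, subjects, positions,
                            rare_copies = 3L) {
  if (inherits(cluster, "allele_cluster")) cluster <- cluster$members
  positions <- as.integer(positions)
  alle <- collapse_alleles(c(as.character(subjects$drb1_1),
                             as.character(subjects$drb1_2)))
  copies <- table(factor(alle[alle %in% cluster], levels = cluster))
  rare <- names(copies)[copies < rare_copies]
  common <- setdiff(cluster, rare)

  idx <- match(positions, catalog$positions)
  if (anyNA(idx)) stop("position(s) not in catalog", call. = FALSE)
  res_all <- catalog$seq[cluster, idx, drop = FALSE]

  status <- character(length(positions))
  partner <- rep(NA_character_, length(positions))

  aa_common <- list()
  for (k in seq_along(positions)) {
    col <- res_all[, k]
    if (anyNA(col)) {
      warning("allele(s) missing residue at ", position_label(positions[k]),
              ": ", paste(cluster[is.na(col)], collapse = ", "),
              "; excluded from this position")
    }
    aa_all <- unique(stats::na.omit(col))
    colc <- col[rownames(res_all) %in% common]
    aa_com <- unique(stats::na.omit(colc))
    aa_common[[k]] <- colc
    if (length(aa_all) <= 1L || length(cluster) == 1L) {
      status[k] <- "monomorphic"
    } else if (length(aa_com) <= 1L) {
      status[k] <- "near_monomorphic"
    } else {
      status[k] <- "kept"
    }
  }

  # complete-LD collapse among surviving polymorphic positions
  poly <- which(status == "kept")
  if (length(poly) > 1L) {
    for (b in poly) {
      for (a in poly[poly < b]) {
        if (status[b] != "kept" || status[a] != "kept") next
        xa <- aa_common[[a]]; xb <- aa_common[[b]]
        ok <- !is.na(xa) & !is.na(xb)
        map <- unique(data.frame(a = xa[ok], b = xb[ok]))
        if (!anyDuplicated(map$a) && !anyDuplicated(map$b)) {
          status[b] <- "collapsed_LD"
          partner[b] <- position_label(positions[a])
        }
      }
    }
  }

  structure(data.frame(position = positions,
                       label = position_label(positions),
                       status = status, ld_partner = partner,
                       stringsAsFactors = FALSE),
            class = c("residue_screen", "data.frame"),
            rare_alleles = rare)
}

# --- motif / residue / antibody association -----------------------------

#' Motif association table (virtual-reference OR + score test)
#'
#' Maps each chromosome to its motif at \code{positions} (non-cluster
#' chromosomes to \code{"OTHER"}), then reports per-motif counts,
#' frequencies, virtual-reference OR, score Z and p.  Because the
#' frequencies are unconditional, a motif unique to one allele carries
#' that allele's odds ratio.  With \code{carriers_only = TRUE} the
#' analysis is instead restricted to cluster chromosomes only.  Motifs
#' carried by fewer than 3 chromosomes are flagged rare.
#'
#' @param subjects Subject data.frame.
#' @param catalog An \code{allele_catalog}.
#' @param positions Integer vector of beta positions (post-screening).
#' @param cluster Optional allele cluster; chromosomes outside it do not
#'   receive a motif.
#' @param carriers_only Restrict to cluster chromosomes (and drop
#'   subjects carrying none) instead of counting them as \code{"OTHER"}.
#' @param covariates Optional covariate data.frame for the score test.
#' @return data.frame of association rows, one per motif.
#' @export
motif_assoc_table <- function(subjects, catalog, positions, cluster = NULL,
                              carriers_only = FALSE, covariates = NULL) {
  if (inherits(cluster, "allele_cluster")) cluster <- cluster$members
  counts <- chromosome_counts(subjects,
                              motif_mapper(catalog, positions, cluster),
                              drop_unmapped = carriers_only)
  assoc_table(counts, covariates)
}

#' Residue association table at one position
#'
#' By default this is the "among carriers" analysis: subjects carrying
#' at least one cluster allele, counting only their cluster chromosomes.
#'
#' @inheritParams motif_assoc_table
#' @param position One beta position.
#' @param carriers_only Restrict to cluster chromosomes (default).
#' @return data.frame of association rows, one per amino acid.
#' @export
residue_assoc_table <- function(subjects, catalog, position, cluster = NULL,
                                carriers_only = TRUE, covariates = NULL) {
  if (inherits(cluster, "allele_cluster")) cluster <- cluster$members
  counts <- chromosome_counts(subjects,
                              residue_mapper(catalog, position, cluster),
                              drop_unmapped = carriers_only && !is.null(cluster))
  assoc_table(counts, covariates)
}

#' Motif association with an autoantibody among patients
#'
#' Restricted to cases, the binary outcome is recoded as antibody
#' positivity and the virtual-reference OR / score test machinery is
#' reused: the "case" frequency is the motif frequency among
#' antibody-positive patients and the "control" frequency among
#' antibody-negative patients.
#'
#' @param subjects Subject data.frame containing only cases (\code{y == 1})
#'   with a 0/1 antibody column.
#' @param catalog An \code{allele_catalog}.
#' @param positions Integer vector of beta positions.
#' @param motif Motif label to test.
#' @param antibody Name of the antibody column (e.g. \code{"GADA"}).
#' @param cluster Optional cluster restriction.
#' @return One association row (data.frame).
#' @export
antibody_assoc <- function(subjects, catalog, positions, motif, antibody,
                           cluster = NULL) {
  if (inherits(cluster, "allele_cluster")) cluster <- cluster$members
  if (!all(subjects$y == 1L)) stop("antibody association is patients-only",
                                   call. = FALSE)
  if (!antibody %in% names(subjects)) {
    stop("no antibody column '", antibody, "'", call. = FALSE)
  }
  ab <- subjects[[antibody]]
  n_missing <- sum(is.na(ab))
  if (n_missing > 0) {
    message(n_missing, " patient(s) without ", antibody,
            " measurement excluded")
    subjects <- subjects[!is.na(ab), , drop = FALSE]
    ab <- ab[!is.na(ab)]
  }
  if (all(ab == 1L) || all(ab == 0L)) {
    stop("antibody ", antibody, " is constant among patients", call. = FALSE)
  }
  if (!is.null(cluster)) {   # patients carrying at least one cluster allele
    carr <- collapse_alleles(as.character(subjects$drb1_1)) %in% cluster |
      collapse_alleles(as.character(subjects$drb1_2)) %in% cluster
    subjects <- subjects[carr, , drop = FALSE]
    ab <- ab[carr]
    if (all(ab == 1L) || all(ab == 0L)) {
      stop("antibody ", antibody, " is constant among carrier patients",
           call. = FALSE)
    }
  }
  counts <- chromosome_counts(subjects,
                              motif_mapper(catalog, positions, cluster),
                              y = ab)
  virtual_reference_or(counts, motif)
}
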