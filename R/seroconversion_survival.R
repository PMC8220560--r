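# Seroconversion endpoints from longitudinal autoantibody panels and
# Cox proportional-hazards association models.

SERO_DEFINITIONS <- c("overall", "double", "GADA", "IAA", "IA2A")
ANTIBODIES <- c("GADA", "IAA", "IA2A")

#' Bundle longitudinal antibody measurements into a panel set
#'
#' @param data Long data.frame with columns \code{id}, \code{visit_time}
#'   (years) and one numeric column per antibody (\code{GADA},
#'   \code{IAA}, \code{IA2A}).
#' @param thresholds Named numeric vector of positivity cutoffs.
#' @param last_contact data.frame with columns \code{id},
#'   \code{last_contact}; defaults to each subject's last visit.
#' @return Object of class \code{antibody_panels}.
#' @export
antibody_panels <- function(data, thresholds, last_contact = NULL) {
  need <- c("id", "visit_time", ANTIBODIES)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("panel lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(ANTIBODIES %in% names(thresholds)) ||
      any(!is.finite(thresholds[ANTIBODIES]))) {
    stop("thresholds must be finite and named for ",
         paste(ANTIBODIES, collapse = ", "), call. = FALSE)
  }
  data <- data[order(data$id, data$visit_time), , drop = FALSE]
  dup <- stats::ave(data$visit_time, data$id,
                    FUN = function(v) c(0, diff(v)))
  if (any(dup[stats::ave(seq_along(data$id), data$id,
                         FUN = seq_along) > 1] <= 0)) {
    stop("visit times must be strictly increasing within subject",
         call. = FALSE)
  }
  if (is.null(last_contact)) {
    last_contact <- stats::aggregate(visit_time ~ id, data, max)
    names(last_contact)[2] <- "last_contact"
  }
  structure(list(data = data, thresholds = thresholds[ANTIBODIES],
                 last_contact = last_contact),
            class = "antibody_panels")
}

#' Read a long-format panel TSV
#' @param path TSV with columns id, visit_time, GADA, IAA, IA2A.
#' @param thresholds Named numeric vector of cutoffs.
#' @return An \code{antibody_panels}.
#' @export
read_panels_tsv <- function(path, thresholds) {
  antibody_panels(utils::read.delim(path, header = TRUE), thresholds)
}

#' Derive a seroconversion endpoint from antibody panels
#'
#' Positivity is a strict threshold crossing (\code{value > threshold})
#' at an observed visit, and the event time is the visit time.
#' Definitions: antibody-specific = first positive visit for that
#' antibody; \code{overall} = earliest antibody-specific event;
#' \code{double} = first visit by which two or more antibodies have ever
#' crossed their thresholds.  Subjects without the event are censored at
#' last contact.
#'
#' @param panels An \code{antibody_panels}.
#' @param definition One of \code{"overall"}, \code{"double"},
#'   \code{"GADA"}, \code{"IAA"}, \code{"IA2A"}.
#' @return data.frame with columns \code{id}, \code{definition},
#'   \code{time}, \code{event}.
#' @export
derive_seroconversion <- function(panels, definition = "overall") {
  definition <- match.arg(definition, SERO_DEFINITIONS)
  dat <- panels$data
  thr <- panels$thresholds
  ids <- panels$last_contact$id
  if (!all(ids %in% dat$id)) {
    stop("subject(s) without visits: ",
         paste(utils::head(setdiff(ids, dat$id)), collapse = ", "),
         call. = FALSE)
  }
  # first crossing time per subject and antibody (Inf = never crossed);
  # crossing times are visit times, so the k-th seroconversion time is the
  # k-th order statistic of the per-antibody crossing times
  cross <- sapply(ANTIBODIES, function(ab) {
    pos <- dat[[ab]] > thr[ab]
    first <- tapply(dat$visit_time[pos], factor(dat$id[pos], levels = ids), min)
    ifelse(is.na(first), Inf, first)
  })
  if (length(ids) == 1L) cross <- matrix(cross, nrow = 1L,
                                         dimnames = list(NULL, ANTIBODIES))
  t_event <- switch(definition,
    overall = do.call(pmin, as.data.frame(cross)),
    double = apply(cross, 1L, function(v) sort(v)[2L]),
    cross[, definition]
  )
  event <- as.integer(is.finite(t_event))
  time <- ifelse(event == 1L, t_event, panels$last_contact$last_contact)
  data.frame(id = ids, definition = definition, time = time, event = event,
             row.names = NULL)
}

#' Kaplan-Meier cumulative incidence
#'
#' Incidence is one minus the product-limit survival estimate; a
#' right-continuous nondecreasing step function with jumps at event
#' times.
#'
#' @param outcomes data.frame with \code{time} and \code{event}.
#' @return data.frame \code{time}, \code{incidence} (step-function
#'   knots), with the \code{survfit} object as attribute \code{"fit"}.
#' @export
km_incidence <- function(outcomes) {
  if (nrow(outcomes) < 1L) stop("need at least one outcome", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = outcomes)
  structure(data.frame(time = sf$time, incidence = 1 - sf$surv),
            fit = sf)
}

#' Log-rank test between groups
#'
#' @param outcomes data.frame with \code{time}, \code{event}.
#' @param group Group label vector (same length).
#' @return list \code{chi2}, \code{df}, \code{p}.
#' @export
logrank_test <- function(outcomes, group) {
  group <- as.factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(outcomes$time, outcomes$event) ~ group)
  df <- length(sd$n) - 1L
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Maximizes the Efron partial likelihood via \code{survival::coxph}
#' with a tight convergence tolerance.  A monotone likelihood
#' (separation, coefficient running away) is reported as an error naming
#' the offending term.
#'
#' @param outcomes data.frame with \code{time}, \code{event}.
#' @param design data.frame of covariates (0 columns = empty fit).
#' @param ties Tie handling, default \code{"efron"}.
#' @return Object of class \code{cox_result}: data.frame with
#'   \code{term}, \code{coef}, \code{HR}, \code{SE}, \code{Z}, \code{p};
#'   the underlying \code{coxph} fit is attached as attribute
#'   \code{"fit"}.
#' @export
cox_fit <- function(outcomes, design, ties = "efron") {
  if (sum(outcomes$event) < 1L) stop("need at least one event", call. = FALSE)
  if (is.null(design) || NCOL(design) == 0L) {
    return(structure(data.frame(term = character(0), coef = numeric(0),
                                HR = numeric(0), SE = numeric(0),
                                Z = numeric(0), p = numeric(0)),
                     class = c("cox_result", "data.frame")))
  }
  df <- cbind(outcomes[c("time", "event")], as.data.frame(design))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ., data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50L)),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Loglik converged before|Ran out of iterations",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || any(abs(co) > 15)) {
    bad <- names(co)[!is.finite(co) | abs(co) > 15]
    stop("monotone partial likelihood (separation) for term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (fit$iter >= 50L) stop("Cox fit did not converge in 50 iterations",
                            call. = FALSE)
  s <- summary(fit)$coefficients
  structure(data.frame(term = rownames(s), coef = s[, "coef"],
                       HR = s[, "exp(coef)"], SE = s[, "se(coef)"],
                       Z = s[, "z"], p = s[, "Pr(>|z|)"],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("cox_result", "data.frame"), fit = fit)
}

# design matrix of adjusters (location enters as a factor)
adjuster_design <- function(cohort, adjusters) {
  if (is.null(adjusters) || length(adjusters) == 0L) {
    return(data.frame(row.names = seq_len(nrow(cohort))))
  }
  miss <- setdiff(adjusters, names(cohort))
  if (length(miss)) stop("adjuster column(s) missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- cohort[adjusters]
  for (nm in names(d)) if (is.character(d[[nm]])) d[[nm]] <- factor(d[[nm]])
  d
}

# copies of alleles mapping to TRUE under `is_member`, per subject
carrier_copies <- function(cohort, is_member) {
  memb <- function(x) {
    ux <- unique(x)
    vapply(ux, is_member, logical(1), USE.NAMES = FALSE)[match(x, ux)]
  }
  m1 <- memb(collapse_alleles(as.character(cohort$drb1_1)))
  m2 <- memb(collapse_alleles(as.character(cohort$drb1_2)))
  as.integer(m1) + as.integer(m2)
}

#' One-vs-rest Cox association per category
#'
#' For each category the model term is a carriage indicator (subject has
#' at least one chromosome of that category) versus all other categories
#' combined, adjusted for \code{adjusters}.
#'
#' @param cohort Subject data.frame with \code{drb1_1}, \code{drb1_2} and
#'   adjuster columns.
#' @param outcomes Outcome data.frame aligned to \code{cohort} rows.
#' @param mapper Mapper from allele to category (see \code{\link{mappers}}).
#' @param adjusters Character vector of adjuster column names.
#' @param categories Categories to test; default every category observed.
#' @return data.frame of \code{cox_result} rows (carrier term only), one
#'   per category; individual fits in attribute \code{"fits"}.
#' @export
cox_one_vs_rest <- function(cohort, outcomes, mapper,
                            adjusters = c("sex", "family_history", "location"),
                            categories = NULL) {
  a1 <- map_chr(collapse_alleles(as.character(cohort$drb1_1)), mapper)
  a2 <- map_chr(collapse_alleles(as.character(cohort$drb1_2)), mapper)
  categories <- categories %||% sort(unique(stats::na.omit(c(a1, a2))))
  adj <- adjuster_design(cohort, adjusters)
  fits <- list()
  rows <- lapply(categories, function(cat) {
    carrier <- as.integer((!is.na(a1) & a1 == cat) | (!is.na(a2) & a2 == cat))
    if (sum(carrier) == 0L) stop("category carried by nobody: ", cat,
                                 call. = FALSE)
    design <- cbind(data.frame(carrier = carrier), adj)
    res <- tryCatch(cox_fit(outcomes, design), error = function(e) e)
    if (inherits(res, "error")) {
      # typically a rare category with monotone likelihood: report, move on
      return(data.frame(term = cat, coef = NA_real_, HR = NA_real_,
                        SE = NA_real_, Z = NA_real_, p = NA_real_,
                        note = conditionMessage(res),
                        stringsAsFactors = FALSE))
    }
    fits[[cat]] <<- attr(res, "fit")
    r <- res[res$term == "carrier", , drop = FALSE]
    r$term <- cat
    r$note <- ""
    r
  })
  structure(do.call(rbind, rows), class = c("cox_result", "data.frame"),
            fits = fits)
}

#' Multivariable Cox model of motif groups against a reference group
#'
#' One carriage indicator per non-reference group enters a single model
#' together with the adjusters; subjects carrying only reference-group
#' alleles form the baseline.
#'
#' @param cohort Subject data.frame.
#' @param outcomes Outcome data.frame aligned to \code{cohort}.
#' @param groups Named list: group label -> character vector of motifs
#'   (or other mapper categories) belonging to the group.
#' @param reference Name of the reference group.
#' @param mapper Mapper from allele to the category space of
#'   \code{groups}.
#' @param adjusters Adjuster column names.
#' @return \code{cox_result} rows for the group indicators.
#' @export
cox_multivar_reference <- function(cohort, outcomes, groups, reference,
                                   mapper,
                                   adjusters = c("sex", "family_history",
                                                 "location")) {
  if (!reference %in% names(groups)) stop("unknown reference group",
                                          call. = FALSE)
  a1 <- map_chr(collapse_alleles(as.character(cohort$drb1_1)), mapper)
  a2 <- map_chr(collapse_alleles(as.character(cohort$drb1_2)), mapper)
  test_groups <- setdiff(names(groups), reference)
  ind <- lapply(test_groups, function(g) {
    as.integer(a1 %in% groups[[g]] | a2 %in% groups[[g]])
  })
  names(ind) <- test_groups
  ind <- ind[vapply(ind, function(v) sum(v) > 0L, logical(1))]
  if (length(ind) == 0L) {
    return(structure(data.frame(term = character(0), coef = numeric(0),
                                HR = numeric(0), SE = numeric(0),
                                Z = numeric(0), p = numeric(0)),
                     class = c("cox_result", "data.frame")))
  }
  design <- cbind(as.data.frame(ind), adjuster_design(cohort, adjusters))
  res <- cox_fit(outcomes, design)
  structure(res[res$term %in% names(ind), , drop = FALSE],
            class = c("cox_result", "data.frame"), fit = attr(res, "fit"))
}

#' Genotype dose-response model for one motif
#'
#' Indicators for carrying exactly one and exactly two copies of the
#' motif, against the zero-copy genotype as reference.  Per-genotype
#' Kaplan-Meier incidence curves are attached for plotting.
#'
#' @param cohort Subject data.frame.
#' @param outcomes Outcome data.frame aligned to \code{cohort}.
#' @param is_member Predicate: allele name -> \code{TRUE} if the allele
#'   carries the motif.
#' @param adjusters Adjuster column names.
#' @return \code{cox_result} rows (\code{het}, \code{hom} when present);
#'   attribute \code{"km"} holds a per-genotype incidence data.frame.
#' @export
genotype_dose_assoc <- function(cohort, outcomes, is_member,
                                adjusters = c("sex", "family_history",
                                              "location")) {
  copies <- carrier_copies(cohort, is_member)
  ind <- data.frame(het = as.integer(copies == 1L),
                    hom = as.integer(copies == 2L))
  if (sum(ind$hom) == 0L) {
    message("no homozygote present; dose model has heterozygote term only")
    ind$hom <- NULL
  }
  if (sum(ind$het) == 0L) stop("no motif carrier present", call. = FALSE)
  design <- cbind(ind, adjuster_design(cohort, adjusters))
  res <- cox_fit(outcomes, design)
  km <- do.call(rbind, lapply(sort(unique(copies)), function(k) {
    ki <- km_incidence(outcomes[copies == k, , drop = FALSE])
    data.frame(genotype = c("other/other", "motif/other", "motif/motif")[k + 1L],
               ki)
  }))
  structure(res[res$term %in% c("het", "hom"), , drop = FALSE],
            class = c("cox_result", "data.frame"), fit = attr(res, "fit"),
            km = km)
}

#' Grambsch-Therneau proportional-hazards diagnostic
#'
#' Scaled Schoenfeld residuals regressed on transformed event times
#' (\code{survival::cox.zph}); per-term and global chi-square tests.
#'
#' @param fit A \code{cox_result} (with attached fit) or a \code{coxph}.
#' @param transform Time transform, default \code{"km"}.
#' @return Object of class \code{ph_diagnostic}: data.frame \code{term},
#'   \code{chisq}, \code{df}, \code{p} including the \code{GLOBAL} row;
#'   attribute \code{transform}.
#' @export
ph_diagnostic <- function(fit, transform = "km") {
  cox <- if (inherits(fit, "coxph")) fit else attr(fit, "fit")
  if (is.null(cox)) stop("no coxph fit attached", call. = FALSE)
  if (sum(cox$nevent) < 2L) stop("need at least two events", call. = FALSE)
  z <- survival::cox.zph(cox, transform = transform)
  tab <- as.data.frame(z$table)
  structure(data.frame(term = rownames(tab), chisq = tab$chisq,
                       df = tab$df, p = tab$p, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("ph_diagnostic", "data.frame"), transform = transform)
}
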