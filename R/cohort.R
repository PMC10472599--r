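#' Filter a bulk cohort to informative AML cases
#'
#' Keeps non-duplicate patients with blast percentage strictly above
#' \code{min_blast} and drops the M3 subtype (treated by differentiation
#' therapy rather than chemotherapy).
#'
#' @param records patient data.frame with \code{patient_id},
#'   \code{blast_pct}, \code{FAB}
#' @param min_blast strict blast cutoff (default 60)
#' @param drop_fab subtypes to exclude (default "M3")
#' @return filtered data.frame (first occurrence of duplicated ids kept)
#' @export
filter_cohort <- function(records, min_blast = 60, drop_fab = "M3") {
  stopifnot(all(c("patient_id", "blast_pct", "FAB") %in% names(records)))
  keep <- records$blast_pct > min_blast &
    !records$FAB %in% drop_fab &
    !duplicated(records$patient_id)
  records[keep, , drop = FALSE]
}

#' Stratify patients by CD69+ HSC-like abundance
#'
#' @param fractions per-patient CD69+ HSC-like proportions
#' @param high_cutoff strict lower bound for "high" (default 0.25)
#' @param low_cutoff strict upper bound for "low" (default 0.10)
#' @return character vector in \{high, middle, low\}; the middle stratum is
#'   excluded from two-group tests downstream
#' @export
stratify_by_cd69 <- function(fractions, high_cutoff = 0.25,
                             low_cutoff = 0.10) {
  if (low_cutoff >= high_cutoff) stop("low_cutoff must be < high_cutoff")
  ifelse(fractions > high_cutoff, "high",
         ifelse(fractions < low_cutoff, "low", "middle"))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value by probability-mass ordering over the hypergeometric
#' support with fixed margins: the sum of probabilities of tables no more
#' likely than the observed one (with a 1 + 1e-7 relative tolerance, the
#' convention of standard statistical software). The odds ratio is the
#' sample ratio ad/bc.
#'
#' @param tab 2x2 nonnegative integer matrix with positive margins
#' @return list: \code{p} (two-sided), \code{odds_ratio}
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 nonnegative integer table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(1, p), odds_ratio = or)
}

#' MRD positivity rates per group with a Fisher test
#'
#' A patient is MRD-positive if the MRD level is >= \code{cutoff} (percent).
#'
#' @param mrd_pct per-patient MRD percentages
#' @param groups per-patient labels; only "high" and "low" are tested
#' @param cutoff positivity cutoff in percent (default 0.1)
#' @return list: \code{table} (2x2 positives/negatives by group),
#'   \code{rates} (named), \code{p}
#' @export
mrd_positivity <- function(mrd_pct, groups, cutoff = 0.1) {
  sel <- groups %in% c("high", "low") & !is.na(mrd_pct)
  pos <- mrd_pct[sel] >= cutoff
  g <- factor(groups[sel], levels = c("high", "low"))
  tab <- rbind(high = c(sum(pos & g == "high"), sum(!pos & g == "high")),
               low = c(sum(pos & g == "low"), sum(!pos & g == "low")))
  colnames(tab) <- c("positive", "negative")
  rates <- tab[, "positive"] / rowSums(tab)
  p <- if (sum(tab[, "positive"]) == 0) 1 else fisher_exact_2x2(tab)$p
  list(table = tab, rates = rates, p = p)
}

#' Bulk differential expression between patient groups
#'
#' Per-gene rank-sum test on linear-scale values with a fold-change filter:
#' genes with |fold| >= \code{fold_min}, p < \code{p_max} and BH-FDR <
#' \code{q_max} are reported.
#'
#' @param bulk genes x patients matrix, log2(x + 1) scale by default
#' @param groups per-patient labels in \{high, low\} (others ignored)
#' @param fold_min linear fold-change threshold (default 1.3)
#' @param p_max,q_max significance thresholds
#' @param input_log2 un-log to the linear scale before testing
#' @return data.frame: \code{gene}, \code{fold} (high/low, linear),
#'   \code{direction}, \code{p}, \code{q}
#' @export
bulk_deg <- function(bulk, groups, fold_min = 1.3, p_max = 0.01,
                     q_max = 0.05, input_log2 = TRUE) {
  hi <- which(groups == "high"); lo <- which(groups == "low")
  if (length(hi) < 3 || length(lo) < 3)
    stop("need at least 3 patients per group")
  x <- as.matrix(bulk)
  if (input_log2) x <- 2^x - 1
  mh <- rowMeans(x[, hi, drop = FALSE]) + 1e-9
  ml <- rowMeans(x[, lo, drop = FALSE]) + 1e-9
  fold <- mh / ml
  p <- vapply(seq_len(nrow(x)), function(i)
    rank_sum_p(x[i, hi], x[i, lo]), 0)
  q <- stats::p.adjust(p, "BH")
  keep <- (fold >= fold_min | fold <= 1 / fold_min) & p < p_max & q < q_max
  data.frame(gene = rownames(x)[keep], fold = fold[keep],
             direction = ifelse(fold[keep] >= 1, "up", "down"),
             p = p[keep], q = q[keep],
             stringsAsFactors = FALSE)[order(p[keep]), , drop = FALSE]
}

#' Kaplan-Meier curves and the log-rank test for two groups
#'
#' Product-limit estimator per group (deaths precede censorings at tied
#' times) and the standard 1-df log-rank statistic.
#'
#' @param time event/censoring times (>= 0)
#' @param event logical/0-1 event indicators
#' @param group two-level group labels
#' @return list: \code{curves} (per group: data.frame time, n_risk,
#'   n_event, surv), \code{chisq}, \code{p}
#' @export
km_logrank <- function(time, event, group) {
  event <- as.logical(event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) == 0)) stop("a group has zero subjects")
  if (sum(event) == 0) stop("need at least one event")
  km_one <- function(sel) {
    tt <- time[sel]; ev <- event[sel]
    ut <- sort(unique(tt[ev]))
    n_risk <- vapply(ut, function(u) sum(tt >= u), 0)
    n_event <- vapply(ut, function(u) sum(tt == u & ev), 0)
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
  }
  curves <- lapply(levels(g), function(l) km_one(g == l))
  names(curves) <- levels(g)
  ut <- sort(unique(time[event]))
  o_minus_e <- 0; v <- 0
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(time == u & event)
    d1 <- sum(time == u & event & g == levels(g)[1])
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = chisq, p = p)
}

#' Univariate-to-multivariate Cox proportional-hazards workflow
#'
#' Fits a univariate Cox model (Efron ties, Wald tests) per covariate;
#' covariates with univariate p below \code{entry_p} enter one multivariate
#' fit, after dropping members of strongly correlated pairs (|r| >
#' \code{cor_cutoff}; the larger univariate p is dropped). Non-converging
#' covariates are excluded with a warning.
#'
#' @param records data.frame with time/event columns and covariates
#' @param covariates covariate column names
#' @param time_col,event_col survival column names
#' @param entry_p multivariate entry threshold (default 0.10)
#' @param cor_cutoff pairwise correlation cutoff (default 0.8)
#' @return list: \code{univariate} (data.frame: covariate, hr, lo95, hi95,
#'   p), \code{multivariate} (same shape, possibly empty), \code{fit}
#'   (multivariate coxph object or NULL)
#' @export
cox_model <- function(records, covariates, time_col = "os_time",
                      event_col = "os_event", entry_p = 0.10,
                      cor_cutoff = 0.8) {
  stopifnot(all(c(time_col, event_col, covariates) %in% names(records)))
  if (sum(records[[event_col]]) < 10)
    warning("fewer than 10 events; multivariate fit may be unstable")
  surv <- survival::Surv(records[[time_col]],
                         as.numeric(records[[event_col]]))
  fit_one <- function(vars) {
    f <- stats::as.formula(paste("surv ~",
                                 paste(sprintf("`%s`", vars), collapse = "+")))
    survival::coxph(f, data = records, ties = "efron")
  }
  uni <- lapply(covariates, function(v) {
    flagged <- FALSE
    fit <- tryCatch(
      withCallingHandlers(fit_one(v), warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    s <- summary(fit)
    data.frame(covariate = v, hr = s$conf.int[1, "exp(coef)"],
               lo95 = s$conf.int[1, "lower .95"],
               hi95 = s$conf.int[1, "upper .95"],
               p = s$coefficients[1, "Pr(>|z|)"],
               flagged = flagged,
               stringsAsFactors = FALSE)
  })
  failed <- covariates[vapply(uni, is.null, TRUE)]
  if (length(failed))
    warning("covariate(s) excluded (non-convergence): ",
            paste(failed, collapse = ", "))
  uni <- do.call(rbind, uni)
  enter <- uni$covariate[!is.na(uni$p) & uni$p < entry_p & !uni$flagged]
  # prune strongly correlated pairs, keeping the smaller univariate p
  if (length(enter) > 1) {
    num <- vapply(records[enter], as.numeric, numeric(nrow(records)))
    cm <- suppressWarnings(stats::cor(num))
    ord <- enter[order(uni$p[match(enter, uni$covariate)])]
    kept <- character()
    for (v in ord) {
      if (all(abs(cm[v, kept]) <= cor_cutoff | is.na(cm[v, kept])))
        kept <- c(kept, v)
    }
    enter <- kept
  }
  multi <- data.frame(covariate = character(), hr = numeric(),
                      lo95 = numeric(), hi95 = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  mfit <- NULL
  if (length(enter)) {
    mfit <- fit_one(enter)
    s <- summary(mfit)
    multi <- data.frame(covariate = enter,
                        hr = s$conf.int[, "exp(coef)"],
                        lo95 = s$conf.int[, "lower .95"],
                        hi95 = s$conf.int[, "upper .95"],
                        p = s$coefficients[, "Pr(>|z|)"],
                        stringsAsFactors = FALSE)
  }
  list(univariate = uni, multivariate = multi, fit = mfit)
}
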