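#' @include hubs.R
NULL

#' Ordinary least-squares fit of one outcome on one predictor
#'
#' Simple linear regression via [stats::lm()], returning the quantities the
#' clinical screen reports: slope, intercept, coefficient of determination
#' and sample size. A constant outcome yields slope 0 and `r_squared` 0
#' (nothing to explain); otherwise `r_squared` is 1 exactly when all
#' residuals vanish.
#'
#' @param x predictor (e.g. edge connectivity), length n >= 3,
#'   non-constant.
#' @param y outcome, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' olsFit(0:9, 2 * (0:9) + 1)  # slope 2, intercept 1, R^2 = 1
#' @export
olsFit <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, n = n)
}

#' Screen atypical edges for linear association with a clinical outcome
#'
#' For every supplied edge, regresses the patients' outcome on that edge's
#' connectivity value across patients and reports the fit, sorted by R
#' squared descending; edges at or above `r2Threshold` are flagged (the
#' reference screen keeps R^2 >= 0.10).
#'
#' @param patients list of patient [ConnectivityMatrix-class] objects.
#' @param edges data.frame with 0-based `seed_index`, `atlas_index` (e.g.
#'   from [edgeCounts()] or [recurrentEdges()]).
#' @param clinical clinical data.frame (see [validateClinicalTable()]).
#' @param outcome outcome column name (default `"vas_pct"`).
#' @param r2Threshold flag threshold on R squared (default 0.10).
#' @return data.frame of per-edge fits with a `flagged` column; patients
#'   with missing outcome are excluded with a warning giving the count.
#' @export
correlateEdgesWithOutcome <- function(patients, edges, clinical,
                                      outcome = "vas_pct",
                                      r2Threshold = 0.10) {
  validateClinicalTable(clinical)
  if (!outcome %in% names(clinical))
    stop("no such outcome column: ", outcome, call. = FALSE)
  ids <- vapply(patients, subjectId, character(1L))
  y <- clinical[[outcome]][match(ids, clinical$subject_id)]
  if (anyNA(y)) {
    nbad <- sum(is.na(y))
    warning(nbad, " patient(s) missing '", outcome, "' excluded from fits",
            call. = FALSE)
    patients <- patients[!is.na(y)]
    y <- y[!is.na(y)]
  }
  fits <- lapply(seq_len(nrow(edges)), function(i) {
    si <- edges$seed_index[i]; ai <- edges$atlas_index[i]
    x <- vapply(patients, function(m) connValues(m)[si + 1L, ai + 1L],
                numeric(1L))
    f <- olsFit(x, y)
    data.frame(seed_index = si, atlas_index = ai, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared, n = f$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  out$outcome <- outcome
  out$flagged <- out$r_squared >= r2Threshold
  out <- out[order(-out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Age-outcome correlation stratified by sex
#'
#' Pearson correlation between patient age and a clinical outcome within
#' each sex stratum, with the two-sided t-based p-value from
#' [stats::cor.test()]; strata with fewer than 3 complete patients are
#' skipped with a warning.
#'
#' @param clinical clinical data.frame.
#' @param outcome outcome column (default `"vas_pct"`).
#' @return data.frame `sex`, `n`, `r`, `p_value`.
#' @export
ageOutcomeBySex <- function(clinical, outcome = "vas_pct") {
  validateClinicalTable(clinical)
  pats <- clinical[clinical$group == "patient", , drop = FALSE]
  out <- lapply(sort(unique(pats$sex)), function(s) {
    d <- pats[pats$sex == s & !is.na(pats[[outcome]]) & !is.na(pats$age), ]
    if (nrow(d) < 3L) {
      warning("sex stratum '", s, "' has fewer than 3 patients; skipped",
              call. = FALSE)
      return(NULL)
    }
    ct <- stats::cor.test(d$age, d[[outcome]])
    data.frame(sex = s, n = nrow(d), r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sex = character(), n = integer(), r = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group confounder screen
#'
#' Tests whether patients and controls differ on age and mean framewise
#' displacement (Welch two-sample t-tests) and on sex (chi-square with
#' continuity correction, or Fisher's exact test when any expected cell is
#' below 5); each p-value is compared against the 0.1 screen used to rule
#' the variables out as confounders.
#'
#' @param clinical clinical data.frame with both groups present.
#' @return data.frame `variable`, `test`, `statistic`, `p_value`,
#'   `pass_screen` (TRUE when p > 0.1).
#' @export
confounderCheck <- function(clinical) {
  validateClinicalTable(clinical)
  pat <- clinical[clinical$group == "patient", , drop = FALSE]
  ctl <- clinical[clinical$group == "control", , drop = FALSE]
  if (!nrow(pat) || !nrow(ctl))
    stop("both groups must be non-empty", call. = FALSE)
  rows <- list()
  for (v in c("age", "mean_fd")) {
    # t.test() errors when both groups are constant; that case is a clean
    # "no difference" (t = 0, p = 1)
    if (stats::sd(pat[[v]]) == 0 && stats::sd(ctl[[v]]) == 0 &&
        pat[[v]][1L] == ctl[[v]][1L]) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(pat[[v]], ctl[[v]])
    }
    rows[[v]] <- data.frame(variable = v, test = "welch_t",
                            statistic = unname(tt$statistic),
                            p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  tabsex <- table(clinical$group, clinical$sex)
  if (ncol(tabsex) < 2L) {
    rows[["sex"]] <- data.frame(variable = "sex", test = "none",
                                statistic = NA_real_, p_value = 1,
                                stringsAsFactors = FALSE)
  } else {
    expected <- outer(rowSums(tabsex), colSums(tabsex)) / sum(tabsex)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tabsex)
      rows[["sex"]] <- data.frame(variable = "sex", test = "fisher_exact",
                                  statistic = NA_real_, p_value = ft$p.value,
                                  stringsAsFactors = FALSE)
    } else {
      ct <- stats::chisq.test(tabsex, correct = TRUE)
      rows[["sex"]] <- data.frame(variable = "sex", test = "chisq",
                                  statistic = unname(ct$statistic),
                                  p_value = ct$p.value,
                                  stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pass_screen <- out$p_value > 0.1
  rownames(out) <- NULL
  out
}
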