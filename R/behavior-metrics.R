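# Behavioral indices for odor-guided tasks and the factorial effect-size
# statistics reported for them.

#' Recognition index
#'
#' `No / (No + Fo)`: the share of investigation time spent at the novel
#' odor. Values above 0.5 indicate memory of the familiar odor.
#'
#' @param novel_s investigation time at the novel odor (seconds, >= 0).
#' @param familiar_s investigation time at the familiar odor (seconds, >= 0).
#' @return fraction in \[0, 1\]. Vectorized.
#' @export
recognition_index <- function(novel_s, familiar_s) {
  check_pair(novel_s, familiar_s)
  novel_s / (novel_s + familiar_s)
}

#' Dishabituation index
#'
#' `(No - Fo) / (No + Fo)`, computed from the trial-5 novel-odor time and
#' the trial-4 familiar-odor time; positive values indicate renewed
#' investigation upon odor substitution. Satisfies
#' `RI = (DI + 1) / 2` for any pair.
#'
#' @inheritParams recognition_index
#' @return real in \[-1, 1\]. Vectorized.
#' @export
dishabituation_index <- function(novel_s, familiar_s) {
  check_pair(novel_s, familiar_s)
  (novel_s - familiar_s) / (novel_s + familiar_s)
}

check_pair <- function(novel_s, familiar_s) {
  if (any(!is.finite(novel_s)) || any(!is.finite(familiar_s)) ||
      any(novel_s < 0) || any(familiar_s < 0))
    stop_data("investigation times must be finite and nonnegative")
  if (any(novel_s + familiar_s == 0))
    stop_data("undefined index: No + Fo = 0")
  invisible(NULL)
}

#' Preference ratio over simultaneously presented objects
#'
#' Each object's share of the total investigation time; shares sum to 1.
#'
#' @param times_per_object nonnegative vector of per-object times (seconds).
#' @return vector of fractions summing to 1.
#' @export
preference_ratio <- function(times_per_object) {
  if (any(!is.finite(times_per_object)) || any(times_per_object < 0))
    stop_data("times must be finite and nonnegative")
  total <- sum(times_per_object)
  if (total == 0) stop_data("undefined preference ratio: all times zero")
  times_per_object / total
}

#' Anhedonia index
#'
#' Fraction of tracked time not spent engaging odorized objects:
#' `(tracked - total_odor) / tracked`. Immobility periods are retained
#' (no freezing exclusion); higher values reflect reduced hedonic
#' engagement.
#'
#' @param tracked_s total tracked time (seconds, > 0).
#' @param total_odor_s summed odor-object investigation time (seconds).
#' @return fraction in \[0, 1\]. Vectorized.
#' @export
anhedonia_index <- function(tracked_s, total_odor_s) {
  if (any(tracked_s <= 0)) stop_data("tracked time must be positive")
  if (any(total_odor_s > tracked_s))
    stop_data("odor exploration time exceeds tracked time")
  if (any(total_odor_s < 0)) stop_data("odor time must be nonnegative")
  (tracked_s - total_odor_s) / tracked_s
}

#' Area under the concentration-response curve
#'
#' Trapezoidal area of the response series over the concentration axis.
#' Because the series includes a zero (vehicle) concentration, the default
#' abscissa is the equally spaced concentration rank (1..k); set
#' `abscissa = "value"` to integrate over the raw concentrations instead.
#'
#' @param concentrations ascending concentration vector (>= 2 points).
#' @param responses response at each concentration.
#' @param normalize divide responses by their sum first.
#' @param abscissa `"rank"` (default) or `"value"`.
#' @return nonnegative real.
#' @export
exploration_auc <- function(concentrations, responses, normalize = FALSE,
                            abscissa = c("rank", "value")) {
  abscissa <- match.arg(abscissa)
  if (length(concentrations) != length(responses))
    stop_data("concentrations and responses differ in length")
  if (length(concentrations) < 2)
    stop_data("need at least 2 concentration points")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop_data("concentrations must be strictly ascending")
  if (normalize) {
    s <- sum(responses)
    if (s == 0) return(0)
    responses <- responses / s
  }
  x <- if (abscissa == "rank") seq_along(concentrations) else concentrations
  sum(diff(x) * (head(responses, -1) + responses[-1]) / 2)
}

#' Trial-wise habituation curve
#'
#' Mean investigation per habituation/dishabituation trial, over all four
#' objects and for the odor-switched object (object 1) alone. Missing
#' trials yield `NA` entries, never a silent drop.
#'
#' @param trial_table long trial table (the `habdis` task rows of
#'   [generate_behavior()] output, or any table with `subject`, `trial`,
#'   `object`, `investigation_s`).
#' @param trials trials expected present (default 1:5).
#' @return data frame: `subject`, `trial`, `mean_all`, `mean_switched`.
#' @export
habituation_curve <- function(trial_table, trials = 1:5) {
  tt <- trial_table
  if ("task" %in% names(tt)) tt <- tt[tt$task == "habdis", ]
  grid <- expand.grid(subject = unique(tt$subject), trial = trials,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(df$subject, df$trial)
  all_mean <- tapply(tt$investigation_s, key(tt), mean)
  sw <- tt[tt$object == 1, ]
  sw_mean <- tapply(sw$investigation_s, key(sw), mean)
  grid$mean_all <- as.numeric(all_mean[key(grid)])
  grid$mean_switched <- as.numeric(sw_mean[key(grid)])
  grid[order(grid$subject, grid$trial), , drop = FALSE]
}

#' Per-subject behavioral summary
#'
#' Collapses the long trial table to one row per subject: preference share
#' of the strongest odor, raw and normalized exploration AUC, anhedonia
#' index, dishabituation index (trial-5 novel vs trial-4 familiar time on
#' the odor-switched object), and recognition indices at the three memory
#' delays.
#'
#' @param trials long trial table from [generate_behavior()].
#' @return data frame, one row per subject.
#' @export
summarize_behavior <- function(trials) {
  subjects <- unique(trials$subject)
  rows <- lapply(subjects, function(id) {
    tt <- trials[trials$subject == id, ]
    pref <- tt[tt$task == "preference", ]
    by_conc <- tapply(pref$investigation_s, pref$concentration, mean)
    by_conc <- by_conc[order(as.numeric(names(by_conc)))]
    concs <- as.numeric(names(by_conc))
    shares <- preference_ratio(as.numeric(by_conc))
    hab <- tt[tt$task == "habdis", ]
    no <- hab$investigation_s[hab$trial == 5 & hab$object == 1]
    fo <- hab$investigation_s[hab$trial == 4 & hab$object == 1]
    arena <- tt[tt$task %in% c("preference", "habdis"), ]
    akey <- paste(arena$task, arena$trial)
    tot <- tapply(arena$investigation_s, akey, sum)
    trk <- tapply(arena$tracked_s, akey, max)
    mem <- tt[tt$task == "memory", ]
    ri_at <- function(d) {
      m <- mem[mem$delay_h == d, ]
      recognition_index(m$investigation_s[m$odor != "coconut"],
                        m$investigation_s[m$odor == "coconut"])
    }
    data.frame(
      subject = id,
      pref_high = shares[length(shares)],
      auc_raw = exploration_auc(concs, as.numeric(by_conc)),
      auc_norm = exploration_auc(concs, as.numeric(by_conc),
                                 normalize = TRUE),
      anhedonia = mean(anhedonia_index(as.numeric(trk), as.numeric(tot))),
      di = dishabituation_index(no, fo),
      ri_1h = ri_at(1), ri_24h = ri_at(24), ri_48h = ri_at(48),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's f from partial eta squared
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param eta_sq partial eta squared, in \[0, 1).
#' @return nonnegative real. Vectorized.
#' @export
cohens_f <- function(eta_sq) {
  if (any(eta_sq < 0) || any(eta_sq >= 1))
    stop_data("eta squared must lie in [0, 1)")
  sqrt(eta_sq / (1 - eta_sq))
}

#' Factorial ANOVA with Type III sums of squares and effect sizes
#'
#' Least-squares fit with sum-to-zero contrasts for all factors, Type III
#' sums of squares, and per-term F, p, partial eta squared and Cohen's f.
#' Repeated measures should be aggregated to one value per subject before
#' fitting. Optionally attaches bootstrap confidence intervals for the
#' effect sizes.
#'
#' @param outcome numeric outcome vector, one value per design row.
#' @param design data frame of factors (e.g. the trait table).
#' @param terms factor names entering the model; crossed with `*` up to
#'   `max_order`.
#' @param max_order highest interaction order (default full factorial).
#' @param boot number of nonparametric bootstrap resamples for effect-size
#'   CIs (0 disables; default 0).
#' @param conf confidence level for bootstrap CIs.
#' @param seed seed for the bootstrap resampling.
#' @return data frame of per-term entries: `term`, `ss_effect`, `ss_error`,
#'   `df1`, `df2`, `F`, `p`, `partial_eta_sq`, `cohens_f` (plus CI columns
#'   when `boot > 0`).
#' @export
factorial_anova <- function(outcome, design, terms,
                            max_order = length(terms), boot = 0,
                            conf = 0.95, seed = 1L) {
  if (length(outcome) != nrow(design))
    stop_data("outcome length does not match design rows")
  df <- design[, terms, drop = FALSE]
  for (nm in terms) {
    if (!is.numeric(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  df$.y <- outcome
  rhs <- if (max_order >= length(terms)) {
    paste(terms, collapse = " * ")
  } else {
    paste0("(", paste(terms, collapse = " + "), ")^", max_order)
  }
  form <- stats::as.formula(paste(".y ~", rhs))
  contr <- lapply(df[terms], function(x)
    if (is.factor(x)) "contr.sum" else NULL)
  contr <- contr[!vapply(contr, is.null, logical(1))]
  fit <- lm(form, data = df, contrasts = contr)
  if (fit$rank < ncol(model.matrix(fit))) {
    aliased <- names(which(is.na(coef(fit))))
    stop_data("rank-deficient design; aliased terms: ",
              paste(aliased, collapse = ", "))
  }
  if (sd(outcome) == 0) {
    # All-equal outcome: every effect and residual SS is zero by
    # construction; report F = 0 rather than 0/0.
    labs <- attr(stats::terms(form), "term.labels")
    tab <- data.frame(term = labs, ss_effect = 0, ss_error = 0,
                      df1 = NA_integer_, df2 = fit$df.residual, F = 0,
                      p = 1, partial_eta_sq = 0, cohens_f = 0,
                      stringsAsFactors = FALSE)
  } else {
    tab <- effect_table(fit)
  }
  if (boot > 0) {
    idx <- seq_len(nrow(df))
    draws <- withr::with_seed(seed, replicate(boot, {
      b <- sample(idx, replace = TRUE)
      fb <- try(lm(form, data = df[b, ], contrasts = contr), silent = TRUE)
      if (inherits(fb, "try-error")) rep(NA_real_, nrow(tab))
      else {
        tb <- try(effect_table(fb), silent = TRUE)
        if (inherits(tb, "try-error")) rep(NA_real_, nrow(tab))
        else tb$partial_eta_sq[match(tab$term, tb$term)]
      }
    }))
    draws <- matrix(draws, nrow = nrow(tab))
    a <- (1 - conf) / 2
    qs <- t(apply(draws, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
    tab$eta_sq_lo <- qs[, 1]
    tab$eta_sq_hi <- qs[, 2]
    tab$f_lo <- cohens_f(pmin(qs[, 1], 1 - 1e-12))
    tab$f_hi <- cohens_f(pmin(qs[, 2], 1 - 1e-12))
  }
  attr(tab, "fit") <- fit
  tab
}

effect_table <- function(fit) {
  a3 <- car::Anova(fit, type = 3, singular.ok = FALSE)
  a3 <- as.data.frame(a3)
  ss_err <- a3["Residuals", "Sum Sq"]
  df2 <- a3["Residuals", "Df"]
  keep <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  ss <- a3[keep, "Sum Sq"]
  df1 <- a3[keep, "Df"]
  # Degenerate all-equal outcome: no variance anywhere; report F = 0.
  if (ss_err == 0 && all(ss < 1e-12)) {
    Fv <- rep(0, length(keep))
    p <- rep(1, length(keep))
    eta <- rep(0, length(keep))
  } else {
    Fv <- (ss / df1) / (ss_err / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
    eta <- ss / (ss + ss_err)
  }
  data.frame(term = keep, ss_effect = ss, ss_error = ss_err,
             df1 = df1, df2 = df2, F = Fv, p = p,
             partial_eta_sq = eta, cohens_f = cohens_f(pmin(eta, 1 - 1e-15)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimated marginal means
#'
#' Model-predicted cell means for the focal factors, averaged with equal
#' weights over all other factors in the model, with normal-approximation
#' confidence intervals.
#'
#' @param fit an `lm` fit (e.g. `attr(factorial_anova(...), "fit")`).
#' @param focal_factors character vector of focal factor names.
#' @param conf confidence level.
#' @return data frame with the focal levels, `emmean`, `se`, `lower`,
#'   `upper`.
#' @export
estimated_marginal_means <- function(fit, focal_factors, conf = 0.95) {
  em <- emmeans::emmeans(fit, specs = focal_factors, level = conf,
                         weights = "equal")
  out <- as.data.frame(em)
  if (any(is.na(out$emmean))) {
    bad <- out[is.na(out$emmean), focal_factors, drop = FALSE]
    stop_data("empty design cell(s): ",
              paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "))
  }
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) %in% c("lower.CL", "asymp.LCL")] <- "lower"
  names(out)[names(out) %in% c("upper.CL", "asymp.UCL")] <- "upper"
  out
}

#' Post hoc contrasts for a fitted factorial model
#'
#' Tukey-adjusted all-pairwise contrasts, or Sidak-adjusted planned
#' contrasts, on the estimated marginal means of a focal factor.
#'
#' @param fit an `lm` fit.
#' @param factor_name focal factor.
#' @param method `"tukey"` for all-pairwise or `"sidak"` for planned pairs.
#' @return data frame of contrasts with adjusted p-values.
#' @export
posthoc_contrasts <- function(fit, factor_name,
                              method = c("tukey", "sidak")) {
  method <- match.arg(method)
  em <- emmeans::emmeans(fit, specs = factor_name, weights = "equal")
  as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = method))
}
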