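#' Deviation coding helpers
#'
#' `deviation_code()` codes a two-level factor as -0.5/+0.5 (reference
#' level -0.5), so the fitted coefficient is the second-minus-reference
#' difference and the intercept stays at the grand mean of a balanced
#' design. `ref_deviation_contrasts()` generalizes this to k levels with a
#' designated reference: it returns the k x (k-1) coding matrix whose
#' coefficients equal each non-reference level's mean minus the reference
#' level's mean, while the intercept remains the (unweighted) grand mean —
#' the coding used for group effects estimated in reference to a clinical
#' group.
#'
#' @param x A factor or character vector with exactly two levels.
#' @param reference The reference level (coded -0.5 / compared against).
#' @return For `deviation_code()`, a numeric vector; for
#'   `ref_deviation_contrasts()`, a named coding matrix.
#' @examples
#' ref_deviation_contrasts(c("OCD", "HC", "SAD"), reference = "OCD")
#' @export
deviation_code <- function(x, reference = NULL) {
  f <- as.factor(x)
  if (nlevels(f) != 2L) abort("`x` must have exactly two levels.")
  lev <- levels(f)
  if (!is.null(reference)) {
    if (!reference %in% lev) abort(sprintf("Unknown level '%s'.", reference))
    lev <- c(reference, setdiff(lev, reference))
  }
  ifelse(as.character(f) == lev[1], -0.5, 0.5)
}

#' @rdname deviation_code
#' @param levels Character vector of factor levels.
#' @export
ref_deviation_contrasts <- function(levels, reference = levels[1]) {
  k <- length(levels)
  if (!reference %in% levels) abort(sprintf("Unknown level '%s'.", reference))
  others <- setdiff(levels, reference)
  # Hypothesis matrix: intercept = grand mean; each row = level - reference.
  h <- rbind(rep(1 / k, k),
             t(vapply(others, function(l) {
               (levels == l) - (levels == reference)
             }, numeric(k))))
  codes <- solve(h)[, -1, drop = FALSE]
  dimnames(codes) <- list(levels, paste0(others, "_vs_", reference))
  codes
}

#' Add the standard trial-level predictor codings
#'
#' Adds the coded columns the trial-level models use: OCD-referenced group
#' contrast columns (`group_HC`, `group_SAD`), deviation-coded agency
#' (`agency_dev`, active = -0.5), feedback valence (`valence_dev`,
#' win = -0.5), block centered around the block midpoint (`block_c` =
#' block - 2.5 for four blocks), and reward contingency coded -1/0/1 from
#' high to low win probability (`contingency_c`: 80% pair -1, 70% pair 0,
#' 60% pair +1). Columns are added only where their source column exists.
#'
#' @param data Trial-level data (coded trials or single-trial scores).
#' @param group_ref Reference group for the group contrasts.
#' @param block_mid Value the block predictor is centered on.
#' @return `data` with the coded columns appended.
#' @export
code_predictors <- function(data, group_ref = "OCD", block_mid = 2.5) {
  if ("group" %in% names(data)) {
    lev <- unique(as.character(data$group))
    lev <- c(group_ref, sort(setdiff(lev, group_ref)))
    codes <- ref_deviation_contrasts(lev, reference = group_ref)
    for (j in seq_len(ncol(codes))) {
      nm <- paste0("group_", sub(paste0("_vs_", group_ref), "",
                                 colnames(codes)[j]))
      data[[nm]] <- codes[match(as.character(data$group), lev), j]
    }
  }
  # two-level deviation codings, added only when both levels are present
  two_level <- function(col, ref) {
    if (!col %in% names(data)) return(NULL)
    x <- data[[col]]
    if (col == "feedback") x[x == "none"] <- NA
    if (dplyr::n_distinct(x, na.rm = TRUE) != 2L) return(NULL)
    out <- rep(NA_real_, length(x))
    out[!is.na(x)] <- deviation_code(x[!is.na(x)], reference = ref)
    out
  }
  set_if <- function(d, name, value) {
    if (!is.null(value)) d[[name]] <- value
    d
  }
  data <- data |>
    set_if("agency_dev", two_level("agency", "active")) |>
    set_if("valence_dev", two_level("feedback", "win")) |>
    set_if("prev_valence_dev", two_level("prev_feedback_valence", "win")) |>
    set_if("prev_auth_dev",
           two_level("prev_feedback_authenticity", "authentic")) |>
    set_if("learning_dev", two_level("learning_status", "pre"))
  if ("correct" %in% names(data)) {
    data$accuracy_dev <- ifelse(data$correct, -0.5, 0.5) # correct = ref
  }
  if ("block" %in% names(data)) {
    data$block_c <- data$block - block_mid
  }
  if ("pair" %in% names(data)) {
    contingency <- c("A/B" = -1, "C/D" = 0, "E/F" = 1)
    if (all(unique(data$pair) %in% names(contingency))) {
      data$contingency_c <- unname(contingency[data$pair])
    }
  }
  if ("spe" %in% names(data)) {
    data$spe_c <- data$spe - mean(data$spe, na.rm = TRUE)
  }
  data
}

# Decompose a mixed-model formula into its fixed part and random terms.
re_terms <- function(formula) {
  bars <- lme4::findbars(formula)
  purrr::map(bars, function(b) {
    list(lhs = deparse(b[[2]]), group = deparse(b[[3]]))
  })
}

interaction_order <- function(term) length(strsplit(term, ":")[[1]])

# Build the deterministic backoff sequence of random-effects
# specifications, from maximal to intercept-only:
#   1. the maximal structure as given;
#   2. the same slopes with correlations removed (||);
#   3. uncorrelated slopes dropped one order at a time, highest-order
#      interaction slopes first;
#   4. the by-participant intercept, which is never removed.
# Secondary intercept-only terms (e.g. by-electrode) are retained
# throughout.
backoff_sequence <- function(formula) {
  fixed <- deparse(lme4::nobars(formula))
  fixed <- paste(fixed, collapse = " ")
  res <- re_terms(formula)
  slope_term <- purrr::detect(res, ~ .x$lhs != "1")
  intercept_terms <- purrr::keep(res, ~ .x$lhs == "1")
  icpt <- purrr::map_chr(intercept_terms,
                         ~ sprintf("(1 | %s)", .x$group))
  specs <- character()
  if (!is.null(slope_term)) {
    slopes <- attr(stats::terms(as.formula(paste("~", slope_term$lhs))),
                   "term.labels")
    g <- slope_term$group
    specs <- c(specs,
               sprintf("(1 + %s | %s)", paste(slopes, collapse = " + "), g),
               sprintf("(1 + %s || %s)", paste(slopes, collapse = " + "), g))
    ord <- vapply(slopes, interaction_order, 1L)
    for (o in sort(unique(ord), decreasing = TRUE)) {
      slopes <- slopes[vapply(slopes, interaction_order, 1L) < o]
      spec <- if (length(slopes)) {
        sprintf("(1 + %s || %s)", paste(slopes, collapse = " + "), g)
      } else {
        sprintf("(1 | %s)", g)
      }
      specs <- c(specs, spec)
    }
    specs <- purrr::map_chr(specs, ~ paste(c(.x, icpt), collapse = " + "))
  } else {
    specs <- paste(icpt, collapse = " + ")
  }
  unique(paste(fixed, "+", specs))
}

#' Fit a mixed-effects model with deterministic random-effects backoff
#'
#' Attempts the maximal random-effects structure first. On non-convergence
#' or a singular fit, the structure is simplified in a fixed order —
#' random-slope correlations first, then interaction slopes from the
#' highest order down, then the remaining slopes — and refitted; the
#' by-participant intercept (and any secondary intercept-only term, e.g.
#' by electrode) is never removed. Gaussian models are fitted with
#' [lmerTest::lmer()] (Satterthwaite degrees of freedom available
#' downstream); binomial models with [lme4::glmer()] (Wald/LRT inference).
#'
#' @param formula Full mixed-model formula including the maximal
#'   random-effects structure, e.g.
#'   `acc ~ group_HC * agency_dev + (1 + agency_dev | participant_id)`.
#' @param data Trial-level data (see [code_predictors()]).
#' @param family `"gaussian"` or `"binomial"`.
#' @param backoff Apply the backoff policy (default TRUE; otherwise only
#'   the maximal model is attempted).
#' @return An object of class `mixed_fit`: list with the fitted `model`,
#'   the `formula` actually used, and a `backoff_log` tibble (one row per
#'   attempt with its status: `"ok"`, `"singular"`, `"no_convergence"` or
#'   `"error"`). Has [tidy()] and [glance()] methods.
#' @export
fit_mixed <- function(formula, data, family = c("gaussian", "binomial"),
                      backoff = TRUE) {
  family <- match.arg(family)
  specs <- backoff_sequence(formula)
  if (!backoff) specs <- specs[1]
  log <- tibble::tibble(step = integer(), formula = character(),
                        status = character())
  for (s in seq_along(specs)) {
    f <- as.formula(specs[s])
    fit <- tryCatch(suppressMessages({
      if (family == "gaussian") {
        lmerTest::lmer(f, data = data,
                       control = lme4::lmerControl(calc.derivs = FALSE))
      } else {
        lme4::glmer(f, data = data, family = binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE))
      }
    }), error = function(e) e)
    status <- if (inherits(fit, "error")) {
      "error"
    } else if (lme4::isSingular(fit, tol = 1e-4)) {
      "singular"
    } else if (length(fit@optinfo$conv$lme4$messages) > 0) {
      "no_convergence"
    } else {
      "ok"
    }
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = s, formula = specs[s], status = status))
    if (status == "ok") {
      return(structure(list(model = fit, formula = specs[s],
                            family = family, backoff_log = log),
                       class = "mixed_fit"))
    }
  }
  # No spec converged cleanly; return the last non-error fit if any.
  if (!inherits(fit, "error")) {
    return(structure(list(model = fit, formula = specs[length(specs)],
                          family = family, backoff_log = log),
                     class = "mixed_fit"))
  }
  abort(paste("No random-effects specification could be fitted. Log:",
              paste(log$status, collapse = ", ")))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit>", x$family, "| formula:", x$formula, "\n")
  cat("  backoff steps:", nrow(x$backoff_log),
      "| final status:", tail(x$backoff_log$status, 1), "\n")
  invisible(x)
}

#' @rdname fit_mixed
#' @param x A `mixed_fit` object.
#' @param ... Unused.
#' @export
tidy.mixed_fit <- function(x, ...) {
  co <- as.data.frame(coef(summary(x$model)))
  out <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"])
  if ("df" %in% names(co)) {
    out$df <- co[["df"]]
    out$statistic <- co[["t value"]]
    out$p.value <- co[["Pr(>|t|)"]]
  } else {
    out$statistic <- co[["z value"]]
    out$p.value <- co[["Pr(>|z|)"]]
  }
  out
}

#' @rdname fit_mixed
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, formula = x$formula,
    n_obs = stats::nobs(x$model),
    backoff_steps = nrow(x$backoff_log),
    converged = tail(x$backoff_log$status, 1) == "ok",
    logLik = as.numeric(stats::logLik(x$model)))
}

#' Planned contrasts from a fitted trial-level model
#'
#' Under the package's coding scheme the planned contrasts of interest
#' (e.g. OCD vs. HC main and interaction effects) are the model's own
#' fixed-effect coefficients, so each requested term is reported with its
#' estimate, confidence interval, test statistic and p value
#' (Satterthwaite t for Gaussian models, Wald z for binomial ones), with
#' Benjamini-Hochberg adjustment applied within the requested family of
#' contrasts.
#'
#' @param fit A [fit_mixed()] result.
#' @param terms Character vector of fixed-effect terms to report; by
#'   default all terms involving a group contrast column (`group_*`).
#' @param conf_level Confidence level (default 0.95).
#' @param adjust Apply BH adjustment across the reported terms (default
#'   TRUE).
#' @return A `ContrastResult` tibble: `term`, `estimate`, `conf.low`,
#'   `conf.high`, `statistic`, `df` (Gaussian only), `p.value`, `p.adj`.
#' @export
planned_contrasts <- function(fit, terms = NULL, conf_level = 0.95,
                              adjust = TRUE) {
  stopifnot(inherits(fit, "mixed_fit"))
  td <- tidy(fit)
  if (is.null(terms)) {
    terms <- grep("group_", td$term, value = TRUE)
  }
  missing_t <- setdiff(terms, td$term)
  if (length(missing_t)) {
    abort(paste("Contrast term(s) not in the model:",
                paste(missing_t, collapse = ", ")))
  }
  out <- td[match(terms, td$term), ]
  crit <- if ("df" %in% names(out)) {
    stats::qt(1 - (1 - conf_level) / 2, out$df)
  } else {
    qnorm(1 - (1 - conf_level) / 2)
  }
  out$conf.low <- out$estimate - crit * out$std.error
  out$conf.high <- out$estimate + crit * out$std.error
  out$p.adj <- if (adjust) fdr_adjust(out$p.value) else out$p.value
  dplyr::relocate(out, "conf.low", "conf.high", .after = "std.error")
}

#' Simple effects within the levels of a moderator
#'
#' When an interaction is flagged, the follow-up of interest is the
#' effect of one predictor within each level of the other. Under
#' deviation coding these are linear combinations of the fitted
#' coefficients: the effect of `term` at moderator value `v` is
#' `b[term] + v * b[term:by]`. Estimates use the model's covariance
#' matrix; Gaussian fits get Satterthwaite degrees of freedom via
#' [lmerTest::contest()], binomial fits Wald z statistics. P values are
#' BH-adjusted within the returned family.
#'
#' @param fit A [fit_mixed()] result.
#' @param term Fixed-effect whose simple effects are wanted.
#' @param by Moderator fixed-effect (deviation coded).
#' @param at Moderator values to evaluate at (default the two deviation
#'   codes -0.5 and 0.5).
#' @param labels Labels for the moderator levels.
#' @param conf_level Confidence level.
#' @return A tibble with one row per moderator level: `level`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `statistic`,
#'   `df` (Gaussian only), `p.value`, `p.adj`.
#' @export
simple_effects <- function(fit, term, by, at = c(-0.5, 0.5),
                           labels = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "mixed_fit"))
  b <- lme4::fixef(fit$model)
  inter <- intersect(c(paste(term, by, sep = ":"),
                       paste(by, term, sep = ":")), names(b))
  if (!term %in% names(b) || !length(inter)) {
    abort(sprintf("Model must contain '%s' and its interaction with '%s'.",
                  term, by))
  }
  if (is.null(labels)) labels <- paste0(by, " = ", at)
  rows <- purrr::map2_dfr(at, labels, function(v, lab) {
    L <- stats::setNames(numeric(length(b)), names(b))
    L[term] <- 1
    L[inter[1]] <- v
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% as.matrix(vcov(fit$model)) %*% L))
    if (fit$family == "gaussian") {
      ct <- as.data.frame(lmerTest::contest(fit$model, L, joint = FALSE))
      tibble::tibble(level = lab, estimate = est, std.error = se,
                     df = ct[["df"]], statistic = ct[["t value"]],
                     p.value = ct[["Pr(>|t|)"]])
    } else {
      z <- est / se
      tibble::tibble(level = lab, estimate = est, std.error = se,
                     statistic = z, p.value = 2 * pnorm(-abs(z)))
    }
  })
  crit <- if ("df" %in% names(rows)) {
    stats::qt(1 - (1 - conf_level) / 2, rows$df)
  } else {
    qnorm(1 - (1 - conf_level) / 2)
  }
  rows$conf.low <- rows$estimate - crit * rows$std.error
  rows$conf.high <- rows$estimate + crit * rows$std.error
  rows$p.adj <- fdr_adjust(rows$p.value)
  dplyr::relocate(rows, "conf.low", "conf.high", .after = "std.error")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values: monotone, capped at 1, equal to the input
#' for a single p value.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
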