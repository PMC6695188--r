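#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Wald 95% confidence interval and
#' two-sided Wald p-value: `OR = (a d)/(b c)`, `CI = exp(ln OR +/- 1.96 SE)`
#' with `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Cell layout follows the
#' case-control convention: `a` exposed good responders, `b` unexposed good,
#' `c` exposed poor, `d` unexposed poor.
#'
#' @param a,b,c,d Nonnegative integer cell counts; all must be positive (a
#'   zero cell makes the cross-product OR undefined — apply a continuity
#'   correction upstream if you need an estimate, it is not applied silently
#'   here).
#' @return One-row tibble: `or`, `ci_low`, `ci_high`, `p_wald`, `log_or`,
#'   `se_log_or`.
#' @export
#' @examples
#' or_from_2x2(17, 31, 24, 18) # prior clinical AIDS vs response group
or_from_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0) && all(cells == round(cells)),
              "cell counts must be nonnegative integers")
  if (any(cells == 0)) {
    abort(paste("zero cell in 2x2 table: the cross-product odds ratio is",
                "undefined; consider a continuity correction or an exact method"))
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log_or / se
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - qnorm(0.975) * se),
    ci_high = exp(log_or + qnorm(0.975) * se),
    p_wald = 2 * pnorm(-abs(z)),
    log_or = log_or,
    se_log_or = se
  )
}

#' Univariate logistic odds ratio
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor, with
#' the odds ratio expressed per `scale` units of the predictor (e.g. per year,
#' or per 100 cells with `scale = 100`), Wald 95% CI and two-sided p. Rows
#' with a missing outcome or predictor are dropped (complete-case).
#'
#' @param data A data frame.
#' @param outcome Name of the binary outcome column (logical, 0/1, or
#'   two-level factor; the second level / `TRUE` / `1` is the event).
#' @param predictor Name of the predictor column.
#' @param scale Units per reported odds ratio (default 1).
#' @return One-row tibble: `term`, `or`, `ci_low`, `ci_high`, `p_wald`,
#'   `scale`, `n`, `flagged` (TRUE when the fit shows separation and no
#'   estimate is trustworthy).
#' @export
univariate_logistic <- function(data, outcome, predictor, scale = 1) {
  y <- binary_outcome(data[[outcome]])
  x <- data[[predictor]]
  if (is.character(x)) x <- as.factor(x)
  if (is.factor(x)) {
    assert_that(nlevels(x) == 2, "factor predictors must have two levels")
    x <- as.numeric(x) - 1
  }
  if (is.logical(x)) x <- as.numeric(x)
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  assert_that(length(unique(y)) == 2, "outcome must have two observed classes")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  beta <- unname(coef(fit)["x"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["x"])
  flagged <- !fit$converged || abs(beta) > 15 || se > 100
  if (flagged) {
    return(tibble::tibble(term = predictor, or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_wald = NA_real_,
                          scale = scale, n = length(y), flagged = TRUE))
  }
  z <- beta / se
  tibble::tibble(
    term = predictor,
    or = exp(beta * scale),
    ci_low = exp((beta - qnorm(0.975) * se) * scale),
    ci_high = exp((beta + qnorm(0.975) * se) * scale),
    p_wald = 2 * pnorm(-abs(z)),
    scale = scale,
    n = length(y),
    flagged = FALSE
  )
}

binary_outcome <- function(y) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y)) return(as.numeric(y) - 1)
  if (is.character(y)) return(as.numeric(as.factor(y)) - 1)
  as.numeric(y)
}

#' Forward stepwise logistic selection
#'
#' Iteratively adds the candidate with the smallest multivariate Wald p-value
#' for its entering coefficient (joint Wald chi-square when a candidate
#' expands to several columns), as long as that p-value is below `entry_p`;
#' stops when no remaining candidate qualifies. Ties break deterministically
#' by candidate name order. Rows with missing values in the outcome or any
#' candidate are dropped up front so every step sees the same data.
#'
#' @param data A data frame.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate predictor columns.
#'   Predictors that enter the outcome definition (such as nadir CD4 for a
#'   gain-above-nadir phenotype) must be excluded by the caller.
#' @param entry_p Entry threshold on the multivariate Wald p (default 0.05).
#' @return An object of class `stepwise_result`: list with `selected`
#'   (ordered character vector), `steps` (tibble of per-step entry p-values),
#'   `model` (the final `glm`, or `NULL` if nothing entered) and `data_n`.
#' @export
forward_stepwise <- function(data, outcome, candidates, entry_p = 0.05) {
  candidates <- sort(unique(candidates))
  df <- data[, c(outcome, candidates), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  y <- binary_outcome(df[[outcome]])
  df$.y <- y

  selected <- character(0)
  steps <- tibble::tibble(step = integer(0), candidate = character(0),
                          p_entry = numeric(0))
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(cand) {
      entering_wald_p(df, c(selected, cand), cand)
    }, numeric(1))
    best <- which.min(ps) # first index wins ties; `remaining` is name-sorted
    if (!is.finite(ps[best]) || ps[best] >= entry_p) break
    selected <- c(selected, remaining[best])
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = length(selected), candidate = remaining[best], p_entry = ps[best]
    ))
  }

  model <- if (length(selected) > 0) {
    glm(stats::reformulate(selected, ".y"), family = binomial(), data = df)
  }
  structure(list(selected = selected, steps = steps, model = model,
                 data_n = nrow(df)),
            class = "stepwise_result")
}

# Joint Wald p for the columns contributed by `cand` in the model with
# predictors `terms`.
entering_wald_p <- function(df, terms, cand) {
  fit <- suppressWarnings(glm(stats::reformulate(terms, ".y"),
                              family = binomial(), data = df))
  if (!fit$converged) return(NA_real_)
  mm_assign <- attr(stats::model.matrix(fit), "assign")
  which_term <- match(cand, attr(stats::terms(fit), "term.labels"))
  idx <- which(mm_assign == which_term)
  beta <- coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  if (anyNA(beta)) return(NA_real_)
  if (length(idx) == 1) {
    se <- sqrt(V[1, 1])
    if (se > 100) return(NA_real_)
    2 * pnorm(-abs(beta / se))
  } else {
    stat <- drop(t(beta) %*% solve(V, beta))
    pchisq(stat, df = length(idx), lower.tail = FALSE)
  }
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> selected:",
      if (length(x$selected)) paste(x$selected, collapse = " -> ") else "(none)",
      "\n")
  invisible(x)
}

#' Tidy the final stepwise model
#'
#' @param x A `stepwise_result`.
#' @param ... Unused.
#' @return Tibble of final-model terms with odds ratios, Wald CIs and p-values
#'   (empty when no candidate entered).
#' @method tidy stepwise_result
#' @export
tidy.stepwise_result <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          or = numeric(0), ci_low = numeric(0),
                          ci_high = numeric(0), p_wald = numeric(0)))
  }
  beta <- coef(x$model)
  se <- sqrt(diag(stats::vcov(x$model)))
  tibble::tibble(
    term = names(beta), estimate = unname(beta),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta - qnorm(0.975) * se)),
    ci_high = exp(unname(beta + qnorm(0.975) * se)),
    p_wald = 2 * pnorm(-abs(unname(beta / se)))
  )
}

#' @rdname tidy.stepwise_result
#' @method glance stepwise_result
#' @export
glance.stepwise_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), n = x$data_n,
                 deviance = if (is.null(x$model)) NA_real_ else x$model$deviance)
}

#' Build a characteristics-table report of univariate associations
#'
#' Computes, for each requested binary predictor, the exposed counts per
#' response group and the cross-product odds ratio with Wald CI and p, and for
#' each continuous predictor the per-unit logistic odds ratio. This mirrors
#' the usual "Table 1" of a case-control phenotype paper.
#'
#' @param data Data frame holding the outcome and predictors.
#' @param outcome Binary outcome column name (`TRUE`/1 = good response).
#' @param binary Character vector of binary predictor columns.
#' @param continuous Named numeric vector: names are continuous predictor
#'   columns, values the per-unit scale for the reported OR.
#' @return Tibble with one row per predictor.
#' @export
univariate_table <- function(data, outcome, binary = character(0),
                             continuous = numeric(0)) {
  y <- binary_outcome(data[[outcome]])
  rows <- list()
  for (b in binary) {
    x <- as.logical(data[[b]])
    keep <- !is.na(x) & !is.na(y)
    tab <- or_from_2x2(sum(x[keep] & y[keep] == 1), sum(!x[keep] & y[keep] == 1),
                       sum(x[keep] & y[keep] == 0), sum(!x[keep] & y[keep] == 0))
    rows[[b]] <- dplyr::bind_cols(tibble::tibble(term = b, type = "binary"),
                                  dplyr::select(tab, "or", "ci_low", "ci_high", "p_wald"))
  }
  for (cn in names(continuous)) {
    u <- univariate_logistic(data, outcome, cn, scale = continuous[[cn]])
    rows[[cn]] <- tibble::tibble(term = cn, type = "continuous",
                                 or = u$or, ci_low = u$ci_low,
                                 ci_high = u$ci_high, p_wald = u$p_wald)
  }
  dplyr::bind_rows(rows)
}
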