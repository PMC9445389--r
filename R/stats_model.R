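#' Sum-to-zero linear model of ADG with backward stepwise selection
#'
#' Fits `ADG ~ Round + StartWeight + Skew + RMSE + AC + ENT` (MD is
#' excluded by default because of its collinearity with RMSE) on
#' listwise-complete rows, with sum-to-zero contrasts for the round
#' factor so each round effect is a deviation from the overall mean and
#' the full set of round effects sums to zero.
#'
#' Selection proceeds in two stages. Stage 1: backward elimination
#' without interactions -- repeatedly drop the term with the largest
#' F-test p-value above `alpha` (a factor is dropped as a block). Stage
#' 2: all two-way interactions among the surviving terms are added and
#' backward elimination runs again, respecting marginality (a main
#' effect is never dropped while one of its interactions remains).
#'
#' @param data merged per-bird table containing the response and
#'   candidate columns.
#' @param response response column name (default `"adg"`).
#' @param candidates candidate fixed-effect columns; `"round_id"` is
#'   treated as a factor.
#' @param include_rounds rounds to keep (default `NULL` = all); use e.g.
#'   `2:5` when one round lacks a descriptor wholesale.
#' @param alpha retention threshold for the F-test criterion (default
#'   0.05).
#' @param criterion `"F"` (default: F-test p-value) or `"AIC"`.
#' @param stage2 run the interaction stage (default TRUE).
#' @return object of class `adg_model`: list with `fit` (the final
#'   [stats::lm()]), `coefficients` (coefficient table), `anova`
#'   (sequential Type-I F table), `round_effects` (all levels, incl. the
#'   implied last one; sums to zero), `adj_r_squared`, `n`, `terms`
#'   (retained), `trace` (selection history data.frame).
#' @export
fit_adg_model <- function(data, response = "adg",
                          candidates = c("round_id", "start_weight", "skew",
                                         "rmse", "ac", "ent"),
                          include_rounds = NULL, alpha = 0.05,
                          criterion = c("F", "AIC"), stage2 = TRUE) {
  criterion <- match.arg(criterion)
  df <- as.data.frame(data)
  if (!is.null(include_rounds) && "round_id" %in% names(df))
    df <- df[df$round_id %in% include_rounds, , drop = FALSE]
  cols <- c(response, intersect(candidates, names(df)))
  missing_cols <- setdiff(c(response, candidates), names(df))
  if (length(missing_cols) > 0)
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  df <- df[complete.cases(df[, cols]), cols, drop = FALSE]
  has_round <- "round_id" %in% candidates
  if (has_round) df$round_id <- droplevels(factor(df$round_id))

  n_par <- 1 + length(setdiff(candidates, "round_id")) +
    if (has_round) nlevels(df$round_id) - 1 else 0
  if (nrow(df) < n_par + 10)
    stop("too few complete rows (", nrow(df), ") for ", n_par, " parameters")

  fit_formula <- function(fm) {
    contr <- if (has_round && "round_id" %in% all.vars(fm))
      list(round_id = "contr.sum") else NULL
    f <- lm(fm, data = df, contrasts = contr)
    if (any(is.na(coef(f)))) {
      stop("rank-deficient model; aliased term(s): ",
           paste(names(coef(f))[is.na(coef(f))], collapse = ", "))
    }
    f
  }

  trace <- list()
  note <- function(stage, action, term, value) {
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, action = action, term = term, value = value)
  }

  backward <- function(fm, stage) {
    fit <- fit_formula(fm)
    repeat {
      d1 <- drop1(fit, test = if (criterion == "F") "F" else "none")
      cand <- rownames(d1)[-1]  # droppable terms (marginality respected)
      if (length(cand) == 0) break
      if (criterion == "F") {
        pv <- d1[["Pr(>F)"]][-1]
        worst <- which.max(pv)
        if (pv[worst] <= alpha || is.na(pv[worst])) break
        note(stage, "drop", cand[worst], pv[worst])
      } else {
        aics <- d1[["AIC"]][-1]
        full_aic <- d1[["AIC"]][1]
        worst <- which.min(aics)
        if (aics[worst] >= full_aic) break
        note(stage, "drop", cand[worst], aics[worst])
      }
      fm <- update(as.formula(fm), paste(". ~ . -", cand[worst]))
      fit <- fit_formula(fm)
    }
    fit
  }

  terms0 <- intersect(candidates, names(df))
  fm1 <- as.formula(paste(response, "~", paste(terms0, collapse = " + ")))
  fit1 <- backward(fm1, "main")
  survivors <- attr(terms(fit1), "term.labels")

  fit_final <- fit1
  if (stage2 && length(survivors) >= 2) {
    fm2 <- as.formula(paste(
      response, "~ (", paste(survivors, collapse = " + "), ")^2"))
    note("interaction", "add", paste(survivors, collapse = ":"), NA_real_)
    fit_final <- backward(fm2, "interaction")
  }

  sm <- summary(fit_final)
  round_effects <- NULL
  if (has_round && "round_id" %in% attr(terms(fit_final), "term.labels")) {
    lev <- levels(df$round_id)
    co <- coef(fit_final)
    idx <- grep("^round_id[0-9]+$", names(co))
    eff <- co[idx]
    round_effects <- setNames(c(eff, -sum(eff)), lev)
  }

  structure(list(
    fit = fit_final,
    coefficients = sm$coefficients,
    anova = anova(fit_final),
    round_effects = round_effects,
    adj_r_squared = sm$adj.r.squared,
    r_squared = sm$r.squared,
    n = nrow(df),
    terms = attr(terms(fit_final), "term.labels"),
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(stage = character(), action = character(),
                 term = character(), value = numeric())
  ), class = "adg_model")
}

#' @export
print.adg_model <- function(x, ...) {
  cat("Linear model of ADG (sum-to-zero round contrasts)\n")
  cat("Retained terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("n = %d, adjusted R^2 = %.3f\n\n", x$n, x$adj_r_squared))
  printCoefmat(x$coefficients, ...)
  if (!is.null(x$round_effects)) {
    cat("\nRound effects (sum to zero):\n")
    print(round(x$round_effects, 3))
  }
  invisible(x)
}
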