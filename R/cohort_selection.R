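## Cohort selection: low-HDL-C participants are chosen below a hyperbolic
## quantile isopleth fitted in the (TG, HDL-C) plane, then partitioned into
## four dyslipidemia subphenotype groups by TG >= 150 and LDL-C >= 160
## mg/dl cutoffs.

#' Friedewald LDL-C estimate
#'
#' `LDL-C = TC - HDL-C - TG/5` (all mg/dl), valid only when TG < 400 mg/dl;
#' above that bound the estimate is undefined and `NA` is returned (in
#' practice such samples need ultracentrifugation).
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C and triglycerides in mg/dl
#'   (vectors recycle).
#' @return Numeric vector of LDL-C estimates, `NA` where `tg >= 400`.
#' @examples
#' friedewaldLdl(200, 40, 100)  # 140
#' @export
friedewaldLdl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
    stop("lipid inputs must be non-negative")
  ifelse(tg < 400, tc - hdl - tg / 5, NA_real_)
}

#' Evaluate an isopleth threshold at given TG values
#'
#' @param model An [IsoplethModel][isoplethModel].
#' @param tg Triglyceride values (mg/dl).
#' @return HDL-C threshold values `m1 + m2*m3/(m2 + tg)` (mg/dl).
#' @export
isoplethThreshold <- function(model, tg) {
  model@m1 + model@m2 * model@m3 / (model@m2 + tg)
}

## pinball (quantile) loss at level q
pinballLoss <- function(resid, q) {
  sum(ifelse(resid >= 0, q * resid, (q - 1) * resid))
}

#' Fit a hyperbolic quantile isopleth
#'
#' Fits `y = m1 + m2*m3/(m2 + x)` to (TG, HDL-C) points by minimising the
#' pinball (quantile) loss at level `q` — the standard definition of a
#' quantile curve, so roughly a fraction `q` of points fall below the fit.
#' The loss is non-smooth, so Nelder-Mead searches over
#' `(m1, log m2, c = m2*m3)` from a multistart grid of `m2` values spanning
#' the TG range, followed by a tight polish from the best start.
#'
#' @param tg,hdl Paired triglyceride and HDL-C observations (mg/dl), at
#'   least 30 complete pairs.
#' @param q Quantile level in (0,1), default the 10th percentile.
#' @return An [IsoplethModel][isoplethModel].
#' @examples
#' tg <- exp(rnorm(200, log(150), 0.6))
#' m <- fitIsopleth(tg, 20 + 50 * 30 / (50 + tg), q = 0.10)
#' @export
fitIsopleth <- function(tg, hdl, q = 0.10) {
  ok <- stats::complete.cases(tg, hdl)
  tg <- tg[ok]; hdl <- hdl[ok]
  if (length(tg) < 30)
    stop("need at least 30 complete (TG, HDL-C) pairs")
  if (q <= 0 || q >= 1) stop("q must lie in (0,1)")
  if (diff(range(tg)) < sqrt(.Machine$double.eps))
    stop("all TG values identical: m2 is unidentifiable")

  obj <- function(par) {
    m1 <- par[1]; m2 <- exp(par[2]); cc <- par[3]
    pinballLoss(hdl - (m1 + cc / (m2 + tg)), q)
  }
  yq <- as.numeric(quantile(hdl, q))
  starts <- lapply(quantile(tg, c(0.1, 0.25, 0.5, 0.75, 0.9)), function(m2) {
    ## crude start: flat curve at the hdl q-quantile, moderate drop
    c(yq * 0.5, log(m2), yq * 0.5 * m2)
  })
  fits <- lapply(starts, function(s)
    optim(s, obj, method = "Nelder-Mead",
          control = list(maxit = 4000, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ## polish twice from the winner; restarting NM escapes collapsed simplices
  for (i in 1:2)
    best <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 8000, reltol = 1e-14))
  m2 <- exp(best$par[2])
  isoplethModel(m1 = best$par[1], m2 = m2, m3 = best$par[3] / m2, q = q)
}

#' Select participants strictly below the isopleth
#'
#' Keeps participants whose HDL-C lies strictly below the fitted threshold
#' at their TG; records exactly on the curve stay in the population.
#' Participants missing TG or HDL-C are excluded with a warning, not an
#' error.
#'
#' @param participants data.frame with `tg` and `hdl` columns (mg/dl).
#' @param model An [IsoplethModel][isoplethModel].
#' @return The subset of `participants` below the curve.
#' @export
selectBelowIsopleth <- function(participants, model) {
  if (!nrow(participants)) return(participants)
  ok <- stats::complete.cases(participants$tg, participants$hdl)
  if (any(!ok))
    warning(sum(!ok), " participant(s) missing TG or HDL-C excluded ",
            "from selection")
  thr <- isoplethThreshold(model, participants$tg)
  participants[ok & participants$hdl < thr, , drop = FALSE]
}

#' Assign dyslipidemia subphenotype groups
#'
#' Partitions low-HDL participants by hypertriglyceridemia (TG >= 150
#' mg/dl, the NCEP ATP III cutoff) and high LDL-C (>= 160 mg/dl):
#' group 1 isolated low HDL-C, group 2 low HDL-C plus high LDL-C, group 3
#' low HDL-C plus high TG, group 4 low HDL-C plus combined hyperlipidemia.
#' For participants under 18 a caller-supplied function mapping
#' `(sex, age)` to the LDL-C percentile cutoff replaces the adult 160;
#' without one the adult cutoff is applied with a notice. Participants with
#' no usable LDL-C (missing, and Friedewald invalid at TG >= 400) stay
#' unassigned (`NA`).
#'
#' @param participants data.frame with `tg`, `ldl` and optionally `tc`,
#'   `hdl` (used to fill missing LDL-C by Friedewald when TG < 400), `age`,
#'   `sex`.
#' @param pediatricCutoff Optional `function(sex, age)` returning the LDL-C
#'   cutoff (mg/dl) for participants under 18.
#' @param tgCutoff,ldlCutoff Adult cutoffs in mg/dl.
#' @return Integer vector of groups (1-4, `NA` if unassignable).
#' @export
assignSubphenotype <- function(participants, pediatricCutoff = NULL,
                               tgCutoff = 150, ldlCutoff = 160) {
  n <- nrow(participants)
  ldl <- participants$ldl
  if (!is.null(participants$tc) && !is.null(participants$hdl)) {
    fill <- is.na(ldl) & !is.na(participants$tg) & participants$tg < 400
    ldl[fill] <- friedewaldLdl(participants$tc[fill],
                               participants$hdl[fill],
                               participants$tg[fill])
  }
  cut <- rep(ldlCutoff, n)
  if (!is.null(participants$age)) {
    ped <- !is.na(participants$age) & participants$age < 18
    if (any(ped)) {
      if (is.null(pediatricCutoff)) {
        message(sum(ped), " participant(s) under 18: no pediatric LDL-C ",
                "percentile table supplied, applying the adult cutoff")
      } else {
        cut[ped] <- mapply(pediatricCutoff, participants$sex[ped],
                           participants$age[ped])
      }
    }
  }
  highTg <- participants$tg >= tgCutoff
  highLdl <- ldl >= cut
  grp <- ifelse(highTg, ifelse(highLdl, 4L, 3L), ifelse(highLdl, 2L, 1L))
  as.integer(ifelse(is.na(participants$tg) | is.na(ldl), NA, grp))
}

#' Two-sample comparison with the study's transform rules
#'
#' Continuous variables are compared by a two-sided Welch unpaired t-test
#' after an optional normalising transform (`"log"` for BMI, TC and TG;
#' `"sqrt"` for LDL-C; `"none"` otherwise). Identical or jointly constant
#' samples return p = 1.
#'
#' @param a,b Numeric samples (each of size >= 2 after NA removal).
#' @param transform One of `"none"`, `"log"`, `"sqrt"`.
#' @return Two-sided p-value.
#' @export
compareDistributions <- function(a, b, transform = c("none", "log", "sqrt")) {
  transform <- match.arg(transform)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per sample")
  if (transform == "log") {
    bad <- c(a, b) <= 0
    if (any(bad))
      stop("log transform on non-positive value(s): ",
           paste(head(c(a, b)[bad], 3), collapse = ", "))
    a <- log(a); b <- log(b)
  } else if (transform == "sqrt") {
    if (any(c(a, b) < 0)) stop("sqrt transform on negative value(s)")
    a <- sqrt(a); b <- sqrt(b)
  }
  if (sd(a) == 0 && sd(b) == 0)   # t.test rejects constant data
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Fisher exact comparison of two proportions
#'
#' Two-sided Fisher exact test on the 2x2 table of yes/no counts in two
#' groups; used for categorical cohort variables (sex, clinical flags).
#'
#' @param aYes,aNo,bYes,bNo Counts of the 2x2 table.
#' @return Two-sided p-value.
#' @export
compareProportions <- function(aYes, aNo, bYes, bNo) {
  stats::fisher.test(matrix(c(aYes, aNo, bYes, bNo), 2))$p.value
}

#' Summarise subphenotype groups
#'
#' One row per group: n, percent of cohort (1 decimal), female percent, and
#' mean +/- sd of age, HDL-C, TC, LDL-C, TG and prebeta HDL, with p-values
#' versus group 1 (Welch t-test under the transform table: TC/TG log,
#' LDL-C sqrt; Fisher exact for the female fraction). Means use per-variable
#' complete cases. Empty groups give an `n = 0` row and no tests.
#'
#' @param participants data.frame with a `group` column (see
#'   [assignSubphenotype()]) plus `sex`, `age`, `hdl`, `tc`, `ldl`, `tg`,
#'   and optionally `prebeta`.
#' @return data.frame with one row per group 1-4.
#' @export
summarizeGroups <- function(participants) {
  p <- participants[!is.na(participants$group), , drop = FALSE]
  total <- nrow(p)
  vars <- c(age = "none", hdl = "none", tc = "log", ldl = "sqrt",
            tg = "log", prebeta = "none")
  vars <- vars[names(vars) %in% names(p)]
  ref <- p[p$group == 1, , drop = FALSE]
  rows <- lapply(1:4, function(g) {
    gp <- p[p$group == g, , drop = FALSE]
    row <- data.frame(group = g, n = nrow(gp),
                      percent = round(100 * nrow(gp) / total, 1),
                      female_percent =
                        round(100 * mean(gp$sex == "F"), 1))
    for (v in names(vars)) {
      x <- gp[[v]]
      row[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- sd(x, na.rm = TRUE)
      row[[paste0(v, "_p")]] <-
        if (g == 1 || nrow(gp) < 2 || nrow(ref) < 2) NA_real_
        else compareDistributions(gp[[v]], ref[[v]], vars[[v]])
    }
    row$female_p <-
      if (g == 1 || !nrow(gp) || !nrow(ref)) NA_real_
      else compareProportions(sum(gp$sex == "F"), sum(gp$sex != "F"),
                              sum(ref$sex == "F"), sum(ref$sex != "F"))
    row
  })
  do.call(rbind, rows)
}
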