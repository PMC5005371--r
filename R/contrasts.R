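# Generic linear contrasts on the fixed-effect coefficients: z statistics
# from the fitted coefficient covariance, Benjamini-Hochberg adjustment
# within the family. A single coherent procedure is used for every pairwise
# family in the package.
contrast_table <- function(fit, L, labels_a, labels_b,
                           family = NA_character_) {
  b <- nlme::fixef(fit$lme)
  V <- vcov(fit$lme)
  est <- as.numeric(L %*% b)
  se <- sqrt(diag(L %*% V %*% t(L)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(family = family, level_a = labels_a, level_b = labels_b,
                    estimate = est, se = se, z = z, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  class(out) <- c("contrast_result", class(out))
  out
}

coef_index <- function(fit, name) {
  b <- nlme::fixef(fit$lme)
  match(name, names(b))
}

# unit row vector selecting gamma_level - gamma_other for a dummy-coded
# factor with reference level carrying no coefficient
dummy_diff_row <- function(fit, prefix, level_a, level_b, ref,
                           suffix = "") {
  b <- nlme::fixef(fit$lme)
  row <- numeric(length(b))
  nm <- function(l) paste0(prefix, l, suffix)
  if (level_a != ref) {
    i <- coef_index(fit, nm(level_a))
    if (is.na(i)) stop("coefficient not found: ", nm(level_a))
    row[i] <- row[i] + 1
  }
  if (level_b != ref) {
    i <- coef_index(fit, nm(level_b))
    if (is.na(i)) stop("coefficient not found: ", nm(level_b))
    row[i] <- row[i] - 1
  }
  row
}

#' Pairwise provenance contrasts under a soil-water-deficit scenario
#'
#' Compares all provenance pairs at a chosen deficit level. The PSWD
#' predictor is re-centered at `at_pswd` and the model refit, so the
#' provenance main-effect dummies become the provenance differences at
#' exactly that deficit; all pairwise differences are then tested with z
#' statistics from the coefficient covariance and Benjamini-Hochberg FDR
#' adjustment across the pairs. Typical scenarios are 0 (field capacity),
#' 0.5, and 1 (complete depletion of plant-available water).
#'
#' @param fit a `ct_model_fit` of a soil-water-deficit model.
#' @param at_pswd deficit fraction at which to compare; default 0.
#' @return a `contrast_result` data.frame (one row per provenance pair).
#' @export
provenance_contrasts <- function(fit, at_pswd = 0) {
  stopifnot(inherits(fit, "ct_model_fit"), fit$spec$model_type == "pswd")
  if (!isTRUE(all.equal(at_pswd, fit$spec$pswd_center))) {
    spec <- fit$spec
    spec$pswd_center <- at_pswd
    fit <- fit_lmm(spec, fit$obs, fit$method)
  }
  lv <- levels(fit$frame$provenance)
  ref <- lv[1]
  pairs <- utils::combn(lv, 2)
  L <- t(apply(pairs, 2, function(pr)
    dummy_diff_row(fit, "provenance", pr[1], pr[2], ref)))
  contrast_table(fit, L, pairs[1, ], pairs[2, ],
                 family = sprintf("provenance_at_pswd_%g", at_pswd))
}

#' Pairwise tests of deficit-response curvature across provenances
#'
#' Tests whether provenances differ in the *shape* of their response to
#' soil water deficit: for every provenance pair the differences of the
#' linear and quadratic PSWD-interaction coefficients are tested jointly
#' with a 2-df Wald chi-square, Benjamini-Hochberg adjusted across pairs.
#'
#' @param fit a `ct_model_fit` whose spec retains both
#'   `provenance:pswd` and `provenance:pswd2`.
#' @return data.frame with one row per pair: `statistic` (Wald chi-square,
#'   2 df), `p`, `p_adj`.
#' @export
test_interaction_curvature <- function(fit) {
  stopifnot(inherits(fit, "ct_model_fit"))
  if (!all(c("provenance:pswd", "provenance:pswd2") %in% fit$spec$terms))
    stop("no interaction to test: the model does not retain both PSWD-provenance interaction terms")
  lv <- levels(fit$frame$provenance)
  ref <- lv[1]
  b <- nlme::fixef(fit$lme)
  V <- vcov(fit$lme)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    L <- rbind(dummy_diff_row(fit, "provenance", pr[1], pr[2], ref,
                              suffix = ":pswd_s"),
               dummy_diff_row(fit, "provenance", pr[1], pr[2], ref,
                              suffix = ":I(pswd_s^2)"))
    d <- as.numeric(L %*% b)
    Vd <- L %*% V %*% t(L)
    W <- as.numeric(t(d) %*% solve(Vd, d))
    c(W, stats::pchisq(W, df = 2, lower.tail = FALSE))
  })
  out <- data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
                    statistic = res[1, ], df = 2, p = res[2, ],
                    p_adj = stats::p.adjust(res[2, ], method = "BH"),
                    row.names = NULL)
  class(out) <- c("contrast_result", class(out))
  out
}

#' Post-hoc contrasts for the treatment model
#'
#' Three contrast families, each Benjamini-Hochberg adjusted within itself:
#' the control-vs-drought difference within every provenance (via the
#' treatment dummy plus its provenance interaction, when retained), and the
#' pairwise provenance differences within the drought group and within the
#' control group. If the provenance-treatment interaction was simplified
#' away, the treatment effect is common to all provenances and a single
#' treatment row is returned; likewise one provenance family.
#'
#' @param fit a `ct_model_fit` of a treatment model.
#' @return a `contrast_result` data.frame with a `family` column.
#' @export
treatment_contrasts <- function(fit) {
  stopifnot(inherits(fit, "ct_model_fit"), fit$spec$model_type == "treatment")
  has_prov <- "provenance" %in% fit$spec$terms
  lv <- if (has_prov) levels(droplevels(fit$frame$provenance)) else character()
  ref <- levels(fit$frame$provenance)[1]
  b <- nlme::fixef(fit$lme)
  has_int <- "provenance:treatment" %in% fit$spec$terms
  i_treat <- coef_index(fit, "treatmentcontrol")
  if (is.na(i_treat)) stop("model does not retain a treatment coefficient")

  out <- list()
  # control - drought within provenance
  if (has_int && length(lv) > 1L) {
    L <- t(vapply(lv, function(p) {
      row <- numeric(length(b))
      row[i_treat] <- 1
      if (p != ref) {
        i <- coef_index(fit, paste0("provenance", p, ":treatmentcontrol"))
        if (!is.na(i)) row[i] <- 1
      }
      row
    }, numeric(length(b))))
    out$treat <- contrast_table(fit, L, lv, rep("(within provenance)", length(lv)),
                                family = "treatment_within_provenance")
    out$treat$level_b <- out$treat$level_a
    out$treat$level_a <- "control-drought"
  } else {
    L <- matrix(0, 1, length(b)); L[1, i_treat] <- 1
    out$treat <- contrast_table(fit, L, "control-drought", "(all provenances)",
                                family = "treatment")
  }
  if (length(lv) > 1L) {
    pairs <- utils::combn(lv, 2)
    # within drought: provenance main effects only (treatment dummy = 0)
    L0 <- t(apply(pairs, 2, function(pr)
      dummy_diff_row(fit, "provenance", pr[1], pr[2], ref)))
    out$drought <- contrast_table(fit, L0, pairs[1, ], pairs[2, ],
                                  family = "provenance_within_drought")
    # within control: main effects plus treatment interaction
    L1 <- L0
    if (has_int) {
      Li <- t(apply(pairs, 2, function(pr)
        dummy_diff_row(fit, "provenance", pr[1], pr[2], ref,
                       suffix = ":treatmentcontrol")))
      L1 <- L0 + Li
    }
    out$control <- contrast_table(fit, L1, pairs[1, ], pairs[2, ],
                                  family = "provenance_within_control")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_result", class(res))
  res
}

#' Reduction of the treatment effect from stress to recovery
#'
#' How much of the treatment (water-supply) difference observed during the
#' stress window remains during recovery:
#' \deqn{100 (1 - |\beta_{treat}^{recovery}| / |\beta_{treat}^{stress}|)}
#' also reported rounded to the nearest ten percent.
#'
#' @param fit_stress,fit_recovery `ct_model_fit`s of the stress and
#'   recovery windows, or bare numeric treatment coefficients.
#' @return list with `percent` and `percent_rounded_10`.
#' @export
#' @examples
#' treatment_effect_reduction(-0.23, -0.11)   # 52.2%, rounds to 50%
treatment_effect_reduction <- function(fit_stress, fit_recovery) {
  get_b <- function(x) {
    if (inherits(x, "ct_model_fit")) {
      i <- coef_index(x, "treatmentcontrol")
      if (is.na(i)) stop("fit does not retain a treatment coefficient")
      nlme::fixef(x$lme)[[i]]
    } else as.numeric(x)
  }
  bs <- get_b(fit_stress); br <- get_b(fit_recovery)
  if (bs == 0) stop("stress-period treatment coefficient is zero")
  pct <- 100 * (1 - abs(br) / abs(bs))
  list(percent = pct, percent_rounded_10 = 10 * round(pct / 10))
}
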