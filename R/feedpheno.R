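#' Fit the growth regression of body weight on days in test
#'
#' Ordinary least squares of the body-weight series on days in test (DIT):
#' y = alpha + beta * DIT + e.  The slope beta is the average daily gain
#' (ADG, kg/day) and the intercept alpha estimates initial weight (kg).
#'
#' @param dit numeric, day index of each weighing.
#' @param bw numeric, body weight (kg) at each weighing.
#' @return A list with \code{alpha}, \code{beta} and \code{residualSd}.
#' @examples
#' fitGrowth(c(0, 35, 70), 300 + 1.5 * c(0, 35, 70))
#' @export
fitGrowth <- function(dit, bw) {
  stopifnot(length(dit) == length(bw), length(dit) >= 2)
  if (length(unique(dit)) < 2) {
    stop("singular design: all days-in-test values are identical")
  }
  fit <- lm(bw ~ dit)
  rsd <- if (length(dit) > 2) sqrt(sum(residuals(fit)^2) / (length(dit) - 2))
         else 0
  list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
       residualSd = rsd)
}

#' Metabolic weight from a fitted growth line
#'
#' Mid-test live weight raised to the 0.75 power:
#' MW = (alpha + beta * DIT/2)^0.75, in kg^0.75.
#'
#' @param fit growth fit from \code{\link{fitGrowth}} (or any list with
#'   alpha and beta).
#' @param testDays total days in test (DIT).
#' @return Metabolic weight (kg^0.75).
#' @examples
#' metabolicWeight(list(alpha = 300, beta = 1), 70)  # 335^0.75
#' @export
metabolicWeight <- function(fit, testDays) {
  mid <- fit$alpha + fit$beta * testDays / 2
  if (mid <= 0) stop("domain error: non-positive mid-test weight")
  mid^0.75
}

#' Residual feed intake within contemporary groups
#'
#' Derives ADG and metabolic weight per animal from its weight series and
#' computes residual feed intake (RFI, kg DM/day) as the residual of the
#' multiple regression of test-average DMI on ADG, MW and contemporary
#' group (categorical): DMI = b0 + b1 ADG + b2 MW + b3 CG + e.  Before
#' fitting, contemporary groups with fewer than \code{minCgSize} animals
#' are dropped, and animals whose DMI lies beyond \code{outlierSd}
#' standard deviations of their CG mean are excluded (reported with NA
#' RFI).  Residuals average zero within every retained CG and are
#' orthogonal to the fitted regressors.
#'
#' @param animals data.frame with columns animal, cg, dmi (one row per
#'   animal).
#' @param bodyWeight data.frame with columns animal, dit, bw (long format).
#' @param minCgSize minimum animals per retained contemporary group.
#' @param outlierSd DMI outlier threshold in within-CG SD units.
#' @param testDays days in test for the metabolic-weight midpoint;
#'   defaults to the largest observed DIT.
#' @return data.frame (animal, cg, dmi, adg, mw, rfi) with the regression
#'   coefficients in \code{attr(, "coefficients")}; excluded animals keep
#'   their rows with \code{rfi = NA}.
#' @export
computeRFI <- function(animals, bodyWeight, minCgSize = 4,
                       outlierSd = 3.5, testDays = max(bodyWeight$dit)) {
  stopifnot(all(c("animal", "cg", "dmi") %in% names(animals)),
            all(c("animal", "dit", "bw") %in% names(bodyWeight)))
  if (any(animals$dmi <= 0)) stop("DMI must be positive")
  ids <- as.character(animals$animal)
  # per-animal OLS of bw on dit via grouped normal equations (equivalent
  # to fitGrowth(), vectorised over animals)
  ba <- as.character(bodyWeight$animal)
  if (!all(ids %in% ba)) {
    stop("no body-weight series for animal ",
         ids[!(ids %in% ba)][1])
  }
  agg <- rowsum(cbind(n = 1, d = bodyWeight$dit, y = bodyWeight$bw,
                      dd = bodyWeight$dit^2,
                      dy = bodyWeight$dit * bodyWeight$bw), ba)
  agg <- agg[ids, , drop = FALSE]
  sxx <- agg[, "dd"] - agg[, "d"]^2 / agg[, "n"]
  if (any(agg[, "n"] < 2 | sxx == 0)) {
    stop("singular design: an animal has fewer than 2 distinct ",
         "days-in-test values")
  }
  beta <- (agg[, "dy"] - agg[, "d"] * agg[, "y"] / agg[, "n"]) / sxx
  alpha <- (agg[, "y"] - beta * agg[, "d"]) / agg[, "n"]
  mid <- alpha + beta * testDays / 2
  if (any(mid <= 0)) stop("domain error: non-positive mid-test weight")
  out <- data.frame(
    animal = ids, cg = animals$cg, dmi = animals$dmi,
    adg = unname(beta), mw = unname(mid^0.75),
    rfi = NA_real_, stringsAsFactors = FALSE
  )

  cgSize <- table(out$cg)
  keepCg <- names(cgSize)[cgSize >= minCgSize]
  use <- as.character(out$cg) %in% keepCg
  # DMI outliers relative to their contemporary-group mean, flagged once
  cgMean <- tapply(out$dmi[use], out$cg[use], mean)
  cgSd <- tapply(out$dmi[use], out$cg[use], sd)
  dev <- abs(out$dmi - cgMean[as.character(out$cg)])
  lim <- outlierSd * cgSd[as.character(out$cg)]
  use <- use & (is.na(lim) | lim == 0 | dev <= lim)

  dat <- out[use, ]
  if (length(unique(dat$adg)) < 2 && length(unique(dat$mw)) < 2) {
    stop("singular design: no variation in ADG and MW")
  }
  dat$cg <- factor(dat$cg)
  fit <- if (nlevels(dat$cg) > 1) lm(dmi ~ adg + mw + cg, data = dat)
         else lm(dmi ~ adg + mw, data = dat)
  out$rfi[use] <- residuals(fit)
  attr(out, "coefficients") <- coef(fit)
  attr(out, "excluded") <- out$animal[!use]
  out
}

#' Select extreme feed-efficiency groups
#'
#' High feed efficiency (HFE) is the \code{nPerGroup} animals with the
#' lowest RFI (most efficient); low feed efficiency (LFE) the
#' \code{nPerGroup} with the highest.  Ties at a boundary are broken by
#' ascending animal id.
#'
#' @param rfi data.frame from \code{\link{computeRFI}} (animals with NA
#'   RFI are ignored).
#' @param nPerGroup animals per group.
#' @return A list with character vectors \code{hfe} and \code{lfe}.
#' @export
selectExtremeGroups <- function(rfi, nPerGroup = 9) {
  ok <- rfi[!is.na(rfi$rfi), ]
  if (nrow(ok) < 2 * nPerGroup) {
    stop("invalid configuration: need at least ", 2 * nPerGroup,
         " animals with RFI")
  }
  idKey <- suppressWarnings(as.numeric(ok$animal))
  if (anyNA(idKey)) idKey <- ok$animal
  oH <- order(ok$rfi, idKey)
  oL <- order(-ok$rfi, idKey)
  list(hfe = as.character(ok$animal[oH[seq_len(nPerGroup)]]),
       lfe = as.character(ok$animal[oL[seq_len(nPerGroup)]]))
}
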