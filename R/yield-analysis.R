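# Latex yield-potential correlation and regeneration-ability analysis.
#
# Trunk-circumference-adjusted total solid content (TSC/C) is the yield
# potential; snoRNA expression is screened against it by Spearman
# correlation with the printed rule rho > 0 and rho^2 > 0.2.  Regeneration
# ability is the TSC of the first tapping at or past the stable point (3 h)
# of a continuous 30-min tapping series.

#' Adjust TSC by trunk circumference
#'
#' @param records data.frame with columns `tree_id`, `tsc` (grams dry
#'   weight), `circumference` (cm).
#' @return the input with a `tsc_c` column (grams/cm) filled.
#' @export
adjustTsc <- function(records) {
  stopifnot(all(c("tree_id", "tsc", "circumference") %in% colnames(records)))
  if (any(records$circumference <= 0)) stop("non-positive circumference")
  if (any(records$tsc < 0)) stop("negative TSC")
  records$tsc_c <- records$tsc / records$circumference
  records
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged); invariant under
#' strictly monotone transforms of either argument.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return rho in `[-1, 1]`.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Is a snoRNA positively yield-correlated?
#'
#' `TRUE` iff `rho > 0` and `rho^2 > 0.2` (both strict, as printed).
#'
#' @param rho Spearman coefficient.
#' @return logical.
#' @examples
#' classifyYieldCorrelated(0.5)   # TRUE  (0.25 > 0.2)
#' classifyYieldCorrelated(-0.9)  # FALSE (negative)
#' classifyYieldCorrelated(0.4)   # FALSE (0.16 < 0.2)
#' @export
classifyYieldCorrelated <- function(rho) {
  !is.na(rho) & rho > 0 & rho^2 > 0.2
}

#' Correlate snoRNA expression with yield potential
#'
#' @param expression numeric matrix, trees x snoRNAs (rownames = tree ids).
#' @param tscC named numeric vector of TSC/C per tree.
#' @return data.frame sorted by rho descending: `snorna_id`, `rho`,
#'   `rho_sq`, `n`, `yield_correlated`.
#' @export
correlateYield <- function(expression, tscC) {
  trees <- rownames(expression)
  if (is.null(trees) || !all(trees %in% names(tscC)))
    stop("tree ids of expression and TSC/C do not match")
  y <- tscC[trees]
  rho <- vapply(colnames(expression),
                function(s) spearmanRho(expression[, s], y), numeric(1))
  out <- data.frame(snorna_id = colnames(expression), rho = rho,
                    rho_sq = rho^2, n = length(y),
                    yield_correlated = classifyYieldCorrelated(rho),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$rho, out$snorna_id), , drop = FALSE]
}

#' Latex regeneration ability from a continuous-tapping series
#'
#' Continuous tapping at fixed intervals depletes the isolated laticifers:
#' the TSC drops sharply over the first tappings and then plateaus.  The
#' TSC of the first tapping at or past `stableTimeMin` (default 3 h) is
#' taken as the regeneration ability.  If the readings from that point on
#' vary more than `cvTol` (coefficient of variation), a warning flags a
#' non-stable plateau.
#'
#' @param time_min strictly increasing tapping times in minutes.
#' @param tsc non-negative TSC readings, same length.
#' @param stableTimeMin stable-state time point (default 180 min).
#' @param cvTol plateau coefficient-of-variation tolerance (default 0.25).
#' @return the TSC value at the stable point.
#' @export
regenerationAbility <- function(time_min, tsc, stableTimeMin = 180,
                                cvTol = 0.25) {
  stopifnot(length(time_min) == length(tsc))
  if (any(diff(time_min) <= 0)) stop("tapping times must strictly increase")
  if (any(tsc < 0)) stop("negative TSC reading")
  if (max(time_min) < stableTimeMin)
    stop("series ends before the stable point (", stableTimeMin, " min)")
  idx <- which(time_min >= stableTimeMin)[1L]
  tail <- tsc[idx:length(tsc)]
  if (length(tail) > 1L && mean(tail) > 0 &&
      stats::sd(tail) / mean(tail) > cvTol)
    warning("plateau readings vary more than cvTol = ", cvTol)
  tsc[idx]
}

#' Correlate snoRNA expression with regeneration ability
#'
#' Spearman correlation of per-tree expression against per-tree
#' regeneration ability (TSC/C at the stable point), one row per snoRNA,
#' sorted by coefficient descending.
#'
#' @param expression numeric matrix, trees x snoRNAs.
#' @param abilities named numeric vector of regeneration abilities per tree.
#' @return data.frame: `snorna_id`, `rho`, `rho_sq`, `n`.
#' @export
correlateRegeneration <- function(expression, abilities) {
  trees <- rownames(expression)
  if (is.null(trees) || !all(trees %in% names(abilities)))
    stop("tree ids of expression and abilities do not match")
  y <- abilities[trees]
  rho <- vapply(colnames(expression),
                function(s) spearmanRho(expression[, s], y), numeric(1))
  out <- data.frame(snorna_id = colnames(expression), rho = rho,
                    rho_sq = rho^2, n = length(y),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$rho, out$snorna_id), , drop = FALSE]
}
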