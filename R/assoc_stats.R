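#' Pearson correlation with p-value
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom (no multiple-testing correction).
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Count miRNAs discrepant between pools beyond a fold line
#'
#' Among expressed miRNAs, how many differ by more than `fold` (in either
#' direction) between their total-pool and IP-pool representation.
#'
#' @param quants A `mirna_quant` data.frame.
#' @param fold Fold line (default 2).
#' @return List with `n_discrepant`, `n_total`.
#' @export
discrepancy_count <- function(quants, fold = 2) {
  q <- quants[quants$expressed & !is.na(quants$ratio), , drop = FALSE]
  disc <- q$ratio > fold | q$ratio < 1 / fold
  list(n_discrepant = sum(disc), n_total = nrow(q))
}

#' Normalize qPCR values to a reference miRNA
#'
#' Divides each target's linear abundance by the reference's. With
#' `mode = "ct"`, raw Ct values are first linearized as `2^-Ct`. The
#' reference should be a miRNA with neither selective loading into nor
#' exclusion from RISC (e.g. miR-138), so it cancels in IP/total contrasts.
#'
#' @param values Named numeric vector: target id -> value (linear or Ct).
#' @param reference_id Name of the reference target (must be present).
#' @param mode `"linear"` (default) or `"ct"`.
#' @return Named numeric vector of normalized values; the reference maps
#'   to 1.
#' @export
normalize_qpcr <- function(values, reference_id, mode = c("linear", "ct")) {
  mode <- match.arg(mode)
  if (!reference_id %in% names(values)) {
    stop("reference '", reference_id, "' not found")
  }
  if (mode == "ct") values <- 2^(-values)
  if (values[[reference_id]] <= 0) stop("reference value must be > 0")
  values / values[[reference_id]]
}

#' Relative luciferase sensor expression
#'
#' RLuc/FLuc (internal control) ratio normalized so the control construct
#' equals 1; scale-invariant in both channels.
#'
#' @param rluc,fluc Sensor Renilla and firefly activities (> 0).
#' @param control_rluc,control_fluc Control-construct activities (> 0).
#' @return Relative expression (< 1 means repression).
#' @export
sensor_relative_expression <- function(rluc, fluc, control_rluc,
                                       control_fluc) {
  if (any(c(rluc, fluc, control_rluc, control_fluc) <= 0)) {
    stop("luciferase activities must be > 0")
  }
  (rluc / fluc) / (control_rluc / control_fluc)
}

#' Fold change in RISC association relative to a control condition
#'
#' Each condition contributes an IP-pool and total-pool (reference
#' -normalized) abundance of the miRNA of interest; the readout is the
#' sensor condition's IP/total contribution relative to the control's,
#' which is set to 1.
#'
#' @param sensor_ip,sensor_total Normalized abundances under the sensor
#'   (target-overexpression) condition.
#' @param control_ip,control_total Normalized abundances under the control
#'   condition.
#' @return Fold change of RISC association (> 1 means enhanced loading).
#' @export
relative_risc_change <- function(sensor_ip, sensor_total,
                                 control_ip, control_total) {
  vals <- c(sensor_ip, sensor_total, control_ip, control_total)
  if (any(vals <= 0)) stop("all normalized values must be > 0")
  (sensor_ip / sensor_total) / (control_ip / control_total)
}

#' Correlate sensor repression with miRNA shares
#'
#' The package-level restatement of the association-predicts-function
#' analysis: Pearson correlation between sensor relative expression and the
#' miRNA's percent share on a chosen scale (RISC/IP pool or total pool).
#' Family-level sensors should be matched against pooled family shares.
#'
#' @param shares Named numeric vector: target id -> percent share.
#' @param sensors Named numeric vector: target id -> relative expression.
#' @param log2_shares Correlate against log2 shares instead of linear
#'   (default `FALSE`).
#' @return List with `r`, `p`, `n` over the shared targets (>= 3 required).
#' @export
function_correlation <- function(shares, sensors, log2_shares = FALSE) {
  common <- intersect(names(shares), names(sensors))
  if (length(common) < 3L) stop("fewer than 3 shared targets")
  x <- shares[common]
  if (log2_shares) x <- log2(x)
  pearson_cor(unname(x), unname(sensors[common]))
}
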