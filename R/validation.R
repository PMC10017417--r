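#' Silique-count recall ratios
#'
#' Three recalls relate the estimated count `SN_E`, the count visible in the
#' laser cloud `SN_L`, and the manually measured count `SN_M`:
#' `Re_EL = SN_E / SN_L`, `Re_LM = SN_L / SN_M`, `Re_EM = SN_E / SN_M`,
#' each expressed in percent.
#'
#' @param sn_e estimated silique count.
#' @param sn_l silique count in the point cloud (> 0).
#' @param sn_m manually measured count (> 0).
#' @return list with the three counts and `re_el`, `re_lm`, `re_em` (%).
#' @export
recalls <- function(sn_e, sn_l, sn_m) {
  if (sn_l <= 0 || sn_m <= 0)
    stop("recall denominators SN_L and SN_M must be positive")
  list(sn_e = sn_e, sn_l = sn_l, sn_m = sn_m,
       re_el = 100 * sn_e / sn_l,
       re_lm = 100 * sn_l / sn_m,
       re_em = 100 * sn_e / sn_m)
}

#' Agreement between estimates and reference values
#'
#' `R^2` of the least-squares linear fit of estimates against truths
#' (the squared Pearson correlation; `r2_method = "identity"` instead
#' reports `1 - SSE/SST` about the identity line), root mean squared error
#' of the raw differences, and the Pearson correlation with its p-value.
#'
#' @param estimates numeric vector.
#' @param truths numeric vector of the same length (>= 2, not constant).
#' @param r2_method `"regression"` (default) or `"identity"`.
#' @return list with `r2`, `rmse`, `r`, `p_value`, `n`.
#' @export
agreement <- function(estimates, truths,
                      r2_method = c("regression", "identity")) {
  r2_method <- match.arg(r2_method)
  if (length(estimates) != length(truths))
    stop("estimates and truths must have the same length")
  if (length(truths) < 2) stop("agreement needs at least 2 pairs")
  if (sd(truths) == 0) stop("constant truths: correlation undefined")
  r <- cor(estimates, truths)
  r2 <- if (r2_method == "regression") r^2
        else 1 - sum((estimates - truths)^2) / sum((truths - mean(truths))^2)
  rmse <- sqrt(mean((estimates - truths)^2))
  p <- if (sd(estimates) > 0)
    cor.test(estimates, truths)$p.value else NA_real_
  list(r2 = r2, rmse = rmse, r = r, p_value = p, n = length(truths))
}
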