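#' Model parameters for the resistant/sensitive growth model
#'
#' Bundles the parameters of the two-compartment drug-response model:
#' a sensitive subpopulation that dies off under drug with a possibly delayed
#' onset of death, and a resistant subpopulation that resumes logistic growth
#' after a proliferation delay.
#'
#' @param f_r Resistant fraction of the initial population, in `[0, 1]`.
#' @param g_r Post-treatment regrowth rate of resistant cells (per hour).
#' @param t_r Proliferation delay: duration of growth arrest of resistant
#'   cells after treatment (hours).
#' @param k_d Maximum sensitive-cell death rate (per hour).
#' @param t_d Death-delay time scale (hours): exponential time constant or
#'   linear ramp duration, depending on the death-rate form.
#' @param g_0 Pre-treatment (initial) growth rate (per hour).
#' @param N_max Carrying capacity of the well (cells).
#' @param N0 Initial cell count at the start of the final drug exposure.
#'
#' @return An object of class `model_params` (a named list).
#' @export
#' @examples
#' p <- model_params(f_r = 0.05, g_r = 0.02, t_r = 150, k_d = 0.04,
#'                   t_d = 40, g_0 = 0.02, N_max = 3e4, N0 = 2000)
model_params <- function(f_r, g_r, t_r, k_d, t_d, g_0, N_max, N0) {
  p <- list(f_r = f_r, g_r = g_r, t_r = t_r, k_d = k_d, t_d = t_d,
            g_0 = g_0, N_max = N_max, N0 = N0)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  vals <- unlist(p)
  if (any(!is.finite(vals)))
    stop("model parameters must be finite", call. = FALSE)
  if (p$f_r < 0 || p$f_r > 1) stop("f_r must lie in [0, 1]", call. = FALSE)
  if (p$g_r < 0) stop("g_r must be >= 0", call. = FALSE)
  if (p$t_r < 0) stop("t_r must be >= 0", call. = FALSE)
  if (p$k_d < 0) stop("k_d must be >= 0", call. = FALSE)
  if (p$t_d <= 0) stop("t_d must be > 0", call. = FALSE)
  if (p$g_0 < 0) stop("g_0 must be >= 0", call. = FALSE)
  if (p$N_max <= 0) stop("N_max must be > 0", call. = FALSE)
  if (p$N0 <= 0) stop("N0 must be > 0", call. = FALSE)
  if (p$N0 > p$N_max) stop("N0 must not exceed N_max", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Resistant/sensitive growth model parameters:\n")
  cat(sprintf("  f_r = %.4g  g_r = %.4g /h  t_r = %.4g h\n",
              x$f_r, x$g_r, x$t_r))
  cat(sprintf("  k_d = %.4g /h  t_d = %.4g h  g_0 = %.4g /h\n",
              x$k_d, x$t_d, x$g_0))
  cat(sprintf("  N_max = %.4g cells  N0 = %.4g cells\n", x$N_max, x$N0))
  invisible(x)
}

K_FORMS <- c("exponential", "linear", "constant")
TR_MODES <- c("input", "calibrated", "zero")
NMAX_MODES <- c("calibrated", "fixed")

#' Define one model variant
#'
#' A variant is one combination of structural assumptions: the form of the
#' sensitive-cell death rate, how the proliferation delay is handled, and
#' whether the carrying capacity is calibrated or fixed. The full grid has
#' 3 x 3 x 2 = 18 variants; the three retained for routine analysis use
#' `tr_mode = "input"` and `nmax_mode = "calibrated"` and differ only in
#' `k_form`.
#'
#' @param k_form Death-rate form: `"exponential"`, `"linear"` or `"constant"`.
#' @param tr_mode Proliferation-delay handling: `"input"` (measured value
#'   supplied), `"calibrated"` (fitted), or `"zero"` (assumed absent).
#' @param nmax_mode Carrying capacity: `"calibrated"` or `"fixed"`.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(k_form = c("exponential", "linear", "constant"),
                          tr_mode = c("input", "calibrated", "zero"),
                          nmax_mode = c("calibrated", "fixed")) {
  v <- list(k_form = match.arg(k_form), tr_mode = match.arg(tr_mode),
            nmax_mode = match.arg(nmax_mode))
  structure(v, class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("model variant: k = %s, t_r %s, N_max %s (p = %d)\n",
              x$k_form, x$tr_mode, x$nmax_mode, n_free_params(x)))
  invisible(x)
}

#' The full 18-variant model grid
#'
#' @return A data frame with columns `variant_id`, `k_form`, `tr_mode`,
#'   `nmax_mode` and `p` (free-parameter count), enumerating all 18 structural
#'   variants. Numbering follows the convention that variants 1-3 are the
#'   t_r-as-input, calibrated-N_max family (exponential, linear, constant
#'   death delay respectively).
#' @export
variant_grid <- function() {
  g <- expand.grid(k_form = K_FORMS,
                   tr_mode = TR_MODES,
                   nmax_mode = NMAX_MODES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(match(g$nmax_mode, NMAX_MODES),
               match(g$tr_mode, TR_MODES),
               match(g$k_form, K_FORMS)), ]
  g$variant_id <- seq_len(nrow(g))
  g$p <- vapply(seq_len(nrow(g)), function(i)
    n_free_params(model_variant(g$k_form[i], g$tr_mode[i], g$nmax_mode[i])),
    integer(1))
  rownames(g) <- NULL
  g[, c("variant_id", "k_form", "tr_mode", "nmax_mode", "p")]
}

#' Retrieve a variant from the 18-variant grid by id
#' @param id Integer 1..18.
#' @return A `model_variant`.
#' @export
variant_by_id <- function(id) {
  g <- variant_grid()
  if (!id %in% g$variant_id) stop("variant id must be in 1..18")
  row <- g[g$variant_id == id, ]
  model_variant(row$k_form, row$tr_mode, row$nmax_mode)
}

#' The three standard variants (death-delay forms with measured t_r)
#' @return A named list of `model_variant` objects (`"1"`, `"2"`, `"3"`).
#' @export
standard_variants <- function() {
  list(`1` = model_variant("exponential", "input", "calibrated"),
       `2` = model_variant("linear", "input", "calibrated"),
       `3` = model_variant("constant", "input", "calibrated"))
}

#' Number of free parameters of a variant
#'
#' The exponential and linear death-delay forms fit `f_r`, `g_r`, `k_d`,
#' `t_d` and `g_0`; the constant form drops the two delay-related terms
#' (`t_d`, `g_0`). Calibrating `t_r` adds one parameter, as does calibrating
#' `N_max`.
#'
#' @param variant A `model_variant`.
#' @return Integer free-parameter count.
#' @export
n_free_params <- function(variant) {
  p <- if (variant$k_form == "constant") 1L else 3L  # k_d (+ t_d, g_0)
  p <- p + 2L                                        # f_r, g_r
  p <- p + if (variant$tr_mode == "calibrated") 1L else 0L
  p <- p + if (variant$nmax_mode == "calibrated") 1L else 0L
  p
}

free_param_names <- function(variant, recovered = TRUE) {
  nm <- character(0)
  if (recovered) nm <- c(nm, "f_r", "g_r")
  nm <- c(nm, "k_d")
  if (variant$k_form != "constant") nm <- c(nm, "t_d", "g_0")
  if (variant$tr_mode == "calibrated" && recovered) nm <- c(nm, "t_r")
  if (variant$nmax_mode == "calibrated" && recovered) nm <- c(nm, "N_max")
  nm
}
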