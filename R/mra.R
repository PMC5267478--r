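#' Global response coefficient from a perturbed/control pair
#'
#' Modular response analysis quantifies the response of readout `i` to the
#' silencing of node `j` with the global response coefficient
#' `R = 2 (v_s - v_c) / (v_s + v_c)`, a symmetrized logarithmic derivative
#' computed from the perturbed (`v_s`) and control (`v_c`) activities.
#' `R` lies in `(-2, 2)` when both activities are positive, reaching -2 at
#' complete knockdown.
#'
#' @param v_perturbed activity under silencing, >= 0; vectorized.
#' @param v_control control activity, > 0; vectorized.
#' @return dimensionless response coefficient(s).
#' @seealso [ratio_from_R()] for the inverse mapping.
#' @export
response_coefficient <- function(v_perturbed, v_control) {
  if (any(v_control < 0) || any(v_perturbed < 0))
    stop("activities must be non-negative")
  if (any(v_perturbed == 0 & v_control == 0))
    stop("response coefficient undefined when both activities are 0")
  if (any(v_control == 0))
    stop("control activity must be > 0")
  2 * (v_perturbed - v_control) / (v_perturbed + v_control)
}

#' Fold change implied by a global response coefficient
#'
#' Inverts [response_coefficient()]: the concentration of readout `i` after
#' silencing, relative to control, is `v_s / v_c = (2 + R) / (2 - R)`.
#'
#' @param R response coefficient(s), < 2.
#' @return fold change(s) `v_s / v_c`.
#' @export
ratio_from_R <- function(R) {
  if (any(R >= 2)) stop("R must be < 2")
  (2 + R) / (2 - R)
}

# silencing factors measured in the RNA-interference experiments:
# remaining fractions of total Raf, MEK, ERK
SILENCING_FACTORS <- c(raf = 0.72, mek = 0.70, erk = 0.65)

#' Simulated global response coefficients
#'
#' Reproduces the silencing experiments in silico: for each cascade tier
#' the corresponding silencing factor (Raf 0.72, MEK 0.70, ERK 0.65) is
#' applied on its own, the model is simulated alongside the unsilenced
#' control, and the three observables (pRaf, ppMEK, ppERK) are compared at
#' the evaluation time with [response_coefficient()].  Following the
#' experimental convention, activities at t = 5 min (EGF) or t = 5/15 min
#' (NGF) stand in for steady states.
#'
#' @param theta [mapk_params].
#' @param growth_factor `"EGF"` or `"NGF"`; selects the feedback topology.
#' @param t_eval evaluation time in minutes (5 for EGF; 5 or 15 for NGF).
#' @param silencing_factors named numeric(3), remaining totals under siRNA.
#' @return A `mapk_grc` object: 3x3 matrix `R` (rows = readouts pRaf,
#'   ppMEK, ppERK; columns = silenced tier Raf, MEK, ERK) plus metadata.
#' @export
simulated_grc <- function(theta, growth_factor = c("EGF", "NGF"), t_eval = 5,
                          silencing_factors = SILENCING_FACTORS) {
  growth_factor <- match.arg(growth_factor)
  cond_fun <- if (growth_factor == "EGF") cond_egf else cond_ngf
  t_grid <- sort(unique(c(t_eval, 5)))
  ctrl <- simulate_cascade(theta, cond_fun(), t_grid)
  i_eval <- match(t_eval, ctrl$times)
  v_c <- observables(ctrl)[i_eval, ]
  if (any(v_c <= 0))
    stop("degenerate control: observable 0 at t_eval = ", t_eval, " min")
  R <- matrix(NA_real_, 3, 3,
              dimnames = list(readout = c("pRaf", "ppMEK", "ppERK"),
                              silenced = c("Raf", "MEK", "ERK")))
  for (j in 1:3) {
    s <- c(1, 1, 1)
    s[j] <- silencing_factors[j]
    pert <- simulate_cascade(theta, cond_fun(s = s), t_grid)
    v_s <- observables(pert)[match(t_eval, pert$times), ]
    R[, j] <- response_coefficient(v_s, v_c)
  }
  structure(list(R = R, sd = NULL, growth_factor = growth_factor,
                 t_eval = t_eval), class = "mapk_grc")
}

#' @export
print.mapk_grc <- function(x, ...) {
  cat("Global response coefficients (", x$growth_factor, ", t = ",
      x$t_eval, " min):\n", sep = "")
  print(round(x$R, 4))
  invisible(x)
}

#' Write GRC tables as tidy CSV
#'
#' @param grc_df data frame with columns `growth_factor`, `t_min`,
#'   `readout`, `silenced`, `R_mean`, `R_sd`, `n_replicates` (the GRC block
#'   of a dataset), or a `mapk_grc` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grc_csv <- function(grc_df, path) {
  if (inherits(grc_df, "mapk_grc")) {
    grc_df <- data.frame(growth_factor = grc_df$growth_factor,
                         t_min = grc_df$t_eval,
                         readout = rep(rownames(grc_df$R), 3),
                         silenced = rep(colnames(grc_df$R), each = 3),
                         R_mean = as.vector(grc_df$R),
                         R_sd = NA_real_, n_replicates = NA_integer_)
  }
  utils::write.csv(grc_df, path, row.names = FALSE)
  invisible(path)
}
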