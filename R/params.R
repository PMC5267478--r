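#' Parameter vector of the MAPK cascade model
#'
#' Constructs the 12-parameter vector of the rescaled cascade model:
#' phosphorylation rates `k1p..k4p`, dephosphorylation rates `k1m..k4m`,
#' the negative- and positive-feedback strengths `kFn` and `kFp`, the Hill
#' exponent `g` of the positive feedback, and the half-decay time `K` (min)
#' of the transient input signal.
#'
#' Units: `k1p`, `kFp` are 1/min (they multiply a dimensionless activity);
#' `k2p`, `k3p`, `k4p`, `kFn` are 1/(min * fraction); all dephosphorylation
#' rates are 1/min; `g` is dimensionless and must be >= 1; `K` is in minutes.
#'
#' @param x named numeric vector, list, or 12 numbers in canonical order
#'   (`k1p, k2p, k3p, k4p, k1m, k2m, k3m, k4m, kFn, kFp, g, K`).
#' @return An object of class `mapk_params`: a named numeric vector of
#'   length 12.
#' @examples
#' theta <- mapk_params(c(k1p = 1, k2p = 1, k3p = 1, k4p = 1,
#'                        k1m = 0.5, k2m = 0.5, k3m = 0.5, k4m = 0.5,
#'                        kFn = 1, kFp = 2, g = 2, K = 10))
#' @export
mapk_params <- function(x) {
  if (is.list(x)) x <- unlist(x)
  nm <- names(x)
  x <- stats::setNames(as.numeric(x), nm)
  if (!is.null(nm) && all(PARAM_NAMES %in% nm)) {
    x <- x[PARAM_NAMES]
  } else if (length(x) == length(PARAM_NAMES)) {
    names(x) <- PARAM_NAMES
  }
  validate_params(x)
  structure(x, class = "mapk_params")
}

#' @rdname mapk_params
#' @export
PARAM_NAMES <- c("k1p", "k2p", "k3p", "k4p",
                 "k1m", "k2m", "k3m", "k4m",
                 "kFn", "kFp", "g", "K")

validate_params <- function(x) {
  if (length(x) != 12L || !all(names(x) == PARAM_NAMES))
    stop("parameter vector must contain exactly the 12 named constants: ",
         paste(PARAM_NAMES, collapse = ", "))
  if (any(!is.finite(x)))
    stop("parameter vector contains non-finite entries")
  if (any(x <= 0))
    stop("all model parameters must be strictly positive")
  if (x[["g"]] < 1)
    stop("Hill exponent g must be >= 1")
  invisible(x)
}

#' @export
print.mapk_params <- function(x, ...) {
  cat("MAPK cascade parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read or write a parameter vector as a JSON record
#'
#' Parameter vectors are persisted as flat JSON objects keyed by the
#' canonical parameter names, so they survive as plain text and round-trip
#' exactly at double precision.
#'
#' @param theta an [mapk_params] object.
#' @param path file path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns an [mapk_params] object.
#' @export
write_params_json <- function(theta, path) {
  stopifnot(inherits(theta, "mapk_params"))
  jsonlite::write_json(as.list(unclass(theta)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  mapk_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Experimental condition for a cascade simulation
#'
#' Bundles everything outside the inferred parameter vector that defines a
#' simulation: which feedback loop is active (positive for NGF, negative for
#' EGF), the silencing factors `s1..s3` (remaining fraction of total Raf,
#' MEK, ERK after RNA interference), the input dose multiplier `ku`, and the
#' intervention switches (MEK inhibition, feedback removal, abrupt signal
#' termination at `t_off`).
#'
#' @param fp logical; positive feedback ppERK -> Raf phosphorylation active
#'   (the NGF topology).
#' @param fn logical; negative feedback ppERK -> pRaf dephosphorylation
#'   active (the EGF topology). `fp` and `fn` must not both be `TRUE`.
#' @param s numeric(3) > 0; remaining fractions of total Raf, MEK, ERK.
#'   Silencing experiments use values in (0, 1]; values above 1 model
#'   increased protein content in sensitivity analyses.
#' @param ku input scale >= 0 (dose multiplier on the Raf activation rate).
#' @param mek_inhibited logical; forces the MEK phosphorylation rate to 0.
#' @param feedback_removed logical; forces `kFp = kFn = 0`.
#' @param t_off time (min) after which the input is clamped to 0; `Inf`
#'   leaves the signal untouched.
#' @return An object of class `mapk_condition`.
#' @seealso [cond_egf()], [cond_ngf()] for the two control topologies.
#' @export
mapk_condition <- function(fp = FALSE, fn = FALSE, s = c(1, 1, 1), ku = 1,
                           mek_inhibited = FALSE, feedback_removed = FALSE,
                           t_off = Inf) {
  if (isTRUE(fp) && isTRUE(fn))
    stop("fp and fn must not both be TRUE: a condition has one effective feedback")
  if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
    stop("protein-content factors s must be three positive values")
  if (ku < 0) stop("ku must be >= 0")
  if (t_off < 0) stop("t_off must be >= 0 (use Inf for no termination)")
  structure(list(fp = isTRUE(fp), fn = isTRUE(fn),
                 s = as.numeric(s), ku = as.numeric(ku),
                 mek_inhibited = isTRUE(mek_inhibited),
                 feedback_removed = isTRUE(feedback_removed),
                 t_off = as.numeric(t_off)),
            class = "mapk_condition")
}

#' @rdname mapk_condition
#' @param ... passed on to [mapk_condition()] (e.g. `s`, `ku`, `t_off`).
#' @export
cond_egf <- function(...) mapk_condition(fp = FALSE, fn = TRUE, ...)

#' @rdname mapk_condition
#' @export
cond_ngf <- function(...) mapk_condition(fp = TRUE, fn = FALSE, ...)

#' @export
print.mapk_condition <- function(x, ...) {
  gf <- if (x$fp) "NGF (positive feedback)"
        else if (x$fn) "EGF (negative feedback)" else "no feedback"
  cat("MAPK condition:", gf, "\n")
  cat("  s = (", paste(format(x$s), collapse = ", "), "), ku =", x$ku, "\n")
  if (x$mek_inhibited) cat("  MEK inhibited (k2p = 0)\n")
  if (x$feedback_removed) cat("  feedback removed (kFp = kFn = 0)\n")
  if (is.finite(x$t_off)) cat("  signal terminated at t =", x$t_off, "min\n")
  invisible(x)
}

# flat double vector handed to the compiled derivative function
pack_parms <- function(theta, cond) {
  c(unclass(theta),
    fp = as.numeric(cond$fp), fn = as.numeric(cond$fn),
    s1 = cond$s[1], s2 = cond$s[2], s3 = cond$s[3],
    ku = cond$ku,
    mek_inhibited = as.numeric(cond$mek_inhibited),
    feedback_removed = as.numeric(cond$feedback_removed),
    t_off = if (is.finite(cond$t_off)) cond$t_off else .Machine$double.xmax)
}
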