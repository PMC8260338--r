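# Mass <-> molar conversion. Immunoassays report pg/mL; the binding
# equations need pmol/L. All internal binding math is in pmol/L; pg/mL
# appears only at the I/O boundary.

#' Built-in analyte molecular weights
#'
#' Returns the registry of analyte molecular weights used for mass/molar
#' conversion. The two built-in analytes are the PlGF ligand (34 kDa) and the
#' sFlt-1 receptor (100 kDa); both are fixed. Additional analytes can be
#' supplied via `extra`.
#'
#' @param extra Optional named numeric vector of additional analytes
#'   (name = molecular weight in Da, g/mol). Must be strictly positive and
#'   must not redefine `plgf` or `sflt1`.
#' @return Named numeric vector of molecular weights in Daltons.
#' @examples
#' analyte_registry()
#' analyte_registry(extra = c(vegf = 45000))
#' @export
analyte_registry <- function(extra = NULL) {
  reg <- c(plgf = 34000, sflt1 = 100000)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop_plgf("extra analytes must be a named numeric vector", "invalid_analyte")
    }
    if (any(names(extra) %in% names(reg))) {
      stop_plgf("built-in analytes plgf and sflt1 cannot be redefined",
                "invalid_analyte")
    }
    if (any(!is.finite(extra)) || any(extra <= 0)) {
      stop_plgf("molecular weights must be strictly positive", "invalid_analyte")
    }
    reg <- c(reg, extra)
  }
  reg
}

#' Molecular weight of an analyte
#'
#' @param analyte Analyte name (`"plgf"` or `"sflt1"`, or a name registered
#'   via the `registry` argument).
#' @param registry Registry as returned by [analyte_registry()].
#' @return Molecular weight in Daltons.
#' @export
analyte_mw <- function(analyte, registry = analyte_registry()) {
  if (!is.character(analyte) || length(analyte) != 1L || !analyte %in% names(registry)) {
    stop_plgf(sprintf("unknown analyte '%s'", paste(analyte, collapse = ",")),
              "invalid_analyte")
  }
  mw <- unname(registry[[analyte]])
  if (!is.finite(mw) || mw <= 0) {
    stop_plgf("molecular weight must be strictly positive", "invalid_analyte")
  }
  mw
}

#' Convert mass concentration (pg/mL) to molar concentration (pmol/L)
#'
#' pg/mL and pmol/L are related by the molecular weight:
#' `pmol/L = pg/mL * 1000 / MW(Da)`. One molecular weight's worth of pg per
#' mL is 1 nmol/L by construction.
#'
#' @param x Mass concentration(s) in pg/mL, non-negative. Vectorized.
#' @param analyte `"plgf"` or `"sflt1"` (or a registered extra analyte).
#' @param mw Molecular weight in Da; overrides `analyte` when given.
#' @return Molar concentration(s) in pmol/L.
#' @examples
#' mass_to_molar(34000, "plgf")   # 1000 pmol/L
#' mass_to_molar(208, "plgf")     # AFLP median free PlGF -> 6.1176 pmol/L
#' @seealso [molar_to_mass()] for the exact inverse.
#' @export
mass_to_molar <- function(x, analyte = "plgf", mw = NULL) {
  if (is.null(mw)) mw <- analyte_mw(analyte)
  if (!is.finite(mw) || mw <= 0) {
    stop_plgf("molecular weight must be strictly positive", "invalid_analyte")
  }
  check_nonneg(x, "concentration (pg/mL)")
  x * 1000 / mw
}

#' Convert molar concentration (pmol/L) to mass concentration (pg/mL)
#'
#' Exact inverse of [mass_to_molar()]: `pg/mL = pmol/L * MW(Da) / 1000`.
#'
#' @inheritParams mass_to_molar
#' @param x Molar concentration(s) in pmol/L, non-negative. Vectorized.
#' @return Mass concentration(s) in pg/mL.
#' @examples
#' molar_to_mass(1000, "plgf")  # 34000 pg/mL
#' @export
molar_to_mass <- function(x, analyte = "plgf", mw = NULL) {
  if (is.null(mw)) mw <- analyte_mw(analyte)
  if (!is.finite(mw) || mw <= 0) {
    stop_plgf("molecular weight must be strictly positive", "invalid_analyte")
  }
  check_nonneg(x, "concentration (pmol/L)")
  x * mw / 1000
}

# classed errors so callers/tests can distinguish failure modes
stop_plgf <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("plgfbind_", class), "plgfbind_error")))
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x)) stop_plgf(paste(what, "must be numeric"), "domain_error")
  bad <- is.finite(x) & x < 0
  if (any(is.na(x)) || any(!is.finite(x)) || any(bad)) {
    stop_plgf(paste(what, "must be finite and non-negative"), "domain_error")
  }
  invisible(x)
}
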