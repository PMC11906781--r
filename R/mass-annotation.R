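# Mass arithmetic for LC-MS annotation: elemental formulas, monoisotopic
# masses, adduct m/z, ppm error, and external-standard semi-quantification.

# Monoisotopic masses (Da) of the most abundant isotope; C is exactly 12 by
# definition of the unified atomic mass scale.
.MONOISOTOPIC <- c(
  H = 1.007825032,
  C = 12,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972071174,
  P = 30.973761998
)

.PROTON_MASS <- 1.007276467
.WATER_MASS  <- 18.010565 # H2O monoisotopic, 2*H + O

# Registered ESI adducts, all singly charged. m = molecular multiplicity,
# dp = proton delta (+1 protonation, -1 deprotonation), w = water losses.
.ADDUCTS <- list(
  "[M+H]+"      = list(m = 1L, dp = +1L, w = 0L),
  "[M-H]-"      = list(m = 1L, dp = -1L, w = 0L),
  "[M+H-H2O]+"  = list(m = 1L, dp = +1L, w = 1L),
  "[M-H-H2O]-"  = list(m = 1L, dp = -1L, w = 1L),
  "[2M+H]+"     = list(m = 2L, dp = +1L, w = 0L),
  "[2M-H]-"     = list(m = 2L, dp = -1L, w = 0L)
)

#' List registered adduct names
#'
#' @return Character vector of adduct names understood by [adduct_mz()] and
#'   [neutral_mass_from_mz()].
#' @export
adduct_registry <- function() names(.ADDUCTS)

# Normalize an adduct label: strip whitespace, underscores (subscript
# markers), carets, and a trailing charge magnitude ("+1" -> "+").
.normalize_adduct <- function(name) {
  x <- gsub("[[:space:]_^]", "", name)
  x <- sub("([+-])1\\]?$", "\\1", x)
  # tolerate "]+1" style: charge digits after the bracket
  x <- sub("\\]([+-])1$", "]\\1", x)
  if (!grepl("\\]$", x) && grepl("[+-]$", x)) {
    # "[M+H]+" forms already end in sign; keep as-is
  }
  x
}

.lookup_adduct <- function(adduct) {
  key <- .normalize_adduct(adduct)
  spec <- .ADDUCTS[[key]]
  if (is.null(spec)) {
    stop("unregistered adduct: '", adduct, "' (known: ",
         paste(names(.ADDUCTS), collapse = ", "), ")", call. = FALSE)
  }
  spec
}

#' Parse a chemical formula into an elemental composition
#'
#' Accepts plain Hill-style strings such as `"C2H7NO3S"`. Underscore
#' subscript markers (`"C_2_H_7_NO_3_S"`) are tolerated and stripped before
#' parsing. Only elements with tabulated monoisotopic masses (C, H, N, O, S,
#' P) are accepted.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts (zero-count elements are
#'   dropped).
#' @examples
#' parse_formula("C2H7NO3S")   # taurine
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- gsub("[[:space:]_]", "", text)
  if (!nzchar(x)) stop("empty formula", call. = FALSE)
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  tokens <- regmatches(x, list(matches))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(x)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.MONOISOTOPIC)) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'",
           call. = FALSE)
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  counts[counts > 0L]
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named integer vector from [parse_formula()], or a formula
#'   string which is parsed first.
#' @return Mass in Da. An empty composition has mass 0.
#' @examples
#' monoisotopic_mass("H2O")       # 18.010565
#' monoisotopic_mass("C2H7NO3S")  # taurine, 125.014664
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (length(comp) == 0L) return(0)
  missing <- setdiff(names(comp), names(.MONOISOTOPIC))
  if (length(missing)) {
    stop("no monoisotopic mass tabulated for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(comp * .MONOISOTOPIC[names(comp)])
}

#' Theoretical m/z of an adduct ion
#'
#' For a singly charged adduct, `m/z = m*M + dp*1.007276467 - w*18.010565`
#' where `m` is the molecular multiplicity, `dp` the proton delta and `w`
#' the number of water losses. The electron mass is absorbed into the proton
#' mass constant; the difference is far below printed m/z precision.
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (> 0).
#' @param adduct Adduct name, e.g. `"[M+H]+"`, `"[2M-H]-"`, `"[M+H-H2O]+"`.
#'   Spaces, underscores and explicit charge digits are tolerated.
#' @return m/z in Da per unit charge.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  a <- .lookup_adduct(adduct)
  a$m * neutral_mass + a$dp * .PROTON_MASS - a$w * .WATER_MASS
}

#' Neutral mass back-calculated from an observed m/z
#'
#' Exact inverse of [adduct_mz()].
#'
#' @param mz Observed m/z.
#' @param adduct Registered adduct name.
#' @return Neutral mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  stopifnot(is.numeric(mz))
  a <- .lookup_adduct(adduct)
  (mz - a$dp * .PROTON_MASS + a$w * .WATER_MASS) / a$m
}

#' Mass error in parts per million
#'
#' Compares an observed m/z with the theoretical m/z of `formula` ionized as
#' `adduct`: `(observed - theoretical)/theoretical * 1e6`. The identification
#' tolerance used in high-resolution annotation is |ppm| < 5.
#'
#' @param observed_mz Observed m/z.
#' @param formula Formula string or parsed composition.
#' @param adduct Registered adduct name.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed_mz, formula, adduct) {
  theo <- adduct_mz(monoisotopic_mass(formula), adduct)
  (observed_mz - theo) / theo * 1e6
}

#' Annotate a table of formula/adduct/m-z records
#'
#' Computes theoretical monoisotopic mass, theoretical adduct m/z, the
#' observed-derived neutral mass and the ppm error for each record, and flags
#' records within a ppm tolerance.
#'
#' @param records Data frame with columns `formula`, `adduct`, `observed_mz`
#'   (other columns are carried through).
#' @param tol_ppm Acceptance tolerance on |ppm error| (default 5).
#' @return The input with columns `theoretical_mass`, `theoretical_mz`,
#'   `calc_neutral_mass`, `ppm_error`, `accepted` appended.
#' @export
annotate_records <- function(records, tol_ppm = 5) {
  stopifnot(is.data.frame(records),
            all(c("formula", "adduct", "observed_mz") %in% names(records)))
  n <- nrow(records)
  theo_mass <- vapply(records$formula, monoisotopic_mass, numeric(1))
  theo_mz <- numeric(n); neutral <- numeric(n); ppm <- numeric(n)
  for (i in seq_len(n)) {
    theo_mz[i] <- adduct_mz(theo_mass[i], records$adduct[i])
    neutral[i] <- neutral_mass_from_mz(records$observed_mz[i],
                                       records$adduct[i])
    ppm[i] <- (records$observed_mz[i] - theo_mz[i]) / theo_mz[i] * 1e6
  }
  records$theoretical_mass <- theo_mass
  records$theoretical_mz <- theo_mz
  records$calc_neutral_mass <- neutral
  records$ppm_error <- ppm
  records$accepted <- abs(ppm) < tol_ppm
  records
}

#' Bundled example annotation records
#'
#' Ten metabolite annotations (formula, adduct, observed m/z, retention
#' time, HMDB id, PCA loadings and VIP score) for oxidative-stress related
#' metabolites in intestinal epithelial cell extracts, shipped as a CSV
#' fixture for examples and tests.
#'
#' @return Data frame with one row per metabolite.
#' @export
example_annotations <- function() {
  utils::read.csv(system.file("extdata", "metabolite_annotations.csv",
                              package = "chemomet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least-squares regression of detector response (XIC area or
#' absorbance) on standard concentration. Limits of detection and
#' quantification follow the 3.3/10 sigma-over-slope convention with sigma
#' taken as the residual standard deviation of the regression (an
#' `sd_source = "intercept"` alternative uses the standard error of the
#' intercept estimate).
#'
#' @param conc Standard concentrations (>= 3 distinct values).
#' @param response Detector responses, same length.
#' @param sd_source `"residual"` (default) or `"intercept"`.
#' @return Object of class `calibration_curve`: slope, intercept, r_squared,
#'   response_sd, lod, loq, range, n.
#' @export
fit_calibration <- function(conc, response, sd_source = c("residual", "intercept")) {
  sd_source <- match.arg(sd_source)
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct concentration levels", call. = FALSE)
  }
  if (stats::var(conc) == 0) stop("zero concentration variance", call. = FALSE)
  fit <- stats::lm(response ~ conc)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  r2 <- summary(fit)$r.squared
  s <- if (sd_source == "residual") {
    sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  } else {
    summary(fit)$coefficients["(Intercept)", "Std. Error"]
  }
  structure(list(slope = a, intercept = b, r_squared = r2,
                 response_sd = s,
                 lod = 3.3 * s / a, loq = 10 * s / a,
                 range = range(conc), n = length(conc),
                 sd_source = sd_source),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: y = %.6gx %s %.6g (R2 = %.5f)\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$r_squared))
  cat(sprintf("  LOD = %.4g, LOQ = %.4g (sigma: %s), range [%g, %g], n = %d\n",
              x$lod, x$loq, x$sd_source, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' Semi-quantify a peak area as standard equivalents
#'
#' Converts an XIC area to concentration through a calibration curve, then to
#' mg equivalents per g of dried extract given the reconstitution volume and
#' extract mass. Areas below the curve-predicted LOQ response are reported as
#' the string `"< LOQ"`, mirroring how such values are tabulated.
#'
#' @param xic_area Peak area.
#' @param curve A `calibration_curve`.
#' @param extract_mass Dried extract mass in g.
#' @param volume Reconstitution volume in mL.
#' @return List with `concentration` (curve units, typically ug/mL),
#'   `mg_per_g` (mg equivalents per g extract, or `NA`), `label` (formatted
#'   value or `"< LOQ"`), and `in_range` flag.
#' @export
quantify_equivalents <- function(xic_area, curve, extract_mass, volume) {
  stopifnot(inherits(curve, "calibration_curve"),
            extract_mass > 0, volume > 0)
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (xic_area - curve$intercept) / curve$slope
  loq_response <- curve$slope * curve$loq + curve$intercept
  below <- xic_area < loq_response
  in_range <- conc >= curve$range[1] && conc <= curve$range[2]
  mg_per_g <- conc * volume / extract_mass / 1000  # ug/g -> mg/g
  list(concentration = conc,
       mg_per_g = if (below) NA_real_ else mg_per_g,
       label = if (below) "< LOQ" else sprintf("%.4g", mg_per_g),
       in_range = in_range)
}

#' Invert a linear assay curve
#'
#' Reads a concentration off a spectrophotometric standard curve
#' `y = a*x + b`, as done for total phenolic / total flavonoid content.
#'
#' @param absorbance Measured response y.
#' @param curve A `calibration_curve`, or a list with `slope` and `intercept`.
#' @return Concentration `x = (y - b)/a`.
#' @export
invert_assay_curve <- function(absorbance, curve) {
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (absorbance - curve$intercept) / curve$slope
}

#' Construct a calibration curve from published coefficients
#'
#' Convenience constructor when only slope/intercept (and optionally R^2) of
#' a fitted standard curve are available.
#'
#' @param slope,intercept Linear coefficients.
#' @param r_squared Optional coefficient of determination.
#' @return A `calibration_curve` with no LOD/LOQ information.
#' @export
calibration_from_coef <- function(slope, intercept, r_squared = NA_real_) {
  stopifnot(is.numeric(slope), is.numeric(intercept), slope != 0)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, response_sd = NA_real_,
                 lod = NA_real_, loq = NA_real_,
                 range = c(NA_real_, NA_real_), n = NA_integer_,
                 sd_source = "none"),
            class = "calibration_curve")
}
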