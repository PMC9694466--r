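#' Convert an IC50 to an experimental binding free energy
#'
#' \code{dG_exp = R T ln(IC50)} with the IC50 expressed in molar
#' (R = 1.9872e-3 kcal/(mol K)).
#'
#' @param ic50_nM IC50 in nanomolar (vectorized).
#' @param T temperature in K (default 310, the simulation temperature).
#' @return dG_exp in kcal/mol.
#' @export
dg_from_ic50 <- function(ic50_nM, T = 310) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0))
    .fail("IC50 must be positive")
  .const$R * T * log(ic50_nM * 1e-9)
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' The calculated-versus-experimental agreement statistic: the squared
#' Pearson correlation between the two value sets, in [0, 1].
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return squared Pearson correlation.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) .fail("x and y must have equal length")
  if (length(x) < 3) .fail("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) .fail("zero variance")
  cor(x, y)^2
}

#' Assemble the calculated-versus-experimental affinity table
#'
#' Combines per-system energy reports with IC50 values into affinity
#' records: \code{dG_cal} from each report, \code{dG_exp = R T ln(IC50)},
#' and \code{ddG_cal = dG_cal(system) - dG_cal(reference)} (blank for the
#' reference system itself).
#'
#' @param reports named list of \code{\link{energy_report}} objects (or of
#'   lists carrying a \code{dG_cal} element).
#' @param ic50s named numeric vector of IC50 values (nM), names matching
#'   \code{reports}; NA allowed only when \code{allow_missing} is TRUE.
#' @param reference_system name of the reference (wild-type-like) system.
#' @param T temperature (K).
#' @param allow_missing if TRUE, systems with missing IC50 get a blank
#'   \code{dG_exp} (with a warning) instead of an error.
#' @return data.frame with columns \code{system}, \code{ic50_nM},
#'   \code{dG_exp}, \code{dG_cal}, \code{ddG_cal}.
#' @export
assemble_affinity_table <- function(reports, ic50s, reference_system,
                                    T = 310, allow_missing = FALSE) {
  systems <- names(reports)
  if (!(reference_system %in% systems))
    .fail("reference system '%s' not among the reports", reference_system)
  ic <- ic50s[systems]
  miss <- is.na(ic)
  if (any(miss)) {
    if (!allow_missing)
      .fail("missing IC50 for system '%s'", systems[which(miss)[1]])
    warning("missing IC50 for: ", paste(systems[miss], collapse = ", "),
            "; dG_exp left blank", call. = FALSE)
  }
  dg_cal <- vapply(reports, function(r) r$dG_cal, numeric(1))
  dg_exp <- rep(NA_real_, length(systems))
  dg_exp[!miss] <- dg_from_ic50(ic[!miss], T = T)
  ddg <- dg_cal - dg_cal[[reference_system]]
  ddg[systems == reference_system] <- NA_real_
  data.frame(system = systems, ic50_nM = as.numeric(ic), dG_exp = dg_exp,
             dG_cal = as.numeric(dg_cal), ddG_cal = as.numeric(ddg),
             row.names = NULL)
}

#' Printed affinity ledgers of the two inhibitor series
#'
#' The published per-system MM/GBSA component means, entropies, calculated
#' and experimental binding free energies and IC50 values for the AMG510
#' (sotorasib) and MRTX849 (adagrasib) series across KRAS G12C and its four
#' second-site mutants. These printed values are inputs: the package
#' recomputes the derived columns (dG_exp, dG_cal, ddG_cal, r^2) from them.
#'
#' @return named list of two data.frames (\code{AMG510}, \code{MRTX849})
#'   with columns system, dE_vdW, dE_elec, dE_covalent, dG_solv, dE_bind,
#'   minus_TdS, dG_cal, ddG_cal, dG_exp, ic50_nM.
#' @export
kras_affinity_tables <- function() {
  read1 <- function(f) {
    read.delim(system.file("extdata", f, package = "switchscope"),
               stringsAsFactors = FALSE)
  }
  list(AMG510 = read1("kras_affinity_amg510.tsv"),
       MRTX849 = read1("kras_affinity_mrtx849.tsv"))
}
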