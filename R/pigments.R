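#' Photosynthetic pigment quantification from absorbances
#'
#' Spectrophotometric formulas for 96% ethanol extracts (Lichtenthaler
#' coefficient set), absorbances read at 663, 646 and 470 nm:
#' \deqn{Chl\,a = 12.21\,A_{663} - 2.81\,A_{646}}
#' \deqn{Chl\,b = 20.13\,A_{646} - 5.10\,A_{663}}
#' \deqn{Chl\,T = Chl\,a + Chl\,b}
#' \deqn{Car = (1000\,A_{470} - 3.27\,Chl\,a - 104\,Chl\,b)/227}
#' Results are concentrations in ug/ml of extract; [pigment_panel()] can
#' convert to mg/g fresh weight given the extraction volume and tissue
#' mass.
#'
#' @param a663,a646,a470 absorbances (dimensionless, non-negative).
#' @param chl_a,chl_b chlorophyll a and b concentrations (ug/ml).
#' @return pigment concentration(s), ug/ml of extract.
#' @examples
#' chlorophyll_a(0.5, 0.2)
#' carotenoids(0.3, chlorophyll_a(0.5, 0.2), chlorophyll_b(0.5, 0.2))
#' @name pigments
NULL

check_absorbance <- function(...) {
  a <- c(...)
  if (any(!is.finite(a) | a < 0))
    stop("absorbances must be finite and non-negative", call. = FALSE)
  invisible(a)
}

#' @rdname pigments
#' @export
chlorophyll_a <- function(a663, a646) {
  check_absorbance(a663, a646)
  12.21 * a663 - 2.81 * a646
}

#' @rdname pigments
#' @export
chlorophyll_b <- function(a663, a646) {
  check_absorbance(a663, a646)
  20.13 * a646 - 5.1 * a663
}

#' @rdname pigments
#' @export
total_chlorophyll <- function(chl_a, chl_b) {
  chl_a + chl_b
}

#' @rdname pigments
#' @export
carotenoids <- function(a470, chl_a, chl_b) {
  check_absorbance(a470)
  car <- (1000 * a470 - 3.27 * chl_a - 104 * chl_b) / 227
  if (any(car < 0))
    warning("negative carotenoid estimate(s): check absorbance readings",
            call. = FALSE)
  car
}

#' Pigment panel for a table of absorbance readings
#'
#' Applies the four pigment formulas to each row of an absorbance table.
#' With `per_gram = TRUE`, concentrations are converted from ug/ml of
#' extract to mg/g fresh weight using the extraction protocol's volume
#' and tissue mass (defaults: 2 ml of 96% ethanol per 25 mg tissue).
#'
#' @param panel data frame with columns `sample_id`, `a663`, `a646`, `a470`.
#' @param per_gram convert to mg pigment per g fresh tissue.
#' @param extract_ml,tissue_mg extraction volume (ml) and tissue fresh
#'   mass (mg) used when `per_gram = TRUE`.
#' @return `panel` with columns `chl_a`, `chl_b`, `chl_total`,
#'   `carotenoids` appended.
#' @export
pigment_panel <- function(panel, per_gram = FALSE,
                          extract_ml = 2, tissue_mg = 25) {
  stopifnot(is.data.frame(panel))
  need <- c("sample_id", "a663", "a646", "a470")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("absorbance table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- panel
  out$chl_a <- chlorophyll_a(panel$a663, panel$a646)
  out$chl_b <- chlorophyll_b(panel$a663, panel$a646)
  out$chl_total <- total_chlorophyll(out$chl_a, out$chl_b)
  out$carotenoids <- carotenoids(panel$a470, out$chl_a, out$chl_b)
  if (per_gram) {
    # ug/ml * ml / mg = ug/mg = mg/g
    f <- extract_ml / tissue_mg
    for (col in c("chl_a", "chl_b", "chl_total", "carotenoids"))
      out[[col]] <- out[[col]] * f
  }
  out
}

#' Absorbances producing a target pigment profile
#'
#' Inverts the pigment formulas: given target chlorophyll a, chlorophyll b
#' and carotenoid concentrations (ug/ml), returns the unique absorbance
#' triple (A663, A646, A470) that produces them.  Used by the synthetic
#' absorbance generator; the forward/inverse composition is exact to
#' floating precision.
#'
#' @param chl_a,chl_b,carotenoids target concentrations, ug/ml.
#' @return data frame with columns `a663`, `a646`, `a470`.
#' @export
invert_pigments <- function(chl_a, chl_b, carotenoids) {
  # [chl_a; chl_b] = M [a663; a646]
  M <- matrix(c(12.21, -2.81, -5.1, 20.13), 2, 2, byrow = TRUE)
  ab <- solve(M, rbind(chl_a, chl_b))
  a470 <- (227 * carotenoids + 3.27 * chl_a + 104 * chl_b) / 1000
  bad <- ab[1, ] < 0 | ab[2, ] < 0 | a470 < 0
  if (any(bad))
    stop("nonphysical pigment targets (negative implied absorbance) in ",
         sum(bad), " sample(s)", call. = FALSE)
  data.frame(a663 = ab[1, ], a646 = ab[2, ], a470 = a470)
}
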