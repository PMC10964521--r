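#' Collapse technical qPCR replicates
#'
#' Averages technical-replicate CT values within each
#' (genotype, treatment, gene, biological replicate) cell.  Biological
#' replicates are preserved for downstream error estimation.
#'
#' @param ct data frame with columns `genotype`, `treatment`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @return data frame with one row per (genotype, treatment, gene,
#'   bio_rep) and the mean `ct`.
#' @export
collapse_technical <- function(ct) {
  ct <- validate_ct(ct)
  agg <- stats::aggregate(ct["ct"],
                          ct[c("genotype", "treatment", "gene", "bio_rep")],
                          FUN = mean)
  agg[order(agg$genotype, agg$treatment, agg$gene, agg$bio_rep), ,
      drop = FALSE]
}

validate_ct <- function(ct) {
  stopifnot(is.data.frame(ct))
  need <- c("genotype", "treatment", "gene", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("CT table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)))
    stop("non-finite CT value(s) at row(s): ",
         paste(which(!is.finite(ct$ct)), collapse = ", "), call. = FALSE)
  out <- ct$ct < 5 | ct$ct > 45
  if (any(out))
    warning(sum(out), " CT value(s) outside the usual [5, 45] cycle range",
            call. = FALSE)
  ct
}

#' Delta-CT: target minus reference
#'
#' @param target_ct,reference_ct cycle-threshold values (finite reals).
#' @return `target_ct - reference_ct`.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  stopifnot(is.finite(target_ct), is.finite(reference_ct))
  target_ct - reference_ct
}

#' Livak fold change from delta-CT values
#'
#' \eqn{2^{-\Delta\Delta CT}} with
#' \eqn{\Delta\Delta CT = \Delta CT_{treated} - \Delta CT_{calibrator}}.
#' Amplification efficiency is taken as exactly 2 (pure Livak method);
#' use [primer_efficiency()] to check that assumption from a dilution
#' series.
#'
#' @param dct_treated,dct_calibrator delta-CT of the treated sample and of
#'   the calibrator (typically the same genotype's control cell).
#' @return strictly positive fold change.
#' @examples
#' fold_change(2, 2)          # calibrator identity: 1
#' fold_change(1, 2)          # ddCT = -1: one-cycle doubling, 2
#' @export
fold_change <- function(dct_treated, dct_calibrator) {
  stopifnot(all(is.finite(dct_treated)), all(is.finite(dct_calibrator)))
  2^-(dct_treated - dct_calibrator)
}

#' Relative expression by the 2^-ddCT method
#'
#' Full quantification pipeline for a qPCR CT table: technical replicates
#' are collapsed by arithmetic mean, each target gene is normalized to the
#' reference gene within the same (genotype, treatment, bio_rep) cell
#' (delta-CT), the same genotype's calibrator-treatment mean delta-CT is
#' subtracted (delta-delta-CT), and the fold change \eqn{2^{-\Delta\Delta CT}}
#' is reported per biological replicate.
#'
#' @param ct CT table (columns `genotype`, `treatment`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct`) containing the reference gene in every cell.
#' @param reference name of the reference (housekeeping) gene.
#' @param calibrator treatment level used as calibrator (control).
#' @return data frame with one row per (genotype, treatment, target gene,
#'   bio_rep): `dct`, `ddct`, `fold_change`.
#' @seealso [summarize_expression()] for per-cell means.
#' @export
relative_expression <- function(ct, reference = "alpha_tubulin",
                                calibrator = "control_90_95FC") {
  cc <- collapse_technical(ct)
  if (!reference %in% cc$gene)
    stop("reference gene '", reference, "' not present in the CT table",
         call. = FALSE)
  if (!calibrator %in% cc$treatment)
    stop("calibrator treatment '", calibrator, "' not present", call. = FALSE)
  ref <- cc[cc$gene == reference, ]
  tgt <- cc[cc$gene != reference, ]
  key <- function(d) paste(d$genotype, d$treatment, d$bio_rep, sep = "\r")
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  if (any(is.na(ref_ct))) {
    bad <- unique(paste0("(", tgt$genotype, ", ", tgt$treatment,
                         ", bio_rep ", tgt$bio_rep, ")")[is.na(ref_ct)])
    stop("reference gene missing for cell(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  tgt$dct <- tgt$ct - ref_ct
  # calibrator dCT: mean over the genotype's control biological replicates
  cal <- tgt[tgt$treatment == calibrator, ]
  calm <- stats::aggregate(cal["dct"], cal[c("genotype", "gene")], FUN = mean)
  ckey <- paste(tgt$genotype, tgt$gene, sep = "\r")
  cal_dct <- calm$dct[match(ckey, paste(calm$genotype, calm$gene, sep = "\r"))]
  if (any(is.na(cal_dct))) {
    bad <- unique(paste0("(", tgt$genotype, ", ", tgt$gene, ")")[is.na(cal_dct)])
    stop("no calibrator ('", calibrator, "') cell for: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  tgt$ddct <- tgt$dct - cal_dct
  tgt$fold_change <- 2^-tgt$ddct
  rownames(tgt) <- NULL
  tgt[c("genotype", "treatment", "gene", "bio_rep", "dct", "ddct",
        "fold_change")]
}

#' Per-cell expression summary
#'
#' Aggregates a per-biological-replicate fold-change table to one row per
#' (genotype, treatment, gene): the mean delta-delta-CT and the fold
#' change computed from it, \eqn{2^{-\overline{\Delta\Delta CT}}} (the
#' geometric-mean fold change, the natural average on the CT scale).  The
#' calibrator cell's summary fold change is exactly 1.
#'
#' @param rel output of [relative_expression()].
#' @return data frame with columns `genotype`, `treatment`, `gene`,
#'   `ddct`, `fold_change`.
#' @export
summarize_expression <- function(rel) {
  stopifnot(all(c("genotype", "treatment", "gene", "ddct") %in% names(rel)))
  agg <- stats::aggregate(rel["ddct"],
                          rel[c("genotype", "treatment", "gene")], FUN = mean)
  agg$fold_change <- 2^-agg$ddct
  agg[order(agg$genotype, agg$gene, agg$treatment), , drop = FALSE]
}

#' Primer amplification efficiency from a dilution series
#'
#' Fits CT against log10 template input by least squares and converts the
#' slope to an amplification efficiency \eqn{E = 10^{-1/slope} - 1}.
#' Perfect doubling per cycle gives a slope of about -3.322 and E = 1.
#'
#' @param dilution_log10 log10 of the template amounts (>= 3 points).
#' @param ct observed CT at each dilution.
#' @return list with `slope`, `efficiency` (fraction, 1 = 100%), and
#'   `r_squared` of the standard-curve fit.
#' @export
primer_efficiency <- function(dilution_log10, ct) {
  stopifnot(is.numeric(dilution_log10), is.numeric(ct),
            length(dilution_log10) == length(ct))
  if (length(ct) < 3)
    stop("need at least 3 dilution points", call. = FALSE)
  fit <- stats::lm(ct ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate dilution series: standard-curve slope is not negative",
         call. = FALSE)
  ss_tot <- sum((ct - mean(ct))^2)
  list(slope = slope,
       efficiency = 10^(-1 / slope) - 1,
       r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot)
}
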