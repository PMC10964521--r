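#' Yield-based stress-tolerance indices
#'
#' Computes the six classical yield-based drought-tolerance indices for a
#' set of genotypes evaluated under a non-stress (potential yield, `yp`)
#' and a stress (`ys`) environment:
#'
#' \describe{
#'   \item{TOL}{tolerance, \eqn{Yp - Ys}}
#'   \item{MP}{mean productivity, \eqn{(Yp + Ys)/2}}
#'   \item{GMP}{geometric mean productivity, \eqn{\sqrt{Yp \cdot Ys}}}
#'   \item{HM}{harmonic mean, \eqn{2 Yp Ys / (Yp + Ys)}}
#'   \item{STI}{stress tolerance index, \eqn{Yp Ys / \bar{Y}_p^2}}
#'   \item{SSI}{stress susceptibility index,
#'     \eqn{(1 - Ys/Yp)/SI} with stress intensity
#'     \eqn{SI = 1 - \bar{Y}_s/\bar{Y}_p}}
#' }
#'
#' Population means \eqn{\bar{Y}_p, \bar{Y}_s} default to the means of the
#' supplied table; a different trial summary (e.g. from the full trial when
#' indexing a subset) can be passed via `mean_yp` / `mean_ys`.
#'
#' @param yields data frame with columns `genotype`, `yp`, `ys`.
#'   `yp` must be strictly positive, `ys` non-negative; genotype ids unique.
#' @param mean_yp,mean_ys population means of `yp` and `ys`; default the
#'   column means of `yields`.
#' @return `yields` with columns `ssi`, `tol`, `mp`, `gmp`, `sti`, `hm`
#'   appended, one row per genotype, input order preserved.  The trial
#'   summary (`mean_yp`, `mean_ys`, `stress_intensity`) is attached as
#'   attribute `"trial"`.
#' @examples
#' y <- data.frame(genotype = 1:2, yp = c(4, 2), ys = c(1, 1))
#' stress_indices(y)
#' @seealso [sts_score()], [sts_table()]
#' @export
stress_indices <- function(yields, mean_yp = NULL, mean_ys = NULL) {
  yields <- validate_yields(yields)
  if (is.null(mean_yp)) mean_yp <- mean(yields$yp)
  if (is.null(mean_ys)) mean_ys <- mean(yields$ys)
  if (!is.finite(mean_yp) || mean_yp <= 0)
    stop("population mean of yp must be positive", call. = FALSE)
  si <- 1 - mean_ys / mean_yp
  if (si == 0)
    stop("stress intensity is zero (mean ys equals mean yp): SSI undefined ",
         "for this trial", call. = FALSE)
  yp <- yields$yp
  ys <- yields$ys
  out <- yields
  out$ssi <- (1 - ys / yp) / si
  out$tol <- yp - ys
  out$mp  <- (yp + ys) / 2
  out$gmp <- sqrt(yp * ys)
  out$sti <- yp * ys / mean_yp^2
  out$hm  <- 2 * yp * ys / (yp + ys)
  attr(out, "trial") <- list(mean_yp = mean_yp, mean_ys = mean_ys,
                             stress_intensity = si)
  out
}

validate_yields <- function(yields) {
  stopifnot(is.data.frame(yields))
  need <- c("genotype", "yp", "ys")
  miss <- setdiff(need, names(yields))
  if (length(miss))
    stop("yield table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(yields$genotype))
    stop("duplicate genotype id(s): ",
         paste(unique(yields$genotype[duplicated(yields$genotype)]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(yields$yp) | yields$yp <= 0)
  if (length(bad))
    stop("non-positive yp for genotype(s): ",
         paste(yields$genotype[bad], collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(yields$ys) | yields$ys < 0)
  if (length(bad))
    stop("negative or non-finite ys for genotype(s): ",
         paste(yields$genotype[bad], collapse = ", "), call. = FALSE)
  yields
}

#' Finlay-Wilkinson sensitivity slope
#'
#' Least-squares slope of each genotype's yield on the environment mean
#' yields — the classical regression measure of a genotype's sensitivity
#' to environment quality.  A genotype tracking the environment average
#' one-to-one has slope 1; a flat (stable) genotype has slope 0.  With
#' exactly two environments the slope reduces to the closed form
#' \eqn{b_i = (y_{i1} - y_{i2}) / (\bar{Y}_1 - \bar{Y}_2)}.
#'
#' @param yields data frame: column `genotype` plus one numeric column per
#'   environment (at least two), all yields positive.
#' @return numeric vector of slopes, one per genotype, named by genotype.
#' @examples
#' y <- data.frame(genotype = 1:2, yp = c(4, 3), ys = c(2, 3))
#' fw_slope(y)
#' @export
fw_slope <- function(yields) {
  stopifnot(is.data.frame(yields), "genotype" %in% names(yields))
  env_cols <- setdiff(names(yields), "genotype")
  if (length(env_cols) < 2)
    stop("need at least two environment columns", call. = FALSE)
  Y <- as.matrix(yields[env_cols])
  if (!is.numeric(Y) || any(!is.finite(Y)))
    stop("environment columns must be finite numerics", call. = FALSE)
  em <- colMeans(Y)
  sxx <- sum((em - mean(em))^2)
  if (sxx == 0)
    stop("environment means are all equal: sensitivity slope undefined",
         call. = FALSE)
  xc <- em - mean(em)
  b <- as.vector((Y - rowMeans(Y)) %*% xc) / sxx
  names(b) <- yields$genotype
  b
}

#' Composite stress-tolerance score (STS)
#'
#' Combines the six tolerance indices and the sensitivity slope into a
#' single selection score:
#' \deqn{STS = GMP + STI + HM + MP - TOL - SSI - b}
#' Productivity-type indices (higher is better under stress) enter with a
#' positive sign; loss/sensitivity measures (TOL, SSI, b) are subtracted.
#' The sum is taken on the raw index values; set `standardize = TRUE` to
#' z-score each component across genotypes first (changes the weighting,
#' not the spirit of the score).
#'
#' @param indices data frame with columns `ssi`, `tol`, `mp`, `gmp`,
#'   `sti`, `hm` (as from [stress_indices()]) and `b`.
#' @param standardize z-score each component before summing (default off).
#' @return `indices` with an `sts` column appended.
#' @export
sts_score <- function(indices, standardize = FALSE) {
  need <- c("ssi", "tol", "mp", "gmp", "sti", "hm", "b")
  miss <- setdiff(need, names(indices))
  if (length(miss))
    stop("index table is missing component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(indices[need])
  if (any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)
    stop("non-finite index component(s) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (standardize) X <- scale(X)
  indices$sts <- X[, "gmp"] + X[, "sti"] + X[, "hm"] + X[, "mp"] -
    X[, "tol"] - X[, "ssi"] - X[, "b"]
  indices
}

#' Rank genotypes by STS
#'
#' Rank 1 is the largest STS (most tolerant), rank n the smallest.  Ties
#' are broken by ascending genotype id so the ranking is deterministic and
#' invariant to the input row order.
#'
#' @param indices data frame with columns `genotype` and `sts`.
#' @return `indices` with an integer `rank` column appended.
#' @export
rank_genotypes <- function(indices) {
  stopifnot(is.data.frame(indices))
  if (nrow(indices) == 0) {
    indices$rank <- integer(0)
    return(indices)
  }
  if (!all(c("genotype", "sts") %in% names(indices)))
    stop("need columns genotype and sts", call. = FALSE)
  if (any(!is.finite(indices$sts)))
    stop("sts must be filled and finite for all genotypes", call. = FALSE)
  ord <- order(-indices$sts, indices$genotype)
  rk <- integer(nrow(indices))
  rk[ord] <- seq_len(nrow(indices))
  indices$rank <- rk
  indices
}

#' Extreme (tolerant / sensitive) genotypes
#'
#' The top-`k_tolerant` genotypes by rank (best STS first) and the
#' bottom-`k_sensitive` (worst STS first).
#'
#' @param indices ranked index table (see [rank_genotypes()]).
#' @param k_tolerant,k_sensitive how many genotypes to take from each end.
#' @return list with elements `tolerant` and `sensitive`, each a vector of
#'   genotype ids.
#' @export
classify_extremes <- function(indices, k_tolerant = 9, k_sensitive = 11) {
  stopifnot(is.data.frame(indices), "rank" %in% names(indices))
  n <- nrow(indices)
  if (k_tolerant < 0 || k_sensitive < 0 || k_tolerant + k_sensitive > n)
    stop("k_tolerant + k_sensitive must be between 0 and the number of ",
         "genotypes (", n, ")", call. = FALSE)
  byrank <- indices$genotype[order(indices$rank)]
  list(
    tolerant  = if (k_tolerant > 0) byrank[seq_len(k_tolerant)] else byrank[0],
    sensitive = if (k_sensitive > 0) rev(byrank)[seq_len(k_sensitive)] else byrank[0]
  )
}

#' Full index-and-ranking pipeline for a two-environment trial
#'
#' Convenience wrapper: computes the six indices, the two-environment
#' Finlay-Wilkinson slope, the STS score and the genotype ranks in one
#' call.
#'
#' @inheritParams stress_indices
#' @inheritParams sts_score
#' @return data frame with columns `genotype`, `yp`, `ys`, `ssi`, `tol`,
#'   `mp`, `gmp`, `sti`, `hm`, `b`, `sts`, `rank`.
#' @examples
#' set.seed(1)
#' y <- data.frame(genotype = 1:6, yp = runif(6, 2, 6), ys = runif(6, 1, 3))
#' sts_table(y)
#' @export
sts_table <- function(yields, standardize = FALSE) {
  idx <- stress_indices(yields)
  idx$b <- fw_slope(yields[c("genotype", "yp", "ys")])
  idx <- sts_score(idx, standardize = standardize)
  rank_genotypes(idx)
}
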