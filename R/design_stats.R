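#' Two-factor completely randomized factorial ANOVA
#'
#' Closed-form fixed-effects decomposition for a balanced genotype x
#' stress-level factorial in a completely randomized design (CRD):
#' sums of squares for Genotype (G), Stress (S), their interaction
#' (G x S) and Error, with F statistics against the error mean square,
#' p-values from the F distribution, and the trial coefficient of
#' variation CV% = 100 sqrt(MSE) / grand mean.
#'
#' The design must be balanced (every genotype x stress cell observed
#' with the same number of replicates, r >= 2); an unbalanced layout is
#' an error rather than a silent switch to a different sum-of-squares
#' type.
#'
#' @param observations data frame with columns `genotype`, `stress_level`,
#'   `replicate`, `value` (and optionally `trait`; see `trait`).
#' @param trait if `observations` carries a `trait` column, which trait to
#'   analyse (required when more than one is present).
#' @return object of class `"drought_anova"`: a list with `table` (data
#'   frame: source, df, ss, ms, f, p, stars), `cv_percent`, `grand_mean`,
#'   `ms_error`, `df_error`, `r` (replicates per cell), and `cell_means`.
#' @examples
#' d <- sim_trait_matrix(sim_config(seed = 1))
#' anova_crd2(d, trait = "chl_a")
#' @export
anova_crd2 <- function(observations, trait = NULL) {
  stopifnot(is.data.frame(observations))
  need <- c("genotype", "stress_level", "replicate", "value")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("trait" %in% names(observations)) {
    traits <- unique(observations$trait)
    if (is.null(trait)) {
      if (length(traits) > 1)
        stop("multiple traits present; choose one via `trait`", call. = FALSE)
      trait <- traits
    }
    observations <- observations[observations$trait == trait, , drop = FALSE]
    if (nrow(observations) == 0)
      stop("no observations for trait '", trait, "'", call. = FALSE)
  }
  y <- observations$value
  if (any(!is.finite(y)))
    stop("non-finite trait value(s)", call. = FALSE)
  G <- factor(observations$genotype)
  S <- factor(observations$stress_level)
  g <- nlevels(G)
  s <- nlevels(S)
  counts <- table(G, S)
  r <- counts[1]
  if (any(counts != r))
    stop("unbalanced layout: every genotype x stress cell must have the ",
         "same number of replicates", call. = FALSE)
  if (r < 2)
    stop("need at least 2 replicates per cell for an error term",
         call. = FALSE)

  grand <- mean(y)
  cell <- tapply(y, list(G, S), mean)
  gm <- rowMeans(cell)
  sm <- colMeans(cell)
  ss_g  <- s * r * sum((gm - grand)^2)
  ss_s  <- g * r * sum((sm - grand)^2)
  ss_gs <- r * sum((cell - outer(gm, rep(1, s)) -
                      outer(rep(1, g), sm) + grand)^2)
  fit <- cell[cbind(as.integer(G), as.integer(S))]
  ss_e <- sum((y - fit)^2)

  df <- c(g - 1L, s - 1L, (g - 1L) * (s - 1L), g * s * (r - 1L))
  ss <- c(ss_g, ss_s, ss_gs, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)

  tab <- data.frame(
    source = c("Genotype (G)", "Stress (S)", "G x S", "Error"),
    df = df, ss = ss, ms = ms, f = f, p = p,
    stars = c(vapply(p[1:3], function(pp)
      if (is.finite(pp)) sig_stars(pp) else "", ""), ""),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = tab,
    cv_percent = cv_percent(ms[4], grand),
    grand_mean = grand,
    ms_error = ms[4],
    df_error = df[4],
    r = as.integer(r),
    cell_means = cell,
    trait = trait
  ), class = "drought_anova")
}

#' @export
print.drought_anova <- function(x, ...) {
  if (!is.null(x$trait)) cat("Trait:", x$trait, "\n")
  cat("Two-factor CRD factorial ANOVA (", nrow(x$cell_means), " genotypes x ",
      ncol(x$cell_means), " stress levels, r = ", x$r, ")\n\n", sep = "")
  tab <- x$table
  tab$ss <- signif(tab$ss, 6)
  tab$ms <- signif(tab$ms, 6)
  tab$f <- signif(tab$f, 5)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE, na.print = "")
  cat(sprintf("\nCV%% = %.2f%%   grand mean = %.4g\n",
              x$cv_percent, x$grand_mean))
  invisible(x)
}

#' Coefficient of variation of an ANOVA
#'
#' \eqn{CV\% = 100 \sqrt{MSE} / |\bar{y}|}, the residual standard
#' deviation as a percentage of the grand mean.
#'
#' @param ms_error error mean square (>= 0).
#' @param grand_mean trial grand mean (nonzero).
#' @return CV as a percentage.
#' @export
cv_percent <- function(ms_error, grand_mean) {
  stopifnot(is.finite(ms_error), ms_error >= 0)
  if (!is.finite(grand_mean) || grand_mean == 0)
    stop("CV% undefined: grand mean is zero", call. = FALSE)
  100 * sqrt(ms_error) / abs(grand_mean)
}

#' Significance markers
#'
#' The conventional table annotation: `"**"` for p <= 0.01, `"*"` for
#' p <= 0.05, `""` otherwise.
#'
#' @param p_value p-value in [0, 1].
#' @return character marker.
#' @export
sig_stars <- function(p_value) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1)
    stop("p-value must lie in [0, 1]", call. = FALSE)
  if (p_value <= 0.01) "**" else if (p_value <= 0.05) "*" else ""
}

#' Duncan's multiple range test
#'
#' Stepwise comparison of treatment means using span-dependent least
#' significant ranges.  Means are sorted in decreasing order; two means
#' spanning p positions differ when their gap exceeds
#' \deqn{R_p = q(\alpha_p;\, p,\, df_E)\,\sqrt{MSE/r},\qquad
#'       \alpha_p = 1 - (1 - \alpha)^{p-1}}
#' where q is the studentized-range quantile (Duncan's protection levels;
#' computed from the distribution, no lookup tables).  Letters are
#' assigned by the standard underlining algorithm: each maximal run of
#' mutually non-significant means shares a letter.
#'
#' @param means named numeric vector of treatment (or treatment-
#'   combination) means.
#' @param ms_error,df_error error mean square (positive) and its degrees
#'   of freedom from the ANOVA.
#' @param r number of observations per mean.
#' @param alpha significance level (default 0.05).
#' @return object of class `"duncan_groups"`: data frame `groups` with
#'   columns `treatment`, `mean`, `letters` (means in decreasing order),
#'   plus the least significant ranges `lsr` for spans 2..k.
#' @examples
#' a <- anova_crd2(sim_trait_matrix(sim_config(seed = 2)), trait = "chl_a")
#' m <- tapply_cell_means(a)
#' duncan_groups(m, a$ms_error, a$df_error, a$r)
#' @export
duncan_groups <- function(means, ms_error, df_error, r, alpha = 0.05) {
  stopifnot(is.numeric(means), length(means) >= 1, all(is.finite(means)))
  if (!is.finite(ms_error) || ms_error <= 0)
    stop("MSE must be positive", call. = FALSE)
  if (df_error < 1) stop("df_error must be >= 1", call. = FALSE)
  k <- length(means)
  if (is.null(names(means))) names(means) <- seq_len(k)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(ms_error / r)
  lsr <- if (k >= 2) {
    p <- 2:k
    stats::qtukey((1 - alpha)^(p - 1), p, df_error,
                  lower.tail = TRUE) * se
  } else numeric(0)
  names(lsr) <- if (k >= 2) paste0("p", 2:k) else character(0)

  # significant difference between sorted positions i < j (Duncan rule:
  # gap exceeds the range for its span; a pair inside a non-significant
  # spanning range is never declared different)
  sig <- function(i, j) {
    span <- j - i + 1
    if (m[i] - m[j] <= lsr[span - 1]) return(FALSE)
    # protection: any enclosing span that is itself non-significant
    # shields the pair
    for (a in seq_len(i)) for (b in j:k) {
      if (a == i && b == j) next
      if (m[a] - m[b] <= lsr[b - a]) return(FALSE)
    }
    TRUE
  }

  letters_out <- rep("", k)
  if (k == 1) {
    letters_out <- "a"
  } else {
    # under the protection rule non-significance is an interval property
    # on the sorted means, so each letter is a maximal run [i, end(i)]
    # with end(i) = largest j such that (i, j) is not significant
    run_end <- function(i) {
      j <- i
      while (j < k && !sig(i, j + 1)) j <- j + 1
      j
    }
    runs <- list()
    i <- 1
    repeat {
      e <- run_end(i)
      runs[[length(runs) + 1]] <- c(i, e)
      if (e == k) break
      i <- i + 1
      while (i <= k && run_end(i) == e) i <- i + 1  # skip contained runs
    }
    for (u in seq_along(runs)) {
      rng <- runs[[u]][1]:runs[[u]][2]
      letters_out[rng] <- paste0(letters_out[rng], letters[u])
    }
  }
  structure(list(
    groups = data.frame(treatment = names(m), mean = unname(m),
                        letters = letters_out, stringsAsFactors = FALSE),
    lsr = lsr, alpha = alpha
  ), class = "duncan_groups")
}

#' @export
print.duncan_groups <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", x$alpha, ")\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Cell means of a fitted factorial ANOVA as a named vector
#'
#' Flattens the genotype x stress cell-mean matrix of a
#' [anova_crd2()] fit into the named vector [duncan_groups()] expects,
#' names `genotype:stress_level`.
#'
#' @param fit a `"drought_anova"` object.
#' @return named numeric vector of treatment-combination means.
#' @export
tapply_cell_means <- function(fit) {
  stopifnot(inherits(fit, "drought_anova"))
  cm <- fit$cell_means
  out <- as.vector(cm)
  names(out) <- as.vector(outer(rownames(cm), colnames(cm), paste, sep = ":"))
  out
}
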