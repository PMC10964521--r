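# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

oracle_indices <- function(yields, mean_yp, mean_ys) {
  si <- 1 - mean_ys / mean_yp
  out <- data.frame(genotype = yields$genotype, ssi = NA_real_,
                    tol = NA_real_, mp = NA_real_, gmp = NA_real_,
                    sti = NA_real_, hm = NA_real_)
  for (i in seq_len(nrow(yields))) {
    yp <- yields$yp[i]; ys <- yields$ys[i]
    out$ssi[i] <- (1 - ys / yp) / si
    out$tol[i] <- yp - ys
    out$mp[i]  <- (yp + ys) / 2
    out$gmp[i] <- sqrt(yp * ys)
    out$sti[i] <- (yp * ys) / (mean_yp * mean_yp)
    out$hm[i]  <- (2 * yp * ys) / (yp + ys)
  }
  out
}

# least-squares slope via explicit normal equations, one genotype at a time
oracle_slope <- function(Y) {
  x <- colMeans(Y)
  b <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    b[i] <- sxy / sxx
  }
  b
}

# two-factor balanced CRD decomposition by explicit loops over levels
oracle_anova <- function(d) {
  gl <- sort(unique(d$genotype)); sl <- sort(unique(d$stress_level))
  g <- length(gl); s <- length(sl)
  r <- nrow(d) / (g * s)
  grand <- mean(d$value)
  ss_g <- 0
  for (gi in gl) {
    m <- mean(d$value[d$genotype == gi])
    ss_g <- ss_g + s * r * (m - grand)^2
  }
  ss_s <- 0
  for (si in sl) {
    m <- mean(d$value[d$stress_level == si])
    ss_s <- ss_s + g * r * (m - grand)^2
  }
  ss_gs <- 0; ss_e <- 0
  for (gi in gl) for (si in sl) {
    sub <- d$value[d$genotype == gi & d$stress_level == si]
    cm <- mean(sub)
    gm <- mean(d$value[d$genotype == gi])
    sm <- mean(d$value[d$stress_level == si])
    ss_gs <- ss_gs + r * (cm - gm - sm + grand)^2
    ss_e <- ss_e + sum((sub - cm)^2)
  }
  df <- c(g - 1, s - 1, (g - 1) * (s - 1), g * s * (r - 1))
  ms <- c(ss_g, ss_s, ss_gs, ss_e) / df
  list(ss = c(ss_g, ss_s, ss_gs, ss_e), df = df, ms = ms,
       f = ms[1:3] / ms[4],
       cv = 100 * sqrt(ms[4]) / abs(grand))
}

# Duncan oracle: "share a letter" matrix from exhaustive enclosing-pair
# checks; pair (i, j) of the sorted means is non-significant iff any
# enclosing span (a, b) has gap <= its least significant range
oracle_duncan_share <- function(means, ms_error, df_error, r, alpha = 0.05) {
  m <- sort(means, decreasing = TRUE)
  k <- length(m)
  lsr <- function(span)
    qtukey((1 - alpha)^(span - 1), span, df_error) * sqrt(ms_error / r)
  share <- matrix(FALSE, k, k)
  diag(share) <- TRUE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ns <- FALSE
    for (a in 1:i) for (b in j:k) {
      if (m[a] - m[b] <= lsr(b - a + 1)) ns <- TRUE
    }
    share[i, j] <- share[j, i] <- ns
  }
  share
}

# share-a-letter matrix implied by a duncan_groups() result
share_from_letters <- function(dg) {
  lt <- strsplit(dg$groups$letters, "")
  k <- length(lt)
  share <- matrix(FALSE, k, k)
  for (i in 1:k) for (j in 1:k)
    share[i, j] <- length(intersect(lt[[i]], lt[[j]])) > 0
  share
}

random_yields <- function(n) {
  data.frame(genotype = seq_len(n),
             yp = runif(n, 1, 10),
             ys = runif(n, 0.2, 8))
}

random_balanced_design <- function(g = 3, s = 3, r = 3, sd = 1) {
  d <- expand.grid(genotype = paste0("g", seq_len(g)),
                   stress_level = paste0("s", seq_len(s)),
                   replicate = seq_len(r),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), 10, sd)
  d
}
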