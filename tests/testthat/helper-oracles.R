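# Independent oracles used to cross-check package routines. These are kept
# deliberately plain (loops, explicit arithmetic) and separate from the
# implementation paths they verify.

# Brute-force FWHM: scan the peak-normalized template on a fine wavelength
# grid and measure the half-maximum crossings nearest the peak.
oracle_fwhm <- function(spec, resolution = 0.001) {
  wl <- seq(spec$lambda_max - 150, min(800, spec$lambda_max + 200),
            by = resolution)
  v <- evaluate_template(spec, wl)
  ipk <- which.max(v)
  left <- ipk
  while (left > 1 && v[left] >= 0.5) left <- left - 1
  right <- ipk
  while (right < length(v) && v[right] >= 0.5) right <- right + 1
  wl[right] - wl[left]
}

# Brute-force template fit: exhaustive SSE scan over a fine lambda-max grid
# with the same fixed limb-window rule (window set once from the peak
# estimate), implemented as a straightforward loop.
oracle_fit_argmin <- function(norm, chromophore, center, half_width = 30,
                              resolution = 0.01) {
  cand <- seq(center - half_width, center + half_width, by = resolution)
  cand <- cand[cand >= 350 & cand <= 650]
  ctr <- min(max(center, 350), 650)
  tv0 <- evaluate_template(template_spec(chromophore, ctr), norm$wavelength)
  keep <- norm$wavelength > center & tv0 >= 0.10 & tv0 <= 0.90
  wlk <- norm$wavelength[keep]
  abk <- norm$absorbance[keep]
  best_sse <- Inf
  best_lm <- NA_real_
  for (lm in cand) {
    tv <- evaluate_template(template_spec(chromophore, lm), wlk)
    sse <- sum((abk - tv)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_lm <- lm
    }
  }
  best_lm
}

# Spreadsheet-style dn/dc: explicit per-residue rows, mass fractions,
# Lorentz-Lorenz mixing and the Heller relation, over the same shipped
# residue table.
oracle_dndc <- function(sequence, solvent_n = 1.3340) {
  tab <- utils::read.delim(
    system.file("extdata", "residue_refractivity.tsv", package = "visadapt"),
    comment.char = "#")
  rownames(tab) <- tab$residue
  n_ref <- 1.3340
  counts <- table(strsplit(sequence, "")[[1]])
  rows <- tab[names(counts), ]
  mass <- as.numeric(counts) * rows$mass_residue
  w <- mass / sum(mass)
  k <- 2 * rows$dndc / (3 * n_ref * rows$vbar)
  n_i <- n_ref * sqrt((1 + 2 * k) / (1 - k))
  r_i <- rows$vbar * (n_i^2 - 1) / (n_i^2 + 2)
  vbar <- sum(w * rows$vbar)
  q <- sum(w * r_i) / vbar
  n_p <- sqrt((1 + 2 * q) / (1 - q))
  m <- n_p / solvent_n
  1.5 * solvent_n * vbar * (m^2 - 1) / (m^2 + 2)
}

# Step-by-step TMM reference: upper-quartile reference selection, pairwise
# M/A with zero removal, double trimming by rank, precision weighting,
# geometric-mean rescaling -- written as an explicit per-sample loop.
oracle_tmm <- function(x, m_trim = 0.30, a_trim = 0.05) {
  lib <- colSums(x)
  uq <- vapply(seq_len(ncol(x)),
               function(j) unname(stats::quantile(x[, j] / lib[j], 0.75)), 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    keep <- x[, j] > 0 & x[, ref] > 0
    po <- x[keep, j] / lib[j]
    pr <- x[keep, ref] / lib[ref]
    M <- log2(po / pr)
    A <- 0.5 * log2(po * pr)
    w <- 1 / ((lib[j] - x[keep, j]) / (lib[j] * x[keep, j]) +
                (lib[ref] - x[keep, ref]) / (lib[ref] * x[keep, ref]))
    if (max(abs(M)) < 1e-6) {
      f[j] <- 1
      next
    }
    n <- length(M)
    lo_m <- floor(n * m_trim) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * a_trim) + 1
    hi_a <- n + 1 - lo_a
    sel <- rank(M) >= lo_m & rank(M) <= hi_m &
      rank(A) >= lo_a & rank(A) <= hi_a
    f[j] <- 2^(sum(M[sel] * w[sel]) / sum(w[sel]))
  }
  f / exp(mean(log(f)))
}

# Brute-force unconditional exact p-value: enumerate outcomes, scan the
# nuisance proportion on a very fine grid.
oracle_exact_p <- function(x1, n1, x2, n2, step = 1e-5) {
  zfun <- function(y1, y2) {
    ph <- (y1 + y2) / (n1 + n2)
    se <- sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    ifelse(se > 0, (y1 / n1 - y2 / n2) / se, 0)
  }
  ys <- expand.grid(y1 = 0:n1, y2 = 0:n2)
  z <- zfun(ys$y1, ys$y2)
  reg <- abs(z) >= abs(zfun(x1, x2)) - 1e-12
  grid <- seq(step, 1 - step, by = step)
  d1 <- vapply(0:n1, function(y) stats::dbinom(y, n1, grid),
               numeric(length(grid)))
  d2 <- vapply(0:n2, function(y) stats::dbinom(y, n2, grid),
               numeric(length(grid)))
  p <- numeric(length(grid))
  for (i in which(reg)) {
    p <- p + d1[, ys$y1[i] + 1] * d2[, ys$y2[i] + 1]
  }
  min(1, max(p))
}

# Small helpers for building fixture files in tests.
write_spectrum_file <- function(wl, ab, path = tempfile(fileext = ".tsv"),
                                header = TRUE, sep = "\t") {
  lines <- paste(wl, ab, sep = sep)
  if (header) lines <- c(paste("wavelength_nm", "absorbance", sep = sep), lines)
  writeLines(lines, path)
  path
}
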