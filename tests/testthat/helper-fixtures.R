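# small, fast phantom variants used throughout the suite

small_spec <- function(n_vertebrae = 3, ...) {
  phantom_spec(grid_shape = c(44, 44, as.integer(n_vertebrae * 12 + 4)),
               spacing_mm = c(1, 1, 1.5),
               n_vertebrae = n_vertebrae, ...)
}

# a five-vertebra phantom tall enough for the default BMD targets (3:5)
bmd_spec <- function(...) small_spec(n_vertebrae = 5, ...)

# random compartment-fraction array triplet on a grid, mineral kept < cap
random_fractions <- function(dims, cap_mineral = 0.8, seed = 1) {
  set.seed(seed)
  n <- prod(dims)
  m <- runif(n, 0, cap_mineral)
  s <- runif(n) * (1 - m)
  f <- 1 - m - s
  list(fat = array(f, dims), soft = array(s, dims), mineral = array(m, dims))
}

# forward-model a noiseless spectral volume from fraction arrays
forward_volume <- function(fr, basis = material_basis(), spacing = c(1, 1, 1)) {
  hu <- function(energy) {
    co <- switch(energy,
                 conventional = c(basis$hu_fat_conv, basis$hu_soft_conv, basis$hu_mineral_conv),
                 low = c(basis$hu_fat_low, basis$hu_soft_low, basis$hu_mineral_low),
                 high = c(basis$hu_fat_high, basis$hu_soft_high, basis$hu_mineral_high))
    fr$fat * co[1] + fr$soft * co[2] + fr$mineral * co[3]
  }
  spectral_volume(hu("conventional"), hu("low"), hu("high"), spacing)
}

# brute-force erosion oracle: voxel kept iff every voxel center within the
# physical radius lies inside the mask
erode_bruteforce <- function(mask, radius_mm, spacing_mm) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    keep <- TRUE
    nx <- floor(radius_mm / spacing_mm + 1e-9)
    for (dx in -nx[1]:nx[1]) for (dy in -nx[2]:nx[2]) for (dz in -nx[3]:nx[3]) {
      if ((dx * spacing_mm[1])^2 + (dy * spacing_mm[2])^2 + (dz * spacing_mm[3])^2 >
          radius_mm^2 + 1e-9) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask[ii, jj, kk]) { keep <- FALSE; break }
    }
    out[i, j, k] <- keep
  }
  out
}

# latent-logit cohort simulator: infiltration generated so that the
# compressed-logit response is exactly linear-Gaussian in the predictors
simulate_cohort_df <- function(b, n, seed, sd = 1) {
  set.seed(seed)
  x <- rnorm(n); bmd <- rnorm(n, 97, 15)
  lat <- b * x + rnorm(n, 0, sd)
  infl <- pmin(pmax((plogis(lat) * n - 0.5) / (n - 1), 0), 1)
  tibble::tibble(infiltration = infl, non_fatty_percent = x, bmd_mg_ml = bmd)
}

# brute-force Youden oracle: exhaustive enumeration over all candidate
# thresholds with the midpoint convention and the specificity tie-break
youden_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- sort(unique(scores))
  thr <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in thr) {
    sens <- mean(pos > th); spec <- mean(neg <= th)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && th > best$th)))) {
      best <- list(th = th, j = j, sens = sens, spec = spec)
    }
  }
  best
}
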