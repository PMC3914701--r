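# Independent brute-force oracles, kept free of the package's compiled paths.

# all-patch weighted-vote label fusion on small same-grid volumes.
# Semantics: for every target voxel, every in-bounds candidate centre within
# the search window contributes weight
#   exp(-SSD/(h^2 n)) * exp(-|offset_mm|^2 / s^2)
# to the label at its centre; fused label is the weight-argmax with ties
# toward the lower code.
fuse_labels_bruteforce <- function(target, atlas_intens, atlas_labs, params) {
  d <- dim(target$data)
  sp <- target$spacing
  pr <- pmax(1L, as.integer(floor(params$patch_size_mm / (2 * sp))))
  sr <- pmax(1L, as.integer(floor(params$search_radius_mm / sp)))
  h2 <- params$similarity_bandwidth^2
  s2 <- params$spatial_bandwidth^2
  out <- array(0L, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    wlab <- numeric(4)
    for (a in seq_along(atlas_intens)) {
      for (dz in -sr[3]:sr[3]) for (dy in -sr[2]:sr[2]) for (dx in -sr[1]:sr[1]) {
        ci <- i + dx; cj <- j + dy; ck <- k + dz
        if (ci < 1 || cj < 1 || ck < 1 || ci > d[1] || cj > d[2] || ck > d[3])
          next
        # patch offsets where BOTH the target patch (around ijk) and the
        # atlas patch (around the candidate centre) are in bounds
        olo <- pmax(-pr, pmax(1 - c(i, j, k), 1 - c(ci, cj, ck)))
        ohi <- pmin(pr, pmin(d - c(i, j, k), d - c(ci, cj, ck)))
        if (any(olo > ohi)) next
        tp <- target$data[(i + olo[1]):(i + ohi[1]),
                          (j + olo[2]):(j + ohi[2]),
                          (k + olo[3]):(k + ohi[3]), drop = FALSE]
        ap <- atlas_intens[[a]][(ci + olo[1]):(ci + ohi[1]),
                                (cj + olo[2]):(cj + ohi[2]),
                                (ck + olo[3]):(ck + ohi[3]), drop = FALSE]
        n <- length(tp)
        ssd <- sum((tp - ap)^2)
        off2 <- sum((c(dx, dy, dz) * sp)^2)
        w <- exp(-ssd / (h2 * n)) * exp(-off2 / s2)
        lab <- atlas_labs[[a]][ci, cj, ck]
        wlab[lab + 1] <- wlab[lab + 1] + w
      }
    }
    out[i, j, k] <- which.max(wlab) - 1L  # which.max takes first (lower code)
  }
  out
}

# exact two-sided signed-rank p-value by enumerating all sign patterns
wilcoxon_exact_enum <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^n
  vs <- vapply(0:(total - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  # two-sided: fold around the mean n(n+1)/4
  mu <- n * (n + 1) / 4
  dev <- abs(v_obs - mu)
  mean(abs(vs - mu) >= dev - 1e-12)
}

# ICC(2,1) from aov() mean squares (route independent of the implementation)
icc_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   occ = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + occ, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
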