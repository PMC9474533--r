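# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (flood fill instead of union-find, explicit
# sums of squares instead of library calls) so agreement is evidence, not
# tautology.

# Flood-fill connected-component labelling of a logical 3D array.
flood_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0) next
    nxt <- nxt + 1L
    queue <- arrayInd(start, d)
    labels[start] <- nxt
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, , drop = FALSE]
        if (any(w < 1) || any(w > d)) next
        if (mask[w] && labels[w] == 0) {
          labels[w] <- nxt
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

# Brute-force TFCE: explicit per-threshold labelling and summation.
tfce_oracle <- function(m, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  enh_pos <- function(v) {
    out <- array(0, dim(v))
    vmax <- max(v)
    if (vmax <= 0) return(out)
    nsteps <- floor(vmax / dh + 1e-9)
    for (k in seq_len(nsteps)) {
      h <- k * dh
      labs <- flood_label(v >= h, connectivity)
      if (max(labs) == 0) next
      sizes <- tabulate(labs[labs > 0])
      sel <- labs > 0
      out[sel] <- out[sel] + sizes[labs[sel]]^E * h^H * dh
    }
    out
  }
  if (is.null(dh)) dh <- max(abs(m)) / 100
  enh_pos(pmax(m, 0)) - enh_pos(pmax(-m, 0))
}

# Pooled-variance two-sample t by hand.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tv <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tv, dof = n1 + n2 - 2,
       p = 2 * pt(-abs(tv), n1 + n2 - 2))
}

# One-sample t on difference scores.
paired_t_oracle <- function(x, y) {
  d <- x - y; n <- length(d)
  tv <- mean(d) / (sd(d) / sqrt(n))
  list(t = tv, dof = n - 1, p = 2 * pt(-abs(tv), n - 1))
}

# Repeated-measures one-way F from the explicit sum-of-squares partition.
ranova_oracle <- function(wide) {
  n <- nrow(wide); k <- ncol(wide); grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_err <- sum((wide - grand)^2) - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(f = f, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# Pearson correlation from the covariance formula.
pearson_oracle <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tv, p = 2 * pt(-abs(tv), n - 2))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Small standard phantom + subject used by several files.
small_acq <- function(grid = c(12, 12, 12)) acq_params(grid_shape = grid)

noiseless_subject <- function(cvr_gm = 0.105, cvr_wm = 0.068, grid = c(12, 12, 12),
                              lesions = 0, lesion_cvr = NULL, seed = 1,
                              noise_sd = 0, bold_seed = seed + 1) {
  acq <- small_acq(grid)
  ph <- make_phantom(grid, lesion_count = lesions, seed = seed)
  tm <- make_truth_maps(ph, cvr_gm, cvr_wm, lesion_cvr = lesion_cvr,
                        noise_sd = noise_sd)
  tr <- make_capno_trace(noise_sd = 0)
  reg <- build_regressor(tr, acq)
  bold <- make_bold(ph, tm, reg, acq, seed = bold_seed)
  list(acq = acq, phantom = ph, truth = tm, trace = tr, regressor = reg,
       bold = bold,
       prob_maps = list(gm = ph$prob_gm, wm = ph$prob_wm, csf = ph$prob_csf))
}
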