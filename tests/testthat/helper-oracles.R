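# Shared fixtures and independent oracles for the test suite.

# Dense parametric closed curves ------------------------------------------

circle_points <- function(n = 512, r = 1, center = c(0, 0), start = 0) {
  th <- start + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

ellipse_points <- function(n = 2048, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(a * cos(th), b * sin(th))
}

# Random star-shaped simple polygon: smooth random radial profile r(phi) > 0.
random_star_contour <- function(n = 256, n_modes = 6, min_r = 0.5) {
  amp <- stats::rnorm(n_modes, 0, 0.3 / seq_len(n_modes))
  phs <- stats::runif(n_modes, 0, 2 * pi)
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  r <- 1 + Reduce(`+`, lapply(seq_len(n_modes), function(k)
    amp[k] * cos(k * phi + phs[k])))
  r <- pmax(r, min_r)
  cbind(r * cos(phi), r * sin(phi))
}

# Apply a similarity transform plus start-index shift to a contour.
similarity_transform <- function(xy, angle, scale, shift, translation) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  out <- sweep(t(R %*% t(xy)) * scale, 2L, translation, "+")
  n <- nrow(out)
  shift <- ((shift - 1L) %% n) + 1L
  out[c(shift:n, seq_len(shift - 1L))[seq_len(n)], , drop = FALSE]
}

# Independent EFD oracle: direct trapezoidal quadrature of the Fourier
# integrals over the chain parameter, on an edge-subdivided polygon.  This
# shares no code with efd_decompose (which uses the per-segment closed
# form).
efd_quadrature_oracle <- function(xy, H, subdiv = 20L) {
  # subdivide each edge
  n <- nrow(xy)
  closed <- rbind(xy, xy[1L, , drop = FALSE])
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- seq(0, 1, length.out = subdiv + 1L)[-(subdiv + 1L)]
    cbind(closed[i, 1L] + s * (closed[i + 1L, 1L] - closed[i, 1L]),
          closed[i, 2L] + s * (closed[i + 1L, 2L] - closed[i, 2L]))
  }))
  m <- nrow(pts)
  seg <- sqrt(rowSums((rbind(pts[-1L, ], pts[1L, ]) - pts)^2))
  tt <- c(0, cumsum(seg))          # length m + 1, tt[m+1] = T
  T <- tt[m + 1L]
  px <- c(pts[, 1L], pts[1L, 1L])
  py <- c(pts[, 2L], pts[1L, 2L])
  trap <- function(f) sum(diff(tt) * (f[-1L] + f[-(m + 1L)]) / 2)
  coef <- t(vapply(seq_len(H), function(nh) {
    cn <- cos(2 * pi * nh * tt / T); sn <- sin(2 * pi * nh * tt / T)
    c(a = 2 / T * trap(px * cn), b = 2 / T * trap(px * sn),
      c = 2 / T * trap(py * cn), d = 2 / T * trap(py * sn))
  }, numeric(4)))
  colnames(coef) <- c("a", "b", "c", "d")
  list(coef = coef, A0 = trap(px) / T, C0 = trap(py) / T, T = T)
}

# Brute-force one-way ANOVA by the sum-of-squares decomposition.
anova_ss_oracle <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  k <- length(groups)
  N <- length(y)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Pooled-variance two-sample t by the textbook formula.
t_pooled_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(abs(t), na + nb - 2, lower.tail = FALSE))
}

# Independent CASA oracle: path sums written directly from definitions,
# with its own (sapply-based) shrinking-window average path.
casa_oracle <- function(track, window = 5L) {
  xy <- cbind(track$x_um, track$y_um)
  el <- track$t_seconds[nrow(xy)] - track$t_seconds[1L]
  plen <- function(m) sum(sqrt(diff(m[, 1L])^2 + diff(m[, 2L])^2))
  h <- window %/% 2L
  n <- nrow(xy)
  sm <- t(sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    colMeans(xy[(i - hh):(i + hh), , drop = FALSE])
  }))
  list(VSL = sqrt(sum((xy[n, ] - xy[1L, ])^2)) / el,
       VCL = plen(xy) / el,
       VAP = plen(sm) / el)
}

# Two-population hook-shift experiment used by PCA recovery tests.
hook_shift_experiment <- function(n_per_group = 100, shift_sd = 2,
                                  hook_sd = 4, seed = 1) {
  base <- 25
  s_wt <- population_spec("WT", n_per_group, head_params(hook_length = base),
                          sd = list(hook_length = hook_sd, body_width = 3),
                          seed = seed)
  s_ko <- population_spec("KO", n_per_group,
                          head_params(hook_length = base - shift_sd * hook_sd),
                          sd = list(hook_length = hook_sd, body_width = 3),
                          seed = seed + 7919)
  pop <- c(make_population(s_wt), make_population(s_ko))
  mat <- coefficient_matrix(pop, H = 20)
  model <- fit_shape_pca(mat, 2)
  scores <- pca_scores(model, mat,
                       group = rep(c("WT", "KO"), each = n_per_group))
  hook <- vapply(pop, function(p) p$params$hook_length, numeric(1))
  cors <- vapply(grep("^PC", names(scores), value = TRUE),
                 function(pc) stats::cor(scores[[pc]], hook), numeric(1))
  list(pop = pop, mat = mat, model = model, scores = scores,
       hook = hook, cors = cors,
       best_pc = names(cors)[which.max(abs(cors))])
}
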