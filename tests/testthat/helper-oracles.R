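# Independent brute-force oracles. These deliberately use plain loops and
# literal formulas, never the package's vectorized implementations.

# Triple-loop local mean over an edge^3 window averaged over control maps,
# truncated windows renormalized.
bf_normative <- function(maps, edge) {
  d <- dim(maps[[1]])
  r <- (edge - 1L) %/% 2L
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    tot <- 0; cnt <- 0
    for (m in maps) {
      tot <- tot + sum(m[xs, ys, zs])
      cnt <- cnt + length(xs) * length(ys) * length(zs)
    }
    out[x, y, z] <- tot / cnt
  }
  out
}

# Brute-force erosion/dilation with a cubic window (background outside).
bf_minmax <- function(a, edge, op) {
  d <- dim(a); r <- (edge - 1L) %/% 2L
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    vals <- c()
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      v <- if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
               zz >= 1 && zz <= d[3]) a[xx, yy, zz] else 0
      vals <- c(vals, v)
    }
    out[x, y, z] <- op(vals)
  }
  out
}

bf_opening <- function(a, edge) bf_minmax(bf_minmax(a, edge, min), edge, max)

# Flood-fill connected components (queue-based), returning component count
# and per-voxel component id.
bf_components <- function(a, connectivity) {
  d <- dim(a)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  deg <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = deg == 1, "18" = deg >= 1 & deg <= 2,
                      "26" = deg >= 1), , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(a == 1)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        w <- vi + offs[k, ]
        if (any(w < 1) || any(w > d)) next
        wl <- w[1] + (w[2] - 1L) * d[1] + (w[3] - 1L) * d[1] * d[2]
        if (a[wl] == 1 && lab[wl] == 0L) {
          lab[wl] <- cur
          queue <- c(queue, wl)
        }
      }
    }
  }
  list(n = cur, labels = lab)
}

# Literal-formula discriminant labels (no logs, explicit solve()).
bf_nb_label <- function(m, x) {
  lik <- function(w) {
    p <- 1
    for (f in seq_along(x))
      p <- p * (2 * pi * m$nb_sds[w, f]^2)^(-0.5) *
        exp(-(x[f] - m$mu[w, f])^2 / (2 * m$nb_sds[w, f]^2))
    p
  }
  as.integer(m$priors[["w1"]] * lik("w1") > m$priors[["w2"]] * lik("w2"))
}

bf_lda_label <- function(m, x) {
  Si <- solve(m$pooled_cov)
  g <- function(w) drop(m$mu[w, ] %*% Si %*% x) -
    0.5 * drop(m$mu[w, ] %*% Si %*% m$mu[w, ]) + log(m$priors[[w]])
  as.integer(g("w1") > g("w2"))
}

bf_qda_label <- function(m, x) {
  g <- if (m$qda_variant == "printed") function(w) {
    Si <- solve(m$class_covs[[w]])
    drop(m$mu[w, ] %*% Si %*% x) -
      0.5 * drop(m$mu[w, ] %*% Si %*% m$mu[w, ]) + log(m$priors[[w]])
  } else function(w) {
    Si <- solve(m$class_covs[[w]])
    -0.5 * drop((x - m$mu[w, ]) %*% Si %*% (x - m$mu[w, ])) -
      0.5 * determinant(m$class_covs[[w]], logarithm = TRUE)$modulus +
      log(m$priors[[w]])
  }
  as.integer(g("w1") > g("w2"))
}

bf_mda_label <- function(m, x) {
  Si <- solve(m$pooled_cov)
  D <- function(w) drop((x - m$mu[w, ]) %*% Si %*% (x - m$mu[w, ]))
  as.integer(D("w1") < D("w2"))
}

# Hand-loop confusion counts.
bf_confusion <- function(pred, truth, mask) {
  tp <- fp <- fn <- tn <- 0L
  for (i in which(mask)) {
    p <- pred[i] != 0; t <- truth[i] != 0
    if (p && t) tp <- tp + 1L else if (p) fp <- fp + 1L
    else if (t) fn <- fn + 1L else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
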