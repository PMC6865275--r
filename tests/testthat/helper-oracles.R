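# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (nested loops, flood fill) so they
# cannot share a bug with the vectorized implementations they check.

# Brute-force 3-D attention convolution: full-depth kernel, zero padding
# in height/width only.
oracle_attention_logits <- function(U, W, b) {
  d <- dim(U); dw <- dim(W)
  r <- d[1]; cc <- d[2]; k <- d[3]; Fh <- dw[4]
  off <- (dw[1] - 1) / 2
  out <- array(0, dim = c(Fh, r, cc))
  for (f in seq_len(Fh)) {
    for (i in seq_len(r)) {
      for (j in seq_len(cc)) {
        s <- b[f]
        for (kk in seq_len(k)) {
          for (a in -off:off) {
            for (bb in -off:off) {
              ii <- i + a; jj <- j + bb
              if (ii >= 1 && ii <= r && jj >= 1 && jj <= cc) {
                s <- s + W[a + off + 1, bb + off + 1, kk, f] * U[ii, jj, kk]
              }
            }
          }
        }
        out[f, i, j] <- s
      }
    }
  }
  out
}

# Nested-loop affine combination.
oracle_attend <- function(U, alpha) {
  d <- dim(U); Fh <- dim(alpha)[1]
  z <- numeric(0)
  for (f in seq_len(Fh)) {
    v <- numeric(d[3])
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        v <- v + alpha[f, i, j] * U[i, j, ]
      }
    }
    z <- c(z, v)
  }
  z
}

# 4-connected flood-fill component count on a logical matrix.
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nl <- 0L
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (mask[i0, j0] && lab[i0, j0] == 0L) {
        nl <- nl + 1L
        queue <- list(c(i0, j0))
        lab[i0, j0] <- nl
        while (length(queue) > 0) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nrow(mask) &&
                q[2] >= 1 && q[2] <= ncol(mask) &&
                mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- nl
              queue[[length(queue) + 1]] <- q
            }
          }
        }
      }
    }
  }
  nl
}

# A tiny unfrozen attention model over random cells, for shape and
# gradient tests.
tiny_model <- function(k = 6, n_filters = 3, px = 8, dropout_p = 0,
                       freeze = FALSE, arch = c("cnn", "resnet"),
                       seed = 1) {
  arch <- match.arg(arch)
  set.seed(seed)
  bb <- if (arch == "cnn") backbone_cnn(k = k, width = 4, input_px = px)
        else backbone_resnet(widths = c(4, 5, k), input_px = px)
  bb <- apply_freeze_policy(bb, enabled = freeze)
  new_attn_model(bb, attention_config(n_filters = n_filters,
                                      dropout_p = dropout_p))
}

random_cells <- function(px, n, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(px * px * 3 * n), dim = c(px, px, 3, n))
}

# Texture statistics used by the k-nearest-neighbour separability probe.
crop_stats <- function(crop) {
  g <- (crop[, , 1] + crop[, , 2] + crop[, , 3]) / 3
  ge <- mean(abs(diff(g))) + mean(abs(t(diff(t(g)))))
  c(apply(crop, 3, mean),
    apply(crop, 3, function(m) stats::var(as.vector(m))),
    grad_energy = ge)
}
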