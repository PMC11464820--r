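# shared test builders; everything is generated in code, nothing on disk

test_crs <- "EPSG:32616"

# small categorical raster from a matrix (30 m cells, origin 0 / nrow*30)
mk_raster <- function(values, cell = 30, nodata = 0L) {
  values <- as.matrix(values)
  cat_raster(values, xmin = 0, ymax = nrow(values) * cell, cell = cell,
             crs = test_crs, nodata = nodata)
}

mk_num_raster <- function(values, cell = 30) {
  values <- as.matrix(values)
  num_raster(values, xmin = 0, ymax = nrow(values) * cell, cell = cell,
             crs = test_crs)
}

# random stack of binary class masks on one grid
random_masks <- function(nr, nc, codes, p = 0.4) {
  masks <- list()
  for (cd in codes) {
    v <- matrix(0L, nr, nc)
    v[stats::runif(nr * nc) < p] <- as.integer(cd)
    masks[[as.character(cd)]] <- mk_raster(v)
  }
  masks
}

# tiny two-class registry for overlay tests (codes drawn from the default
# table so priorities exist)
square_feature <- function(id, xmin, ymin, xmax, ymax, tags) {
  tagged_feature(id, geom_rect(xmin, ymin, xmax, ymax), tags)
}

line_feature <- function(id, coords, tags) {
  tagged_feature(id, geom_line(as.matrix(coords)), tags)
}

# brute-force kappa/precision from first principles (independent of the
# package implementation)
oracle_kappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- 0
  for (i in seq_len(nrow(m))) pe <- pe + sum(m[i, ]) * sum(m[, i])
  pe <- pe / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

oracle_precision <- function(m) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    rs <- sum(m[i, ])
    out[i] <- if (rs == 0) NA_real_ else m[i, i] / rs
  }
  out
}

# exhaustive-enumeration autologistic likelihood (latent-state sum)
enum_loglik <- function(h, x, beta, theta, alpha) {
  y <- h$y
  n <- dim(y)[1]; T_ <- dim(y)[2]
  p <- 1 / (1 + exp(-alpha))
  total <- 0
  for (i in seq_len(n)) {
    eta <- beta[1] + if (length(beta) > 1) beta[2] * x[i] else 0
    s <- 0
    for (cfg in 0:(2^T_ - 1)) {
      z <- as.integer(intToBits(cfg))[seq_len(T_)]
      pr <- 1
      for (t in seq_len(T_)) {
        psi <- 1 / (1 + exp(-(eta + if (t > 1) theta * z[t - 1] else 0)))
        pr <- pr * (if (z[t] == 1) psi else 1 - psi)
        wk <- y[i, t, ]
        wk <- wk[!is.na(wk)]
        for (w in wk) {
          pw <- if (z[t] == 1) p^w * (1 - p)^(1 - w) else as.numeric(w == 0)
          pr <- pr * pw
        }
      }
      s <- s + pr
    }
    total <- total + log(s)
  }
  total
}
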