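# Independent straight-line implementations of the quality metrics, written
# as direct summations of the defining formulas with explicit loops. They
# share no code with the package and serve as component-wise oracles.

oracle_entropy <- function(img) {
  img <- unclass(img)
  counts <- numeric(256)
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      g <- round(0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3])
      counts[g + 1] <- counts[g + 1] + 1
    }
  }
  total <- sum(counts)
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / total
      h <- h - p * log2(p)
    }
  }
  h
}

oracle_block_stat <- function(mat, block, f) {
  k1 <- nrow(mat) %/% block
  k2 <- ncol(mat) %/% block
  vals <- c()
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      blk <- mat[((i - 1) * block + 1):(i * block),
                 ((j - 1) * block + 1):(j * block)]
      vals <- c(vals, f(blk))
    }
  }
  list(vals = vals, k1 = k1, k2 = k2)
}

oracle_eme <- function(mat, block = 10) {
  bs <- oracle_block_stat(mat, block, function(blk) {
    mx <- max(blk); mn <- min(blk)
    if (mn > 0 && mx > 0) log(mx / mn) else 0
  })
  2 / (bs$k1 * bs$k2) * sum(bs$vals)
}

oracle_log_amee <- function(mat, block = 10) {
  bs <- oracle_block_stat(mat, block, function(blk) {
    mx <- max(blk); mn <- min(blk)
    if (mx + mn > 0 && mx > mn) {
      w <- (mx - mn) / (mx + mn)
      -w * log(w)
    } else 0
  })
  sum(bs$vals) / (bs$k1 * bs$k2)
}

oracle_sobel <- function(mat) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns: -1 0 1
  ky <- t(kx)
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(0, h - 2, w - 2)
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      gx <- 0; gy <- 0
      for (di in -1:1) for (dj in -1:1) {
        gx <- gx + kx[di + 2, dj + 2] * mat[i + di, j + dj]
        gy <- gy + ky[di + 2, dj + 2] * mat[i + di, j + dj]
      }
      out[i - 1, j - 1] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

oracle_trimmed_moments <- function(x, trim = 0.1) {
  xs <- sort(x)
  n <- length(xs)
  t <- floor(trim * n)
  mu <- mean(xs[(t + 1):(n - t)])
  s2 <- 0
  for (v in x) s2 <- s2 + (v - mu)^2
  list(mu = mu, s2 = s2 / n)
}

oracle_uiqm <- function(img, block = 10) {
  img <- unclass(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  rg <- as.vector(r - g); yb <- as.vector((r + g) / 2 - b)
  mrg <- oracle_trimmed_moments(rg); myb <- oracle_trimmed_moments(yb)
  uicm <- -0.0268 * sqrt(mrg$mu^2 + myb$mu^2) +
    0.1586 * sqrt(mrg$s2 + myb$s2)
  uism <- 0.299 * oracle_eme(oracle_sobel(r), block) +
    0.587 * oracle_eme(oracle_sobel(g), block) +
    0.114 * oracle_eme(oracle_sobel(b), block)
  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  uiconm <- oracle_log_amee(gray, block)
  list(total = 0.0282 * uicm + 0.2953 * uism + 3.5753 * uiconm,
       uicm = uicm, uism = uism, uiconm = uiconm)
}

oracle_uciqe <- function(img) {
  img <- unclass(img)
  n <- nrow(img) * ncol(img)
  srgb <- matrix(0, n, 3)
  k <- 1
  for (j in seq_len(ncol(img))) {
    for (i in seq_len(nrow(img))) {
      srgb[k, ] <- img[i, j, ] / 255
      k <- k + 1
    }
  }
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  L <- lab[, 1]
  chroma <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  mu_c <- mean(chroma)
  sigma_c <- sqrt(sum((chroma - mu_c)^2) / n) / 100
  qs <- sort(L)
  con_l <- (quantile(L, 0.99, names = FALSE) - quantile(L, 0.01, names = FALSE)) / 100
  sat <- 0
  for (k in seq_len(n)) {
    d <- sqrt(chroma[k]^2 + L[k]^2)
    if (d > 0) sat <- sat + chroma[k] / d
  }
  mu_s <- sat / n
  list(total = 0.4680 * sigma_c + 0.2745 * con_l + 0.2576 * mu_s,
       sigma_chroma = sigma_c, con_luminance = con_l, mu_saturation = mu_s)
}

oracle_ccf <- function(img) {
  img <- unclass(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  rg <- r - g; yb <- (r + g) / 2 - b
  psd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  cf <- (sqrt(psd(rg)^2 + psd(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)) / 85.59
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  contrast <- psd(as.vector(gray)) / 255
  dark <- 0
  n <- length(r)
  for (k in seq_len(n)) dark <- dark + min(r[k], g[k], b[k])
  clarity <- 1 - (dark / n) / 255
  list(total = 0.17593 * cf + 0.61759 * contrast + 0.33988 * clarity,
       colorfulness = cf, contrast = contrast, clarity = clarity)
}

# Fixed deterministic test patterns ---------------------------------------

constant_image <- function(level = 128, n = 16) {
  rgb_image(array(level, dim = c(n, n, 3)))
}

two_tone_image <- function(n = 16) {
  px <- array(0, dim = c(n, n, 3))
  px[, 1:(n / 2), ] <- rep(c(200, 50, 30), each = n * n / 2)
  px[, (n / 2 + 1):n, ] <- rep(c(30, 80, 220), each = n * n / 2)
  rgb_image(px)
}

checkerboard_image <- function(n = 16) {
  px <- array(0, dim = c(n, n, 3))
  odd <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 0)
  red <- c(220, 30, 40); blue <- c(20, 40, 210)
  for (c in 1:3) {
    ch <- matrix(blue[c], n, n)
    ch[odd] <- red[c]
    px[, , c] <- ch
  }
  rgb_image(px)
}
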