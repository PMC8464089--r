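# Independent oracles: literal, unoptimized transcriptions of the defining
# equations, kept deliberately separate from the production code paths.

# Higuchi curve-length dimension via explicit nested loops.
higuchi_naive <- function(t_sig, p_max) {
  y <- length(t_sig)
  a_mean <- numeric(p_max)
  for (p in 1:p_max) {
    af <- numeric(p)
    for (f in 1:p) {
      n_j <- floor((y - f) / p)
      total <- 0
      for (j in 1:n_j)
        total <- total + abs(t_sig[f + j * p] - t_sig[f + (j - 1) * p])
      af[f] <- (total * (y - 1) / (n_j * p)) / p
    }
    a_mean[p] <- sum(af) / p
  }
  fit <- stats::lm(log(a_mean) ~ log(1 / (1:p_max)))
  unname(stats::coef(fit)[2])
}

# Katz dimension via the literal normalized form K = log10(U/m)/log10(b/m).
katz_naive <- function(y) {
  n_pts <- length(y)
  x <- seq_len(n_pts)
  u <- 0
  for (j in 1:(n_pts - 1))
    u <- u + sqrt((x[j + 1] - x[j])^2 + (y[j + 1] - y[j])^2)
  b <- 0
  for (j in 1:n_pts)
    b <- max(b, sqrt((x[1] - x[j])^2 + (y[1] - y[j])^2))
  m <- u / (n_pts - 1)
  log10(u / m) / log10(b / m)
}

# Quadratic-time LZ76 exhaustive-history parser: substring occurrence is
# decided by scanning every start position and comparing element-wise.
occurs_in_prefix <- function(bits, from, to) {
  len <- to - from + 1L
  limit <- to - 1L - len + 1L
  if (limit < 1L) return(FALSE)
  for (s in 1:limit) {
    hit <- TRUE
    for (o in 0:(len - 1L)) {
      if (bits[s + o] != bits[from + o]) { hit <- FALSE; break }
    }
    if (hit) return(TRUE)
  }
  FALSE
}

lz76_naive <- function(bits) {
  m <- length(bits)
  count <- 0L
  p <- 1L
  while (p <= m) {
    q <- p
    while (q <= m && occurs_in_prefix(bits, p, q)) q <- q + 1L
    count <- count + 1L          # new component (or incomplete final one)
    p <- q + 1L
  }
  count
}

# Plain-loop multi-class ReliefF over all instances (k nearest hits and
# per-class misses under Manhattan distance on range-normalized features).
relieff_naive <- function(x, labels, k) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x); nf <- ncol(x)
  rng <- apply(x, 2, function(col) max(col) - min(col))
  prior <- table(labels) / n
  ndiff <- function(f, i, j) {
    if (rng[f] == 0) return(0)
    abs(x[i, f] - x[j, f]) / rng[f]
  }
  dist_ij <- function(i, j) {
    d <- 0
    for (f in 1:nf) d <- d + ndiff(f, i, j)
    d
  }
  w <- numeric(nf)
  for (i in 1:n) {
    for (cl in levels(labels)) {
      members <- setdiff(which(labels == cl), i)
      d <- vapply(members, function(j) dist_ij(i, j), numeric(1))
      nb <- members[order(d, members)][1:k]
      for (f in 1:nf) {
        md <- mean(vapply(nb, function(j) ndiff(f, i, j), numeric(1)))
        if (cl == as.character(labels[i])) w[f] <- w[f] - md / n
        else w[f] <- w[f] +
            (prior[[cl]] / (1 - prior[[as.character(labels[i])]])) * md / n
      }
    }
  }
  names(w) <- colnames(x)
  w
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}

# steady-state amplitude of a (near-)sinusoidal response, edges trimmed
tone_amplitude <- function(y, fs, trim_s) {
  core <- y[(round(trim_s * fs) + 1):(length(y) - round(trim_s * fs))]
  sqrt(2) * sqrt(mean(core^2))
}
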