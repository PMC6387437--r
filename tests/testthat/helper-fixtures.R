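# small builders shared across the test files

fs_default <- 250

sine_segment <- function(freq, amp = 100, fs = fs_default, phase = 0) {
  eeg_segment(amp * sin(2 * pi * freq * (0:(fs - 1)) / fs + phase), fs)
}

noise_segment <- function(seed, sd = 20, fs = fs_default) {
  set.seed(seed)
  eeg_segment(stats::rnorm(fs, sd = sd), fs)
}

seg_rms <- function(seg) sqrt(mean(seg$samples^2))

# independent brute-force oracle for symmetrical uncertainty: entropies
# computed from explicitly enumerated joint probabilities
su_oracle <- function(a, b) {
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  av <- unique(a); bv <- unique(b)
  pj <- outer(av, bv, Vectorize(function(x, y) mean(a == x & b == y)))
  ha <- ent(rowSums(pj)); hb <- ent(colSums(pj)); hj <- ent(as.vector(pj))
  ig <- ha + hb - hj                       # = H(a) - H(a|b)
  if (ha + hb == 0) 0 else 2 * ig / (ha + hb)
}

# independent brute-force kNN oracle: full sort, neighbour set includes
# distance ties with the k-th, inverse-square weights, worst-quality ties
knn_oracle <- function(train_x, train_y, x, k, weighted,
                       classes = c("LOW_Q", "MED_Q", "HIGH_Q")) {
  d <- apply(train_x, 1, function(row) sqrt(sum((row - x)^2)))
  kth <- sort(d)[min(k, length(d))]
  nb <- which(d <= kth * (1 + 1e-12) + 1e-300)
  if (any(d[nb] < 1e-10)) {
    nb <- nb[d[nb] < 1e-10]
    w <- rep(1, length(nb))
  } else if (weighted) w <- 1 / d[nb]^2 else w <- rep(1, length(nb))
  votes <- sapply(classes, function(cl) sum(w[train_y[nb] == cl]))
  classes[which.max(votes)]
}

# direct transcription of the normalised Itakura formula, loop form
itakura_oracle <- function(pxx, pyy, freq, f_max = 40) {
  sel <- freq > 0 & freq < f_max
  r <- pmax(pxx[sel], 1e-12) / pmax(pyy[sel], 1e-12)
  s <- 0; sl <- 0; n <- 0
  for (v in r) { s <- s + v; sl <- sl + log(v); n <- n + 1 }
  log(s / n) - sl / n
}
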