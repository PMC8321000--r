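# Independent reference implementations used as oracles. These deliberately
# avoid the code paths of the package functions they check.

# Otsu: exhaustive scan of all 256 candidate thresholds, recomputing the two
# class weights and means from the raw pixel vector each time; smallest tie.
oracle_otsu <- function(values) {
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# local minima of a count sequence via run-length encoding: an interior run
# bounded by strictly larger runs is one minimum at its centre bin
oracle_local_minima <- function(counts) {
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  if (length(r$values) < 3L) return(out)
  for (i in 2:(length(r$values) - 1L)) {
    if (r$values[i - 1L] > r$values[i] && r$values[i + 1L] > r$values[i])
      out <- c(out, starts[i] + (ends[i] - starts[i]) %/% 2L)
  }
  out
}

# second-minimum background threshold from a histogram, brute force
oracle_lambda <- function(hist) {
  minima <- oracle_local_minima(hist$counts)
  if (length(minima) < 2L) return(NULL)
  min(hist$bin_edges[minima[2L]] + hist$bin_step - 1L, 255L)
}

# breadth-first region growing with a running mean, row-major visit order
oracle_grow <- function(img, mask, seed, max_distance) {
  M <- nrow(img); N <- ncol(img)
  v <- img / 255
  region <- matrix(FALSE, M, N)
  region[seed[1], seed[2]] <- TRUE
  queue <- list(seed)
  s <- v[seed[1], seed[2]]
  n <- 1
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  while (length(queue) > 0) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (k in 1:8) {
      r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
      if (r < 1 || r > M || c < 1 || c > N) next
      if (!mask[r, c] || region[r, c]) next
      if (abs(v[r, c] - s / n) <= max_distance + 1e-12) {
        region[r, c] <- TRUE
        s <- s + v[r, c]
        n <- n + 1
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  region
}

# detection metrics recomputed directly from their defining formulas
oracle_metrics <- function(tp, tn, fp, fn, beta, n_images, n_exams) {
  div <- function(a, b) if (b == 0) 0 else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  acc <- div(tp + tn, tp + tn + fp + fn)
  fb <- div((1 + beta^2) * prec * sens, beta^2 * prec + sens)
  mcc <- if ((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn) == 0) 0 else
    (tp * tn - fp * fn) /
      (sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn))
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = acc, f_beta = fb, mcc = mcc,
       fpi = fp / n_images, fpe = fp / n_exams)
}

make_histogram <- function(counts, kappa = 5L) {
  structure(list(bin_step = as.integer(kappa), counts = as.numeric(counts),
                 bin_edges = kappa * (seq_along(counts) - 1L),
                 n_pixels = sum(counts)),
            class = "slice_histogram")
}

random_histogram <- function() {
  nb <- sample(8:52, 1)
  make_histogram(rpois(nb, lambda = sample(c(2, 5, 50), 1)),
                 kappa = sample(c(3L, 5L, 8L), 1))
}

draw_disc <- function(M, N, r0, c0, radius) {
  rr <- matrix(seq_len(M), M, N)
  cc <- matrix(rep(seq_len(N), each = M), M, N)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}
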