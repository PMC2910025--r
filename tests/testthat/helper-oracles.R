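# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately use different algorithms or naive direct
# summation, and must stay independent of the code paths they verify.

# draw a random protein sequence
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# z-scale lookup as a plain matrix, independent of package internals beyond
# the exported table
zmat_oracle <- function() {
  tbl <- zscales()
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$aa
  m
}

# naive double-loop ACC with per-sequence centering
acc_oracle <- function(seq, max_lag) {
  z <- zmat_oracle()[strsplit(seq, "")[[1]], , drop = FALSE]
  z <- sweep(z, 2, colMeans(z))
  n <- nrow(z)
  out <- c()
  for (lag in 1:max_lag) {
    for (a in 1:5) {
      for (b in 1:5) {
        s <- 0
        for (i in 1:(n - lag)) s <- s + z[i, a] * z[i + lag, b]
        out <- c(out, s / (n - lag))
      }
    }
  }
  out
}

# exhaustive MACC1: per (lag, a, b), extreme product in each sign quadrant
# of the raw z-scale values
macc_oracle <- function(seq, max_lag) {
  z <- zmat_oracle()[strsplit(seq, "")[[1]], , drop = FALSE]
  n <- nrow(z)
  out <- c()
  for (lag in 1:max_lag) {
    for (a in 1:5) {
      for (b in 1:5) {
        pp <- nn <- pn <- np <- 0
        for (i in 1:(n - lag)) {
          x1 <- z[i, a]; x2 <- z[i + lag, b]; pr <- x1 * x2
          if (x1 > 0 && x2 > 0 && pr > pp) pp <- pr
          if (x1 < 0 && x2 < 0 && pr > nn) nn <- pr
          if (x1 > 0 && x2 < 0 && pr < pn) pn <- pr
          if (x1 < 0 && x2 > 0 && pr < np) np <- pr
        }
        out <- c(out, pp, nn, pn, np)
      }
    }
  }
  out
}

# SIMPLS (de Jong 1993): an algorithmically distinct PLS1 route used to
# cross-check the NIPALS implementation. Returns the coefficient vector for
# centred X and y.
simpls_oracle <- function(x, y, a_max) {
  n <- nrow(x); p <- ncol(x)
  s <- crossprod(x, y)          # p x 1
  R <- matrix(0, p, a_max)
  V <- matrix(0, p, a_max)
  q <- numeric(a_max)
  for (a in seq_len(a_max)) {
    r <- s
    t_vec <- x %*% r
    t_vec <- t_vec - mean(t_vec)
    normt <- sqrt(sum(t_vec^2))
    t_vec <- t_vec / normt
    r <- r / normt
    p_vec <- crossprod(x, t_vec)
    q[a] <- crossprod(y, t_vec)
    v <- p_vec
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_vec)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
  }
  R %*% q
}

# direct-summation type-1 pseudo-amino-acid oracle
paa_oracle <- function(seq, lambda = 30, w = 0.05) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  h1 <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
          H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
          H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
          P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
          W = -3.4, Y = -2.3)
  ms <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
          K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
          T = 45, V = 43, W = 130, Y = 107)
  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  props <- cbind(std(h1[aa]), std(h2[aa]), std(ms[aa]))
  rownames(props) <- aa
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  theta <- numeric(lambda)
  for (d in 1:lambda) {
    acc <- 0
    for (i in 1:(n - d)) {
      acc <- acc + mean((props[chars[i], ] - props[chars[i + d], ])^2)
    }
    theta[d] <- acc / (n - d)
  }
  f <- table(factor(chars, levels = aa)) / n
  denom <- sum(f) + w * sum(theta)
  c(as.numeric(f) / denom, w * theta / denom)
}

# small synthetic panel shared by model-level tests (built once per run)
tiny_panel <- function(seed = 7) {
  simulate_kinome_panel(synth_config(
    n_kinases = 35, n_inhibitors = 10, n_ligand_descriptors = 30,
    seq_length_range = c(90, 120), length_tails = c(80, 150),
    core_length = 70, seed = seed
  ))
}
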