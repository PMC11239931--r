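# shared desk-scale fixtures, all generated in code

# small analysis grid used across tests
small_grid <- function() {
  list(freqs = seq(40, 140, length.out = 20),
       times = seq(0.75, 1.15, length.out = 30))
}

small_config <- function(seed = 1, ...) {
  g <- small_grid()
  synthetic_config(freqs = g$freqs, times = g$times, seed = seed, ...)
}

# independent brute-force enumerator of the reference model, written
# directly from the level equations without reusing package internals;
# serves as the oracle for contrast_design
brute_force_contrast <- function(s0, s1, s2, q_xx = 0.05, q_xy = 0.2,
                                 d = 0.2, adapted = TRUE) {
  pe_pair <- function(q, fifth, std_fifth) {
    e1_of <- function(f) {
      I <- c(x = if (f == "x") s0 else 0, y = if (f == "y") 1 else 0)
      target_x <- if (adapted) (1 - q) * s0 else (1 - q)
      c(x = I[["x"]] - s1 * target_x, y = I[["y"]] - s1 * q)
    }
    dev_fifth <- setdiff(c("x", "y"), std_fifth)
    P2 <- s2 * ((1 - d) * e1_of(std_fifth) + d * e1_of(dev_fifth))
    e1 <- e1_of(fifth)
    e2 <- e1 - P2
    c(PE1 = sum(abs(e1)), PE2 = sum(abs(e2)))
  }
  rbind(pe_pair(q_xx, "y", "x") - pe_pair(q_xx, "x", "x"),
        pe_pair(q_xy, "y", "y") - pe_pair(q_xy, "x", "y"))
}

# exact rank-2 tensor with the given fixed-mode matrix
exact_rank2_tensor <- function(A, n_ic = 3, n_tf = 40, seed = 7) {
  set.seed(seed)
  B <- matrix(rnorm(n_ic * 2), n_ic, 2)
  C <- matrix(rnorm(n_tf * 2), n_tf, 2)
  X <- array(0, c(2, n_ic, n_tf))
  for (r in 1:2) X <- X + outer(A[, r], outer(B[, r], C[, r]))
  list(X = X, B = B, C = C)
}
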