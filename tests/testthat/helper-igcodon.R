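# Small codes and trees shared across tests. toy2 is the minimal
# 4-"codon" code over {A,C}; toy3 adds G so transitions (A<->G) exist and
# kappa is identifiable, with synonymous transitions and transversions
# and three amino-acid classes.
toy2 <- function() {
  toy_code(c("A", "C"), 2, c(AA = "K", AC = "K", CA = "T", CC = "T"))
}

toy3 <- function() {
  toy_code(c("A", "C", "G"), 2,
           c(AA = "K", AC = "N", AG = "K",
             CA = "T", CC = "T", CG = "R",
             GA = "E", GC = "D", GG = "E"))
}

toy2_params <- function(tau = 0.4, omega = 0.5) {
  igc_params(pi = c(A = 0.6, C = 0.4), kappa = 1, omega = omega, tau = tau)
}

two_tip_tree <- function() {
  read_duplication_tree("(((A:0.15,B:0.15)spec:0.1)dup:0.1,Out:0.3)root;",
                        duplication_node = "dup")
}

# Exhaustive-likelihood oracle for the two_tip_tree shape: direct
# summation over root, duplication and first-speciation states, using
# matrix exponentials but none of the package's pruning code.
brute_force_ll <- function(out_codon, a_pair, b_pair, params, code) {
  tree <- two_tip_tree()
  n <- code$n
  srm <- single_rate_matrix(single_interval_params(params), code)
  prm <- pair_rate_matrix(params, code)
  Ps <- function(t) as.matrix(Matrix::expm(Matrix::Matrix(srm$q) * t))
  Pp <- function(t) as.matrix(Matrix::expm(prm$q * t))
  f <- srm$stationary
  P_out <- Ps(0.3); P_rd <- Ps(0.1); P_ds <- Pp(0.1); P_tip <- Pp(0.15)
  oc <- match(out_codon, code$codons)
  ai <- pair_index(match(a_pair[1], code$codons),
                   match(a_pair[2], code$codons), n)
  bi <- pair_index(match(b_pair[1], code$codons),
                   match(b_pair[2], code$codons), n)
  tot <- 0
  for (r in seq_len(n)) for (d in seq_len(n)) for (s in seq_len(n * n)) {
    tot <- tot + f[r] * P_out[r, oc] * P_rd[r, d] *
      P_ds[pair_index(d, d, n), s] * P_tip[s, ai] * P_tip[s, bi]
  }
  log(tot)
}

# random point on the simplex, for randomized toy parameter draws
random_simplex <- function(k) {
  x <- stats::rgamma(k, 2)
  x / sum(x)
}
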