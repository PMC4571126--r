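# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Unsigned Stirling numbers of the first kind |s(n, k)| for k = 1..n, by the
# integer recurrence |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|. Exact in doubles
# for the small n used here.
stirling1_unsigned <- function(n) {
  s <- 1
  if (n > 1) {
    for (m in seq_len(n - 1)) s <- m * c(s, 0) + c(0, s)
  }
  s
}

# Ewens distribution of the haplotype count by direct enumeration:
# P(K = k) = |s(n, k)| theta^k / theta_(n).
ewens_oracle <- function(n, theta) {
  s <- stirling1_unsigned(n)
  rising <- prod(theta + 0:(n - 1))
  s * theta^seq_len(n) / rising
}

# Brute-force Poisson (x) geometric convolution: the sudden-expansion
# expectation in the theta1 -> Inf limit.
pois_geom_conv <- function(tau, theta0, max_class) {
  g <- theta0^(0:max_class) / (theta0 + 1)^(1:(max_class + 1))
  vapply(0:max_class, function(i) {
    sum(dpois(i - 0:i, tau) * g[1:(i + 1)])
  }, 0)
}

# Toy alignment with hand-counted pairwise differences {0, 1, 1, 1, 1, 2}:
# d(s1,s2)=1, d(s1,s3)=1, d(s1,s4)=0, d(s2,s3)=2, d(s2,s4)=1, d(s3,s4)=1.
toy_alignment <- function() {
  dna_alignment(c(s1 = "AAAAAAAAAA",
                  s2 = "CAAAAAAAAA",
                  s3 = "ACAAAAAAAA",
                  s4 = "AAAAAAAAAA"))
}

# Write a dna_alignment-like FASTA with arbitrary raw lines.
write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
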