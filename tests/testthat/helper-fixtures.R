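# shared fixture builders; everything generated in code, nothing on disk

make_table <- function(values, unit = "counts",
                       samples = sprintf("s%d", seq_len(nrow(values))),
                       features = sprintf("f%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, features)
  abundance_table(values, unit = unit)
}

# random relative-abundance row with a controllable number of zeros
random_rel_row <- function(n_pos, n_zero = 0) {
  v <- c(stats::runif(n_pos), rep(0, n_zero))
  v / sum(v)
}

# random strictly positive composition matrix
random_pos_matrix <- function(n, d) {
  m <- matrix(stats::rexp(n * d) + 1e-8, nrow = n,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("f%d", seq_len(d))))
  m
}
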