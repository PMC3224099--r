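# Shared fixtures, built in code. The standard synthetic study used across
# tests: 200 genes, 10 TFs with 15 targets each, 50 conditions.
std_topology <- function(seed = 42) generate_topology(200L, 10L, 15L, seed)

std_truth <- function(noise_sd = 0, seed = 7, topo = std_topology()) {
  generate_truth(topo, 50L, noise_sd = noise_sd, seed = seed)
}

# Orthogonal control-strength design: TFs with disjoint target blocks.
block_topology <- function(n_tfs = 10L, block = 15L) {
  n <- n_tfs * block
  m <- matrix(0, n, n_tfs,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              sprintf("TF%02d", seq_len(n_tfs))))
  for (j in seq_len(n_tfs)) m[((j - 1L) * block + 1L):(j * block), j] <- 1
  m
}

per_tf_abs_cor <- function(tfa_est, tfa_true) {
  vapply(seq_len(nrow(tfa_true)),
         function(j) abs(stats::cor(tfa_est[j, ], tfa_true[j, ])),
         numeric(1))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
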