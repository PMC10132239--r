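## splicing-event fixture builders shared across test files

mk_event <- function(id, type = "SE", gene = "g1", psi_c = 0.4, dpsi = 0.2,
                     fdr = 0.01, reads_c = 10L, reads_k = 10L) {
  psi_k <- psi_c + dpsi
  data.frame(event_id = id, type = type, gene_id = gene,
             ijc_control = as.integer(round(reads_c * psi_c)),
             sjc_control = as.integer(reads_c - round(reads_c * psi_c)),
             ijc_kd = as.integer(round(reads_k * psi_k)),
             sjc_kd = as.integer(reads_k - round(reads_k * psi_k)),
             psi_control = psi_c, psi_kd = psi_k, dpsi = dpsi, fdr = fdr,
             stringsAsFactors = FALSE)
}

## the canonical 20-row fixture: rows p01-p07 pass all three thresholds
## (reads >= 5, |dpsi| >= 0.1, fdr < 0.05); the rest each violate one
fixture20 <- function() {
  pass <- lapply(1:7, function(i)
    mk_event(sprintf("p%02d", i), dpsi = 0.1 + 0.05 * i,
             fdr = 0.049 / i, reads_c = 5L + i, reads_k = 5L))
  low_reads <- lapply(1:4, function(i)
    mk_event(sprintf("r%02d", i), dpsi = 0.3, fdr = 0.001,
             reads_c = 2L, reads_k = 2L))
  low_dpsi <- lapply(1:5, function(i)
    mk_event(sprintf("d%02d", i), dpsi = 0.09 - 0.01 * i, fdr = 0.001))
  high_fdr <- lapply(1:4, function(i)
    mk_event(sprintf("f%02d", i), dpsi = -0.4, fdr = 0.05 + 0.1 * i))
  do.call(rbind, c(pass, low_reads, low_dpsi, high_fdr))
}
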