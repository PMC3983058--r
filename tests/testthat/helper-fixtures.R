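# Synthetic stand-ins for the study sequences (the CasSD domain of mouse and
# rat p130Cas): generated, not downloaded, with the domain's documented
# statistics -- 306 residues, 15 evenly spaced YxxP motifs, proline fraction
# 19.9% (mouse-like) / 20.9% (rat-like).
synthetic_cassd <- function(seed = 1, proline_fraction = 0.199) {
  gen_proline_rich_sequence(306, proline_fraction, motif_count = 15,
                            motif_period = 20, seed = seed)
}

# Expression tag residues documented for the purified construct: MG at the
# N-terminus and ENLYFQSLEHHHHHH at the C-terminus (17 residues total).
TAG_N <- "MG"
TAG_C <- "ENLYFQSLEHHHHHH"

tagged_construct <- function(seed = 1) {
  paste0(TAG_N, synthetic_cassd(seed), TAG_C)
}

# Independent brute-force radius of gyration via the pairwise double sum:
# Rg^2 = (1/(2 N^2)) * sum_ij d_ij^2
rgyr_bruteforce <- function(m) {
  n <- nrow(m)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + sum((m[i, ] - m[j, ])^2)
    }
  }
  sqrt(s / (2 * n^2))
}
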